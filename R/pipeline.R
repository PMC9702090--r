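# ---- run configuration and end-to-end pipeline --------------------------

.default_run_config <- function() {
  list(
    paths = list(weather = NULL, phenotypes = NULL,
                 output_dir = "envmet-output"),
    simulate = TRUE,
    simulation = list(),                # arguments forwarded to sim_config()
    analysis = list(
      k = 4,
      quantiles = c(0.01, 0.25, 0.50, 0.75, 0.975, 0.99),
      sowing = "06-10",
      theta_y = 70, theta_s = 30,
      intensity = 6 / 26,
      etp_method = "priestley-taylor",
      tbase = 8,
      cardinal = c(9, 26, 32, 45),
      qc_sd = 3,
      lrt_dist = "chisq1"
    ),
    seed = 20221114L,
    log_level = "INFO"
  )
}

# recursively merge `over` into `base`
.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Build a pipeline run configuration
#'
#' Assembles the configuration driving [run_pipeline()]: input paths (or
#' simulation settings), analysis parameters (number of mega-environments,
#' typology quantiles, sowing date, MPS weights, selection intensity, ETP
#' method, thermal parameters, QC threshold, LRT reference distribution)
#' and the seed from which all randomness flows.
#'
#' @param path optional YAML file; its keys override the defaults.
#' @param ... further overrides as named (possibly nested) lists or scalar
#'   values, applied after the YAML.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- .default_run_config()
  if (!is.null(path)) {
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  over <- list(...)
  if (length(over)) cfg <- .merge_config(cfg, over)
  a <- cfg$analysis
  if (a$theta_y < 0 || a$theta_s < 0 || a$theta_y + a$theta_s <= 0) {
    stop("invalid MPS weights in configuration", call. = FALSE)
  }
  if (a$intensity <= 0 || a$intensity > 1) {
    stop("selection intensity must be in (0, 1]", call. = FALSE)
  }
  if (!isTRUE(cfg$simulate)) {
    for (p in c("weather", "phenotypes")) {
      if (is.null(cfg$paths[[p]]) || !file.exists(cfg$paths[[p]])) {
        stop("non-simulation run requires an existing '", p, "' path",
             call. = FALSE)
      }
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full envirotyping-to-selection pipeline
#'
#' Executes, in order: weather ingestion (or simulation), covariable
#' derivation, envirotype matrix and enviromic kernel, mega-environment
#' delineation, environmental typology of the trial seasons, per-trait REML
#' variance components with likelihood-ratio tests and heritability,
#' per-ME mean-performance-and-stability tables, factor-analytic MTMPS
#' selection, selection differentials, and the cross-ME membership summary.
#' All tabular artefacts are written as CSV under the configured output
#' directory together with a machine-readable `summary.json` and a run log;
#' a fixed seed makes the run idempotent.
#'
#' @param config a [run_config()] object.
#' @return (invisibly) a list bundle with every intermediate result and
#'   `paths` of the written artefacts.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  done <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\ncompleted artefacts: ",
           if (length(done)) paste(done, collapse = ", ") else "(none)",
           call. = FALSE)
    })
  }
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_table(x, p)
    done <<- c(done, p)
    p
  }

  a <- config$analysis
  note("seed: ", config$seed)
  note("R version: ", as.character(getRversion()),
       "; envmet ", as.character(utils::packageVersion("envmet")))

  # -- inputs: simulate or read ------------------------------------------
  simcfg <- NULL
  bundle <- list(config = config)
  if (isTRUE(config$simulate)) {
    simcfg <- stage("simulate", do.call(sim_config, c(
      config$simulation, list(rng_seed = .child_seed(config$seed, "sim")))))
    weather <- stage("simulate", simulate_weather(simcfg))
    trial <- stage("simulate", simulate_trial(simcfg))
    emit(weather, "weather.csv")
    emit(trial, "phenotypes.csv")
    note("simulated weather and phenotypes at seed ", simcfg$rng_seed)
  } else {
    weather <- stage("ingest", read_weather(config$paths$weather))
    trial <- stage("ingest", read_phenotypes(config$paths$phenotypes))
    gp <- attr(weather, "gaps")
    if (length(gp)) note("weather gaps: ",
                         paste(names(gp), collapse = ", "))
  }

  # -- envirotyping -------------------------------------------------------
  cpar <- covariable_params(tbase = a$tbase, cardinal = a$cardinal,
                            etp_method = a$etp_method)
  cov <- stage("covariables", derive_covariables(weather, cpar))
  emit(cov, "covariables.csv")

  w <- stage("w_matrix", build_w_matrix(cov, qc_sd = a$qc_sd))
  note(sprintf("W matrix: %d x %d after QC (%d columns removed)",
               nrow(w$W), ncol(w$W), length(w$removed)))
  for (rc in names(w$removed)) note("QC removed ", rc, ": ", w$removed[[rc]])
  emit(w$W, "w_matrix.csv")

  kern <- stage("kernel", enviromic_kernel(w))
  emit(kern$K, "enviromic_kernel.csv")

  asg <- stage("delineate", delineate_mega_environments(kern, k = a$k))
  emit(asg$assignment, "me_assignment.csv")
  note("ME sizes: ", paste(table(asg$assignment$ME), collapse = "/"))

  # -- trial-season typology ---------------------------------------------
  trial_years <- sort(unique(trial$year))
  cov_trial <- cov[as.integer(format(as.Date(cov$date), "%Y")) %in%
                     trial_years, , drop = FALSE]
  typ <- stage("typology", env_typing(cov_trial, asg, sowing = a$sowing,
                                      quantiles = a$quantiles))
  emit(typ, "typology.csv")
  sk <- attr(typ, "skipped")
  if (length(sk)) note("typology groups with no days (omitted): ",
                       paste(sk, collapse = "; "))

  # -- variance components -----------------------------------------------
  trial$ME <- asg$assignment$ME[match(trial$location,
                                      asg$assignment$environment)]
  traits <- intersect(trait_directions()$trait, names(trial))
  if (!length(traits)) traits <- setdiff(
    names(trial), c("genotype", "location", "year", "block", "ME"))
  vc_rows <- list(); part_rows <- list(); fits <- list()
  for (tr in traits) {
    fit <- stage("varcomp", fit_random_model(trial, tr))
    fits[[tr]] <- fit
    lrt <- stage("varcomp", lrt_all_terms(fit, dist = a$lrt_dist))
    if (any(fit$varcomp == 0)) {
      note("boundary variance estimate(s) for ", tr, ": ",
           paste(names(fit$varcomp)[fit$varcomp == 0], collapse = ", "))
    }
    vc_rows[[tr]] <- data.frame(
      trait = tr, term = names(fit$varcomp),
      variance = unname(fit$varcomp),
      p_value = lrt$p_value[match(names(fit$varcomp), lrt$term)],
      stringsAsFactors = FALSE)
    ct <- variance_contributions(fit$varcomp, fit$J, fit$K, fit$total_reps)
    part_rows[[tr]] <- rbind(
      data.frame(trait = tr, partition = "phenotypic",
                 component = names(ct$phenotypic),
                 share_pct = unname(ct$phenotypic)),
      data.frame(trait = tr, partition = "genotype_mean",
                 component = names(ct$genotype_mean),
                 share_pct = unname(ct$genotype_mean)))
  }
  vc_tab <- do.call(rbind, vc_rows); rownames(vc_tab) <- NULL
  gen_par <- data.frame(
    trait = traits,
    sigma_p = unname(vapply(fits, `[[`, numeric(1), "sigma_p")),
    H2 = unname(vapply(fits, `[[`, numeric(1), "H2")),
    Ac = unname(vapply(fits, `[[`, numeric(1), "Ac")))
  emit(vc_tab, "variance_components.csv")
  emit(do.call(rbind, part_rows), "variance_partitions.csv")
  emit(gen_par, "genetic_parameters.csv")

  # -- per-ME selection ---------------------------------------------------
  mes <- sort(unique(asg$assignment$ME))
  selections <- list(); sel_paths <- list(); scen_rows <- list()
  for (me in mes) {
    res <- stage("selection", me_selection(
      trial, me, traits = traits, theta_y = a$theta_y, theta_s = a$theta_s,
      intensity = a$intensity))
    selections[[me]] <- res
    mps_long <- do.call(rbind, lapply(traits, function(tr) {
      data.frame(ME = me, trait = tr,
                 genotype = rownames(res$tables$rM),
                 mean = unname(res$tables$means[, tr]),
                 ecovalence = unname(res$tables$ecovalence[, tr]),
                 mps = unname(res$tables$rM[, tr]),
                 stringsAsFactors = FALSE)
    }))
    emit(mps_long, sprintf("mps_%s.csv", me))
    emit(res$selection, sprintf("mtmps_%s.csv", me))
    emit(rbind(cbind(kind = "means", res$differentials$means),
               cbind(kind = "stability", res$differentials$stability)),
         sprintf("differentials_%s.csv", me))
    for (tr in traits) {
      tb <- trait_mean_stability(trial, me, tr, theta_y = a$theta_y,
                                 theta_s = a$theta_s)
      sc <- weight_scenarios(stats::setNames(tb$r_y, tb$genotype),
                             stats::setNames(tb$r_w, tb$genotype))
      scen_rows[[paste(me, tr)]] <- cbind(ME = me, trait = tr, sc)
    }
  }
  scen <- do.call(rbind, scen_rows); rownames(scen) <- NULL
  emit(scen, "weight_scenarios.csv")

  membership <- cross_me_summary(lapply(selections, `[[`, "selection"))
  emit(membership, "cross_me_membership.csv")

  # -- summary ------------------------------------------------------------
  summary <- list(
    seed = config$seed,
    k = a$k,
    environments = asg$assignment$environment,
    me_assignment = stats::setNames(as.list(asg$assignment$ME),
                                    asg$assignment$environment),
    w_columns_before_qc = ncol(w$raw),
    w_columns_after_qc = ncol(w$W),
    kernel_trace = sum(diag(kern$K)),
    traits = traits,
    heritability = stats::setNames(as.list(gen_par$H2), gen_par$trait),
    selected = lapply(selections, function(s) {
      s$selection$genotype[s$selection$selected]
    }),
    fa_explained = lapply(selections, function(s) s$model$explained),
    config = list(theta_y = a$theta_y, theta_s = a$theta_s,
                  intensity = a$intensity, qc_sd = a$qc_sd,
                  etp_method = a$etp_method, lrt_dist = a$lrt_dist)
  )
  if (!is.null(simcfg)) {
    truth <- .me_label(simcfg$me_archetypes)
    est <- asg$assignment$ME[match(.loc_labels(simcfg$n_locations),
                                   asg$assignment$environment)]
    summary$delineation_ari <- mclust::adjustedRandIndex(truth, est)
    note("adjusted Rand vs planted archetypes: ",
         format(summary$delineation_ari))
  }
  .validate_summary(summary)
  sum_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  done <- c(done, sum_path)
  writeLines(log_lines, file.path(out_dir, "run.log"))

  bundle <- c(bundle, list(
    weather = weather, covariables = cov, w = w, kernel = kern,
    assignment = asg, typology = typ, trial = trial, fits = fits,
    genetic_parameters = gen_par, selections = selections,
    membership = membership, summary = summary, paths = done))
  invisible(bundle)
}

# summary schema: required key -> expected type, shipped as a JSON file so
# downstream consumers can rely on a stable contract
.validate_summary <- function(summary) {
  schema_path <- system.file("schema", "summary-schema.json",
                             package = "envmet")
  if (!nzchar(schema_path)) return(invisible(TRUE))  # not installed yet
  schema <- jsonlite::read_json(schema_path)
  missing <- setdiff(unlist(schema$required), names(summary))
  if (length(missing)) {
    stop("summary JSON violates schema; missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
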