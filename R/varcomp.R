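# ---- variance components, heritability, variance partitions -------------

# term registry: model term -> lme4 grouping factor and required columns
.vc_terms <- function() {
  data.frame(
    term = c("G", "M", "Y", "GM", "GY", "MY", "GMY", "REP"),
    group = c("genotype", "ME", "year", "genotype:ME", "genotype:year",
              "ME:year", "genotype:ME:year", "rep_id"),
    stringsAsFactors = FALSE
  )
}

.vc_formula <- function(trait, terms) {
  reg <- .vc_terms()
  gr <- reg$group[match(terms, reg$term)]
  stats::as.formula(paste(trait, "~", paste(sprintf("(1 | %s)", gr),
                                            collapse = " + ")))
}

#' Fit the crossed random-effects model by REML
#'
#' Fits, for one trait, the intercept-plus-random-terms model
#' `y = mu + G + M + Y + GM + GY + MY + GMY + REP(M:Y) + e`
#' where `G`, `M` and `Y` are genotype, mega-environment and year main
#' effects, the interactions are crossed, and the replicate effect `REP` is
#' the location x block combination nested within each ME x year.  Variance
#' components are estimated by restricted maximum likelihood (REML) and are
#' constrained non-negative; boundary estimates are reported as exact
#' zeros.
#'
#' @param data a `trial_data` frame (or any data frame with columns
#'   `genotype`, `ME`, `year`, `location`, `block` as required by `terms`,
#'   plus the trait column).
#' @param trait name of the trait column to analyse.
#' @param terms model terms to include (default all eight); the residual is
#'   always present.  Every included term must have at least 2 levels.
#' @return an object of class `varcomp_fit`: the named variance vector
#'   (`G, M, Y, GM, GY, MY, GMY, REP, residual` as applicable), the REML
#'   log-likelihood, convergence information, the design constants
#'   `J` (MEs), `K` (years) and `total_reps` (location x block x year
#'   combinations), and -- when the genotype terms are present --
#'   `sigma_p`, `H2` and `Ac` from [heritability()].
#' @seealso [lrt_random_effects()], [heritability()],
#'   [variance_contributions()]
#' @export
fit_random_model <- function(data, trait,
                             terms = c("G", "M", "Y", "GM", "GY", "MY",
                                       "GMY", "REP")) {
  stopifnot(is.data.frame(data))
  reg <- .vc_terms()
  bad <- setdiff(terms, reg$term)
  if (length(bad)) stop("unknown model term(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!trait %in% names(data)) {
    stop("trait '", trait, "' not found in data", call. = FALSE)
  }
  d <- as.data.frame(data)
  if (!is.numeric(d[[trait]])) stop("trait '", trait, "' is not numeric",
                                    call. = FALSE)

  need_cols <- unique(c(
    if (any(c("G", "GM", "GY", "GMY") %in% terms)) "genotype",
    if (any(c("M", "GM", "MY", "GMY") %in% terms)) "ME",
    if (any(c("Y", "GY", "MY", "GMY", "REP") %in% terms)) "year",
    if ("REP" %in% terms) c("location", "block")
  ))
  miss <- setdiff(need_cols, names(d))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  for (cc in intersect(c("genotype", "ME", "location", "block"), names(d))) {
    d[[cc]] <- factor(d[[cc]])
  }
  if ("year" %in% names(d)) d$year <- factor(d$year)
  if ("REP" %in% terms) {
    d$rep_id <- factor(paste(d$location, d$block, d$year, sep = ":"))
  }

  # confounding guard: each term's grouping factor needs >= 2 levels
  base_lev <- c(genotype = if ("genotype" %in% names(d)) nlevels(d$genotype) else 0,
                ME = if ("ME" %in% names(d)) nlevels(d$ME) else 0,
                year = if ("year" %in% names(d)) nlevels(d$year) else 0)
  for (tm in terms) {
    parts <- strsplit(reg$group[reg$term == tm], ":", fixed = TRUE)[[1]]
    if (tm == "REP") next
    if (any(base_lev[parts] < 2)) {
      stop("term '", tm, "' is confounded: factor(s) ",
           paste(parts[base_lev[parts] < 2], collapse = ", "),
           " have fewer than 2 levels", call. = FALSE)
    }
  }
  if ("REP" %in% terms && nlevels(d$rep_id) < 2) {
    stop("term 'REP' is confounded: fewer than 2 replicate combinations",
         call. = FALSE)
  }

  fml <- .vc_formula(trait, terms)
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.nobs.vs.nRE = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  conv <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs, fixed = TRUE))
  if (!conv) {
    stop("REML fit for trait '", trait, "' did not converge: ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }

  vcl <- lme4::VarCorr(fit)
  vr <- vapply(vcl, function(v) as.numeric(v[1, 1]), numeric(1))
  map <- stats::setNames(reg$term, reg$group)
  vc <- stats::setNames(rep(NA_real_, length(terms)), terms)
  vc[map[names(vr)]] <- unname(vr)
  vc <- c(vc, residual = attr(vcl, "sc")^2)

  J <- if ("ME" %in% names(d)) nlevels(d$ME) else NA_integer_
  K <- if ("year" %in% names(d)) nlevels(d$year) else NA_integer_
  total_reps <- if ("rep_id" %in% names(d)) nlevels(d$rep_id) else NA_integer_

  out <- list(trait = trait, terms = terms, varcomp = vc,
              logLik = as.numeric(stats::logLik(fit)),
              converged = conv, messages = msgs,
              J = J, K = K, total_reps = total_reps,
              fit = fit, data = d, formula = fml)
  if (all(c("G", "GM", "GY", "GMY") %in% terms) && !is.na(J) && !is.na(K) &&
      !is.na(total_reps)) {
    h <- heritability(vc, J = J, K = K, total_reps = total_reps)
    out <- c(out, h)
  }
  structure(out, class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, digits = 3, ...) {
  cat("REML variance components for", x$trait, "\n")
  print(round(x$varcomp, digits))
  if (!is.null(x$H2)) {
    cat(sprintf("sigma_P = %.*f  H2 = %.*f  Ac = %.*f  (J = %d, K = %d, reps = %d)\n",
                digits, x$sigma_p, digits, x$H2, digits, x$Ac,
                x$J, x$K, x$total_reps))
  }
  invisible(x)
}

#' Likelihood-ratio test for one random term
#'
#' Refits the model without the named term and computes
#' `LRT = 2 (logLik_full - logLik_reduced)` on the REML log-likelihoods
#' (the fixed part, an intercept, is identical in both models).  The
#' p-value uses a chi-square with 1 df by default (conservative at the
#' boundary) or the 50:50 mixture of chi-square(0) and chi-square(1).
#'
#' @param fit a converged `varcomp_fit` with the full model.
#' @param term the term to test (one of the fitted terms).
#' @param dist reference distribution, `"chisq1"` or `"mixture"`.
#' @return list with `term`, `statistic`, `p_value`, `dist`.
#' @export
lrt_random_effects <- function(fit, term, dist = c("chisq1", "mixture")) {
  stopifnot(inherits(fit, "varcomp_fit"))
  dist <- match.arg(dist)
  if (!fit$converged) stop("full model did not converge", call. = FALSE)
  if (!term %in% fit$terms) stop("term '", term, "' is not in the fitted model",
                                 call. = FALSE)
  reduced_terms <- setdiff(fit$terms, term)
  if (!length(reduced_terms)) {
    stop("cannot drop the only random term", call. = FALSE)
  }
  red <- tryCatch(
    fit_random_model(fit$data, fit$trait, terms = reduced_terms),
    error = function(e) e
  )
  if (inherits(red, "error")) {
    return(list(term = term, statistic = NA_real_, p_value = NA_real_,
                dist = dist, available = FALSE,
                reason = conditionMessage(red)))
  }
  stat <- max(0, 2 * (fit$logLik - red$logLik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (dist == "mixture") p <- if (stat == 0) 1 else 0.5 * p
  list(term = term, statistic = stat, p_value = min(1, p), dist = dist,
       available = TRUE)
}

#' Likelihood-ratio tests for every random term
#'
#' @param fit a `varcomp_fit`.
#' @param dist passed to [lrt_random_effects()].
#' @return data frame with one row per term: `term`, `statistic`, `p_value`.
#' @export
lrt_all_terms <- function(fit, dist = c("chisq1", "mixture")) {
  dist <- match.arg(dist)
  res <- lapply(fit$terms, function(tm) lrt_random_effects(fit, tm, dist))
  data.frame(term = vapply(res, `[[`, character(1), "term"),
             statistic = vapply(res, `[[`, numeric(1), "statistic"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             stringsAsFactors = FALSE)
}

#' Broad-sense heritability on a genotype-mean basis
#'
#' Computes the variance of a genotype mean
#' \deqn{\sigma^2_P = \sigma^2_G + \sigma^2_{GY}/K + \sigma^2_{GM}/J +
#'   \sigma^2_{GMY}/(JK) + \sigma^2_\epsilon / \sum_k N}
#' with `J` mega-environments, `K` years and `total_reps` the total number
#' of location x block replicate combinations summed over years, then
#' `H2 = sigma2_G / sigma2_P` and the selection accuracy `Ac = sqrt(H2)`.
#'
#' @param vc named numeric vector of variances; `G`, `GM`, `GY`, `GMY` and
#'   `residual` are used (missing entries count as 0).
#' @param J number of mega-environments.
#' @param K number of years.
#' @param total_reps total location x block x year combinations.
#' @return list with `sigma_p`, `H2` and `Ac`.
#' @export
heritability <- function(vc, J, K, total_reps) {
  for (nm in c("J", "K", "total_reps")) {
    v <- get(nm)
    .assert_scalar_number(v, nm)
    if (v < 1) stop("'", nm, "' must be >= 1", call. = FALSE)
  }
  if (any(vc < 0, na.rm = TRUE)) stop("variances must be >= 0", call. = FALSE)
  g <- function(nm) if (nm %in% names(vc) && is.finite(vc[[nm]])) vc[[nm]] else 0
  sigma_p <- g("G") + g("GY") / K + g("GM") / J + g("GMY") / (J * K) +
    g("residual") / total_reps
  if (sigma_p == 0) {
    warning("sigma2_P is zero; defining H2 = 0")
    return(list(sigma_p = 0, H2 = 0, Ac = 0))
  }
  h2 <- g("G") / sigma_p
  list(sigma_p = sigma_p, H2 = h2, Ac = sqrt(h2))
}

#' Variance partitions
#'
#' Two normalised percentage partitions: (a) each model term's share of the
#' total phenotypic variance (the sum of all fitted components), and
#' (b) each component of the variance of a genotype mean as a share of
#' `sigma2_P`.  Both sum to 100.
#'
#' @param vc named variance vector (as in a `varcomp_fit`).
#' @param J,K,total_reps design constants for the genotype-mean partition.
#' @return list of two named vectors, `phenotypic` and `genotype_mean`,
#'   in percent.
#' @export
variance_contributions <- function(vc, J, K, total_reps) {
  vc <- vc[!is.na(vc)]
  tot <- sum(vc)
  phen <- if (tot > 0) 100 * vc / tot else vc * 0
  g <- function(nm) if (nm %in% names(vc)) vc[[nm]] else 0
  parts <- c(G = g("G"), GY = g("GY") / K, GM = g("GM") / J,
             GMY = g("GMY") / (J * K), residual = g("residual") / total_reps)
  ps <- sum(parts)
  gm <- if (ps > 0) 100 * parts / ps else parts * 0
  list(phenotypic = phen, genotype_mean = gm)
}
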