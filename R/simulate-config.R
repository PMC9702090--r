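# ---- simulation configuration -------------------------------------------

# Default per-trait variance components for the crossed random-effects model
# y = mu + G + M + Y + GM + GY + MY + GMY + REP(M:Y) + e.  Values are REML
# estimates from a published 26-hybrid, 10-location, 2-year maize panel, so
# simulated trials carry a realistic signal-to-noise structure per trait.
.default_varcomp <- function() {
  terms <- c("G", "M", "Y", "GM", "GY", "MY", "GMY", "REP", "residual")
  tab <- rbind(
    GY  = c(0.038,   0.000,   0.000,  0.059,  0.000,  0.453,  0.355,   1.521,   1.185),
    GMC = c(1.357,   0.000,   9.488,  0.000,  0.000,  2.738,  1.011,   4.033,   9.136),
    PH  = c(199.780, 96.522,  31.061, 0.000,  4.833,  11.210, 128.617, 108.140, 274.329),
    EH  = c(50.028,  0.000,   27.351, 0.000,  4.622,  30.248, 59.987,  98.436,  126.749),
    EL  = c(0.211,   0.053,   0.083,  0.219,  0.000,  0.000,  0.311,   0.657,   1.337),
    ER  = c(0.859,   0.000,   0.016,  0.078,  0.000,  0.000,  0.484,   0.138,   1.194),
    BTL = c(0.050,   0.000,   0.000,  0.048,  0.000,  0.000,  0.353,   0.135,   0.472),
    GWE = c(39.221,  104.484, 55.866, 26.481, 10.899, 0.000,  77.715,  300.744, 464.349),
    HSW = c(1.770,   0.000,   0.000,  0.250,  0.000,  0.000,  0.852,   12.844,  9.817)
  )
  colnames(tab) <- terms
  lapply(stats::setNames(rownames(tab), rownames(tab)),
         function(tr) tab[tr, ])
}

# Default grand means per trait: grain yield in t/ha near the 10-12 t/ha
# range typical of high-input summer maize; heights centred on the hybrid
# panel's catalogue range; remaining traits at field-typical magnitudes.
.default_grand_means <- function() {
  c(GY = 10.5, GMC = 25, PH = 260, EH = 104, EL = 17.5,
    ER = 15.4, BTL = 1.2, GWE = 180, HSW = 32)
}

# Four weather archetypes spanning the climatic contrasts the delineation is
# meant to recover: (1) warm and wet; (2) warm with high downward longwave
# flux; (3) dry with a high vapour-pressure deficit and wide diurnal range;
# (4) cool.  One row per archetype; offsets act on every day of the season.
.default_weather_archetypes <- function() {
  data.frame(
    archetype  = 1:4,
    lat        = c(31.7, 33.5, 37.0, 36.8),
    lon        = c(112.2, 116.3, 114.5, 117.0),
    elevation  = c(75, 40, 60, 120),
    tmean_base = c(24.0, 23.0, 22.0, 19.5),
    tmean_amp  = c(8.5, 9.0, 10.0, 9.5),
    trange     = c(8.0, 9.0, 12.0, 9.0),
    dew_depression = c(2.0, 3.0, 7.0, 4.0),
    clearness  = c(0.45, 0.50, 0.60, 0.50),
    precip_rate = c(5.5, 3.2, 1.2, 2.2),
    wind       = c(1.5, 2.0, 2.5, 2.2),
    dtirf      = c(34, 36, 30, 28)
  )
}

#' Build a simulation configuration
#'
#' Assembles and validates all parameters of the synthetic multi-environment
#' trial: the trial dimensions, the mapping of locations onto weather
#' archetypes (which in turn defines the true mega-environment labels), the
#' variance component of every random term per trait, the grand means, and
#' the per-archetype weather parameters.
#'
#' Defaults emulate the design of a temperate summer-maize trial network:
#' 26 hybrids, 10 locations falling into 4 climatic archetypes (of sizes
#' 1, 3, 4 and 2), 2 years, 3 complete blocks, and nine agronomic traits
#' with realistic variance structures.
#'
#' @param n_genotypes,n_locations,n_years,n_blocks trial dimensions.
#' @param me_archetypes integer vector of length `n_locations` assigning each
#'   location to a weather archetype (values index rows of
#'   `weather_archetypes`). The default splits 10 locations as 1/3/4/2.
#' @param traits character vector of trait names to simulate.
#' @param variance_components named list (one element per trait) of named
#'   vectors with the nine variances `G, M, Y, GM, GY, MY, GMY, REP,
#'   residual`.
#' @param grand_means named numeric vector of per-trait grand means.
#' @param weather_archetypes data frame of per-archetype weather parameters
#'   (see the default for the expected columns).
#' @param weather_years integer vector of calendar years for the long-term
#'   weather archive (default 2001-2020).
#' @param trial_years integer vector of the `n_years` trial years.
#' @param noise_scale non-negative multiplier on all daily weather noise;
#'   `0` makes the weather purely deterministic given the archetype.
#' @param effect_rng distribution used to draw random effects: a function
#'   `f(n, sd)`; defaults to i.i.d. normal draws. Exposed as a hook for
#'   robustness experiments.
#' @param rng_seed integer seed fixing all simulated output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 26, n_locations = 10, n_years = 2,
                       n_blocks = 3,
                       me_archetypes = NULL,
                       traits = trait_directions()$trait,
                       variance_components = NULL,
                       grand_means = NULL,
                       weather_archetypes = NULL,
                       weather_years = 2001:2020,
                       trial_years = NULL,
                       noise_scale = 1,
                       effect_rng = NULL,
                       rng_seed = 20221114L) {
  for (nm in c("n_genotypes", "n_locations", "n_years", "n_blocks")) {
    v <- get(nm)
    .assert_scalar_number(v, nm)
    if (v < 1 || v != round(v)) stop("'", nm, "' must be a positive integer",
                                     call. = FALSE)
  }
  if (n_locations < 1) stop("at least one location is required", call. = FALSE)
  if (n_blocks < 2) stop("'n_blocks' must be at least 2", call. = FALSE)
  if (!length(traits)) stop("trait list must be non-empty", call. = FALSE)

  if (is.null(weather_archetypes)) {
    weather_archetypes <- .default_weather_archetypes()
  }
  if (is.null(me_archetypes)) {
    # default 10-location split 1/3/4/2; otherwise spread archetypes evenly
    me_archetypes <- if (n_locations == 10) {
      c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 4L)
    } else {
      rep_len(seq_len(nrow(weather_archetypes)), n_locations)
    }
  }
  if (length(me_archetypes) != n_locations) {
    stop("'me_archetypes' must assign exactly one archetype per location",
         call. = FALSE)
  }
  if (!all(me_archetypes %in% weather_archetypes$archetype)) {
    stop("'me_archetypes' refers to archetypes missing from ",
         "'weather_archetypes'", call. = FALSE)
  }

  defaults <- .default_varcomp()
  if (is.null(variance_components)) {
    unknown <- setdiff(traits, names(defaults))
    if (length(unknown)) {
      stop("no default variance components for trait(s): ",
           paste(unknown, collapse = ", "),
           "; supply 'variance_components'", call. = FALSE)
    }
    variance_components <- defaults[traits]
  }
  terms <- c("G", "M", "Y", "GM", "GY", "MY", "GMY", "REP", "residual")
  for (tr in traits) {
    vc <- variance_components[[tr]]
    if (is.null(vc) || !all(terms %in% names(vc))) {
      stop("variance components for trait '", tr, "' must name all of: ",
           paste(terms, collapse = ", "), call. = FALSE)
    }
    bad <- names(vc)[vc < 0]
    if (length(bad)) {
      stop("negative variance for term(s) ", paste(bad, collapse = ", "),
           " in trait '", tr, "'", call. = FALSE)
    }
  }
  if (is.null(grand_means)) grand_means <- .default_grand_means()[traits]
  if (!all(traits %in% names(grand_means))) {
    stop("'grand_means' must name every trait", call. = FALSE)
  }
  if (is.null(trial_years)) {
    trial_years <- seq(to = max(weather_years), length.out = n_years)
  }
  if (length(trial_years) != n_years) {
    stop("'trial_years' must have length n_years", call. = FALSE)
  }
  .assert_scalar_number(noise_scale, "noise_scale")
  if (noise_scale < 0) stop("'noise_scale' must be >= 0", call. = FALSE)
  .assert_scalar_number(rng_seed, "rng_seed")
  if (is.null(effect_rng)) effect_rng <- function(n, sd) stats::rnorm(n, 0, sd)

  structure(list(
    n_genotypes = as.integer(n_genotypes),
    n_locations = as.integer(n_locations),
    n_years = as.integer(n_years),
    n_blocks = as.integer(n_blocks),
    me_archetypes = as.integer(me_archetypes),
    traits = traits,
    variance_components = variance_components[traits],
    grand_means = grand_means[traits],
    weather_archetypes = weather_archetypes,
    weather_years = as.integer(weather_years),
    trial_years = as.integer(trial_years),
    noise_scale = noise_scale,
    effect_rng = effect_rng,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d genotypes x %d locations x %d years x %d blocks\n",
              x$n_genotypes, x$n_locations, x$n_years, x$n_blocks))
  cat("  archetype map:", paste(x$me_archetypes, collapse = " "), "\n")
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  cat("  seed:", x$rng_seed, "\n")
  invisible(x)
}

# canonical label makers shared by the generator and the readers
.geno_labels <- function(n) sprintf("G%02d", seq_len(n))
.loc_labels <- function(n) sprintf("L%02d", seq_len(n))
.me_label <- function(archetype) paste0("ME", archetype)
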