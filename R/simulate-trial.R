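# ---- phenotype simulation -----------------------------------------------

#' Simulate plot-level phenotypes for a multi-environment trial
#'
#' Draws one record per genotype x location x year x block from the crossed
#' random-effects model
#' \deqn{y_{ijkn} = \mu + G_i + M_j + Y_k + GM_{ij} + GY_{ik} + MY_{jk} +
#'   GMY_{ijk} + REP_{n(j:k)} + \epsilon_{ijkn}}
#' where the mega-environment (ME) of a location is implied by its weather
#' archetype and the replicate effect is indexed by the location x block
#' combination within each ME x year.  Every random term is drawn
#' independently with the variance configured for the trait.
#'
#' @param config a [sim_config()] object.
#' @return a data frame of class `trial_data` with columns `genotype`,
#'   `location`, `ME`, `year`, `block` and one numeric column per trait.
#'   The drawn effect vectors are attached as attribute `"effects"` (a list
#'   per trait) so recovery checks can compare estimates against the
#'   realised draws.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_locations < 1) stop("zero locations: nothing to simulate",
                                   call. = FALSE)

  geno <- .geno_labels(config$n_genotypes)
  loc <- .loc_labels(config$n_locations)
  yrs <- config$trial_years
  blk <- sprintf("B%d", seq_len(config$n_blocks))
  me <- .me_label(config$me_archetypes)
  names(me) <- loc

  grid <- expand.grid(block = blk, year = yrs, location = loc,
                      genotype = geno, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "location", "year", "block")]
  grid$ME <- unname(me[grid$location])

  mes <- sort(unique(me))
  lev <- list(
    G = geno,
    M = mes,
    Y = as.character(yrs),
    GM = as.vector(outer(geno, mes, paste, sep = ":")),
    GY = as.vector(outer(geno, yrs, paste, sep = ":")),
    MY = as.vector(outer(mes, yrs, paste, sep = ":")),
    GMY = as.vector(outer(geno, as.vector(outer(mes, yrs, paste, sep = ":")),
                          paste, sep = ":")),
    REP = as.vector(outer(as.vector(outer(loc, blk, paste, sep = ":")),
                          yrs, paste, sep = ":"))
  )
  idx <- list(
    G = grid$genotype,
    M = grid$ME,
    Y = as.character(grid$year),
    GM = paste(grid$genotype, grid$ME, sep = ":"),
    GY = paste(grid$genotype, grid$year, sep = ":"),
    MY = paste(grid$ME, grid$year, sep = ":"),
    GMY = paste(grid$genotype, grid$ME, grid$year, sep = ":"),
    REP = paste(grid$location, grid$block, grid$year, sep = ":")
  )

  effects <- vector("list", length(config$traits))
  names(effects) <- config$traits

  .with_seed(.child_seed(config$rng_seed, "trial"), {
    for (tr in config$traits) {
      vc <- config$variance_components[[tr]]
      draws <- lapply(names(lev), function(term) {
        stats::setNames(config$effect_rng(length(lev[[term]]),
                                          sqrt(vc[[term]])),
                        lev[[term]])
      })
      names(draws) <- names(lev)
      y <- rep(config$grand_means[[tr]], nrow(grid))
      for (term in names(lev)) y <- y + unname(draws[[term]][idx[[term]]])
      y <- y + config$effect_rng(nrow(grid), sqrt(vc[["residual"]]))
      grid[[tr]] <- y
      effects[[tr]] <- draws
    }
  })

  structure(grid, effects = effects,
            class = c("trial_data", "data.frame"))
}
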