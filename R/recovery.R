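# ---- simulation-based recovery harnesses --------------------------------

#' REML parameter-recovery study
#'
#' Simulates `n_sim` complete trials from a configuration, refits the full
#' crossed random-effects model on each, and summarises how well the REML
#' estimates recover the generating variance components.  For components
#' generated at zero the informative summary is the boundary rate (the
#' share of replicates estimated exactly 0): a non-negatively constrained
#' estimator cannot average to zero, and terms with very few levels (e.g. a
#' two-level year factor) carry a positive truncation bias that is a
#' property of constrained REML rather than of any particular
#' implementation.
#'
#' @param n_sim number of simulated trials.
#' @param trait trait to simulate and refit.
#' @param seed base seed; replicate `i` runs at `seed + i`.
#' @param config_args further arguments to [sim_config()].
#' @return list with `generating` (the true variances), `mean_estimate`,
#'   `rel_error` (mean estimate / generating - 1, `NA` for zero
#'   components), `boundary_rate` and the full `estimates` matrix
#'   (`n_sim` x components).
#' @export
varcomp_recovery <- function(n_sim = 200, trait = "EH", seed = 1,
                             config_args = list()) {
  est <- NULL
  gen <- NULL
  for (i in seq_len(n_sim)) {
    cfg <- do.call(sim_config, c(list(traits = trait,
                                      rng_seed = seed + i), config_args))
    if (is.null(gen)) gen <- cfg$variance_components[[trait]]
    fit <- fit_random_model(simulate_trial(cfg), trait)
    ord <- c(names(gen)[names(gen) != "residual"], "residual")
    if (is.null(est)) {
      est <- matrix(NA_real_, n_sim, length(ord),
                    dimnames = list(NULL, ord))
    }
    est[i, ] <- fit$varcomp[ord]
  }
  gen <- gen[colnames(est)]
  me <- colMeans(est)
  list(generating = gen,
       mean_estimate = me,
       rel_error = ifelse(gen > 0, me / gen - 1, NA_real_),
       boundary_rate = colMeans(est == 0),
       estimates = est)
}

#' Factor-count recovery study
#'
#' Simulates genotype x trait tables from a known 2-factor latent model
#' (two blocks of traits, within-block loading `load`) and reports how
#' often the eigenvalue-above-one rule retains exactly two factors.
#'
#' @param n_sim number of simulated tables.
#' @param q genotypes per table.
#' @param block_sizes traits loading on each of the two factors.
#' @param load common loading on the latent factor.
#' @param seed base seed.
#' @return list with `rate` (share of replicates retaining 2 factors) and
#'   `counts` (table of retained-factor counts).
#' @export
factor_recovery <- function(n_sim = 200, q = 100, block_sizes = c(3, 3),
                            load = 0.85, seed = 1) {
  counts <- integer(n_sim)
  .with_seed(seed, {
    for (i in seq_len(n_sim)) {
      f <- matrix(stats::rnorm(q * 2), q)
      cols <- lapply(seq_along(block_sizes), function(b) {
        vapply(seq_len(block_sizes[b]), function(j) {
          load * f[, b] + sqrt(1 - load^2) * stats::rnorm(q)
        }, numeric(q))
      })
      m <- do.call(cbind, cols)
      colnames(m) <- paste0("t", seq_len(ncol(m)))
      counts[i] <- factor_analysis(m)$n_factors
    }
  })
  list(rate = mean(counts == 2), counts = table(counts))
}
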