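test_that("REML matches the balanced one-way ANOVA closed form", {
  set.seed(13)
  for (rep_case in 1:3) {
    g <- 12; r <- 5
    d <- data.frame(genotype = rep(sprintf("g%02d", 1:g), each = r))
    d$y <- 3 + rnorm(g, sd = 2)[as.integer(factor(d$genotype))] + rnorm(g * r)
    fit <- fit_random_model(d, "y", terms = "G")
    oracle <- oracle_oneway(d$y, d$genotype)
    expect_equal(unname(fit$varcomp["G"]), unname(oracle["G"]),
                 tolerance = 1e-6)
    expect_equal(unname(fit$varcomp["residual"]), unname(oracle["residual"]),
                 tolerance = 1e-6)
  }
})

test_that("pure-noise data drives every non-residual component to zero", {
  vc0 <- c(G = 0, M = 0, Y = 0, GM = 0, GY = 0, MY = 0, GMY = 0, REP = 0,
           residual = 1)
  cfg <- small_config(seed = 3, traits = "GY",
                      variance_components = list(GY = vc0),
                      grand_means = c(GY = 10))
  fit <- fit_random_model(simulate_trial(cfg), "GY")
  non_res <- fit$varcomp[setdiff(names(fit$varcomp), "residual")]
  # most components sit exactly on the boundary; the rest are negligible
  # relative to the residual (sampling noise of a finite layout)
  expect_gte(sum(non_res == 0), 5)
  expect_true(all(non_res < 0.05))
  expect_equal(unname(fit$varcomp["residual"]), 1, tolerance = 0.2)
})

test_that("confounded designs are refused with the term named", {
  tr <- simulate_trial(small_config())
  one_year <- tr[tr$year == max(tr$year), ]
  expect_error(fit_random_model(one_year, "GY"), "'Y' is confounded")
  expect_error(fit_random_model(tr, "nope"), "not found")
})

test_that("likelihood-ratio tests respect nesting and calibrate to signal", {
  tr <- simulate_trial(small_config(seed = 10))
  fit <- fit_random_model(tr, "EH")
  for (term in c("G", "MY", "GMY")) {
    lrt <- lrt_random_effects(fit, term)
    red <- fit_random_model(tr, "EH", terms = setdiff(fit$terms, term))
    expect_gte(fit$logLik, red$logLik - 1e-6)   # nesting, up to optimiser tol
    expect_gte(lrt$statistic, 0)
    expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  }
  # mixture halves the chi-square(1) tail p for positive statistics
  l1 <- lrt_random_effects(fit, "G", dist = "chisq1")
  l2 <- lrt_random_effects(fit, "G", dist = "mixture")
  if (l1$statistic > 0) expect_equal(l2$p_value, l1$p_value / 2)
})

test_that("LRT has power for strong terms and stays flat for null terms", {
  base <- c(G = 0.2, M = 0.1, Y = 0.1, GM = 25, GY = 0, MY = 0.1,
            GMY = 0.2, REP = 0.2, residual = 1)
  hits_strong <- 0; p_null <- numeric(30)
  for (i in 1:30) {
    cfg <- small_config(seed = 100 + i, traits = "GY",
                        variance_components = list(GY = base),
                        grand_means = c(GY = 10))
    fit <- fit_random_model(simulate_trial(cfg), "GY")
    if (lrt_random_effects(fit, "GM")$p_value < 0.01) {
      hits_strong <- hits_strong + 1
    }
    p_null[i] <- lrt_random_effects(fit, "GY")$p_value
  }
  expect_gte(hits_strong / 30, 0.95)          # signal >> noise is detected
  expect_gte(mean(p_null > 0.1), 0.8)         # null term rarely flagged
})

test_that("heritability follows the genotype-mean variance formula", {
  vc <- c(G = 0.038, GM = 0.059, GY = 0, GMY = 0.355, residual = 1.185)
  h <- heritability(vc, J = 4, K = 2, total_reps = 60)
  expect_equal(h$sigma_p, 0.038 + 0.059 / 4 + 0.355 / 8 + 1.185 / 60)
  expect_equal(h$H2, 0.325, tolerance = 1e-3)
  expect_equal(h$Ac, sqrt(h$H2))
  expect_equal(heritability(c(G = 0, residual = 1), 4, 2, 60)$H2, 0)
  expect_error(heritability(c(G = -1, residual = 1), 4, 2, 60), ">= 0")
})

test_that("H2 is monotone in the variance components", {
  vc <- c(G = 2, GM = 1, GY = 1, GMY = 1, residual = 4)
  h0 <- heritability(vc, 4, 2, 60)$H2
  up <- function(nm, eps = 1e-3) {
    v <- vc; v[nm] <- v[nm] + eps
    heritability(v, 4, 2, 60)$H2
  }
  expect_gt(up("G"), h0)
  for (nm in c("GM", "GY", "GMY", "residual")) expect_lt(up(nm), h0)
})

test_that("variance partitions are normalised percentages", {
  vc <- c(G = 0.038, M = 0, Y = 0, GM = 0.059, GY = 0, MY = 0.453,
          GMY = 0.355, REP = 1.521, residual = 1.185)
  ct <- variance_contributions(vc, 4, 2, 60)
  expect_equal(sum(ct$phenotypic), 100, tolerance = 1e-9)
  expect_equal(sum(ct$genotype_mean), 100, tolerance = 1e-9)
  expect_equal(unname(ct$genotype_mean["G"]), 100 * 0.038 / 0.116875,
               tolerance = 1e-9)
  only_res <- variance_contributions(c(G = 0, residual = 2), 4, 2, 60)
  expect_equal(unname(only_res$phenotypic["residual"]), 100)
})
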