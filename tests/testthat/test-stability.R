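test_that("genotype-year means pool plots within the mega-environment", {
  d <- expand.grid(genotype = c("A", "B", "C"), year = c(2019, 2020),
                   block = 1:2, stringsAsFactors = FALSE)
  d$ME <- "ME1"; d$location <- "L01"
  set.seed(2); d$y <- rnorm(nrow(d), 10)
  m <- genotype_year_means(d, "ME1", "y")
  for (g in c("A", "B", "C")) {
    for (yr in c("2019", "2020")) {
      expect_equal(m[g, yr],
                   mean(d$y[d$genotype == g & d$year == as.integer(yr)]))
    }
  }
  # row permutation changes nothing
  m2 <- genotype_year_means(d[sample(nrow(d)), ], "ME1", "y")
  expect_identical(m, m2)
  # a genotype missing a year is excluded with a warning
  d2 <- d[!(d$genotype == "C" & d$year == 2020), ]
  expect_warning(m3 <- genotype_year_means(d2, "ME1", "y"), "C")
  expect_setequal(rownames(m3), c("A", "B"))
})

test_that("ecovalence matches the definition and its algebraic identities", {
  # purely additive response: every genotype perfectly stable
  a <- outer(c(1, 3, 7), c(0, 2), "+")
  expect_equal(unname(ecovalence(a)), c(0, 0, 0))
  # hand-computed 2x2 crossover
  expect_equal(unname(ecovalence(matrix(c(1, 0, 0, 1), 2))), c(0.5, 0.5))
  # brute-force oracle on random 6x2 matrices + interaction-SS identity
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("g", 1:6), NULL))
    w <- ecovalence(m)
    expect_equal(w, oracle_ecovalence(m), tolerance = 1e-10)
    res <- m - outer(rowMeans(m), colMeans(m), "+") + mean(m)
    expect_equal(sum(w), sum(res^2), tolerance = 1e-10)
    expect_true(all(w >= 0))
  }
  expect_error(ecovalence(matrix(1:6, ncol = 1)), "single year")
  expect_error(ecovalence(matrix(1:2, nrow = 1)), "2 genotypes")
})

test_that("rescaling maps extremes to 0/100 along the desired direction", {
  x <- c(2, 5, 8)
  up <- rescale_index(x, "increase")
  dn <- rescale_index(x, "decrease")
  expect_equal(up, c(0, 50, 100))
  expect_equal(dn, c(100, 50, 0))
  expect_equal(dn[which.min(x)], 100)      # best value when lower is better
  expect_true(all(diff(up[order(x)]) > 0))
  expect_warning(flat <- rescale_index(c(4, 4), "increase"), "degenerate")
  expect_equal(flat, c(50, 50))
  # idempotent on already-rescaled extremes
  expect_equal(rescale_index(up, "increase"), up)
})

test_that("MPS is the weighted mean of its two components", {
  expect_equal(mps(c(80), c(50), 70, 30), 71)
  expect_equal(mps(c(10, 90), c(40, 60), 100, 0), c(10, 90))
  expect_equal(mps(c(33, 33), c(33, 33), 7, 13), c(33, 33))
  expect_error(mps(1:3, 1:2), "lengths differ")
  expect_error(mps(1, 1, 0, 0), "positive sum")
  # monotone in each argument
  expect_gt(mps(81, 50), mps(80, 50))
  expect_gt(mps(80, 51), mps(80, 50))
})

test_that("weight scenarios cover the 21-step grid with rank limits", {
  set.seed(1)
  r_y <- setNames(runif(8, 0, 100), paste0("g", 1:8))
  r_w <- setNames(runif(8, 0, 100), paste0("g", 1:8))
  sc <- weight_scenarios(r_y, r_w)
  expect_equal(length(unique(sc$scenario)), 21)
  s100 <- sc[sc$scenario == "100/0", ]
  expect_equal(s100$rank, unname(rank(-r_y)))
  s0 <- sc[sc$scenario == "0/100", ]
  expect_equal(s0$rank, unname(rank(-r_w)))
  expect_error(weight_scenarios(r_y, r_w, ratios = matrix(numeric(0), 0, 2)),
               "non-empty")
})

test_that("a planted zero-interaction genotype is the most stable", {
  set.seed(44)
  hits <- 0; n_sim <- 200
  for (i in 1:n_sim) {
    # 11 noisy genotypes + 1 perfectly additive one over 8 years; the
    # interaction noise is moderate relative to the main effects
    g <- rnorm(12, 0, 2); yr <- rnorm(8, 0, 1)
    m <- outer(g, yr, "+") + rbind(matrix(rnorm(88, 0, 0.8), 11), 0)
    rownames(m) <- paste0("g", 1:12)
    if (which.min(ecovalence(m)) == 12) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("the per-trait mean/stability table is internally consistent", {
  tr <- simulate_trial(small_config(seed = 6))
  tb <- trait_mean_stability(tr, "ME1", "GY")
  expect_true(all(tb$mps >= 0 & tb$mps <= 100))
  expect_true(all(tb$r_y >= 0 & tb$r_y <= 100))
  expect_true(all(tb$r_w >= 0 & tb$r_w <= 100))
  expect_equal(sort(tb$rank), seq_len(nrow(tb)))
  expect_equal(tb$mps, mps(tb$r_y, tb$r_w, 70, 30))
  # lower values desired for GMC: lowest mean earns r_y = 100
  tb2 <- trait_mean_stability(tr, "ME1", "GMC")
  expect_equal(tb2$r_y[which.min(tb2$mean)], 100)
})
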