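# build an MPS-like table from a known latent structure: `blocks` lists the
# traits loading on each latent factor
latent_table <- function(q, blocks, load = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- matrix(rnorm(q * length(blocks)), q)
  cols <- list()
  for (b in seq_along(blocks)) {
    for (tr in blocks[[b]]) {
      cols[[tr]] <- load * f[, b] + sqrt(1 - load^2) * rnorm(q)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("G%02d", seq_len(q))
  m
}

test_that("two independent trait blocks yield two clean rotated factors", {
  m <- latent_table(80, list(c("a1", "a2", "a3"), c("b1", "b2", "b3")),
                    load = sqrt(0.9), seed = 15)
  fm <- factor_analysis(m)
  expect_equal(fm$n_factors, 2)
  A <- abs(fm$loadings)
  f_a <- which.max(A["a1", ]); f_b <- which.max(A["b1", ])
  expect_false(f_a == f_b)
  expect_true(all(A[c("a1", "a2", "a3"), f_a] >= 0.7))
  expect_true(all(A[c("b1", "b2", "b3"), f_b] >= 0.7))
  # eigenvalue > 1 retention implies each factor explains > 1/p
  expect_true(all(fm$eigenvalues[seq_len(fm$n_factors)] / ncol(m) > 1 / ncol(m)))
  # communalities bounded by 1
  expect_true(all(fm$communalities <= 1 + 1e-9))
})

test_that("factor scores reproduce the scoring equation independently", {
  set.seed(23)
  for (i in 1:5) {
    m <- matrix(runif(15, 0, 100), 5, 3,
                dimnames = list(paste0("g", 1:5), paste0("t", 1:3)))
    fm <- factor_analysis(m)
    expect_equal(fm$scores, oracle_factor_scores(m, fm$loadings),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("duplicated genotypes get identical scores and constant traits drop", {
  m <- latent_table(20, list(c("x", "y"), c("z", "w")), seed = 3)
  m2 <- rbind(m, m[1, , drop = FALSE])
  fm <- factor_analysis(m2)
  expect_equal(fm$scores[21, ], fm$scores[1, ], ignore_attr = TRUE)
  m3 <- cbind(m, flat = 50)
  expect_warning(fm3 <- factor_analysis(m3), "constant")
  expect_false("flat" %in% rownames(fm3$loadings))
  expect_error(factor_analysis(m[, 1, drop = FALSE]), "at least 2")
})

test_that("the all-100 genotype coincides with the ideotype", {
  m <- latent_table(12, list(c("t1", "t2"), c("t3", "t4")), seed = 9)
  m <- 50 + 10 * m
  m["G01", ] <- 100
  fm <- factor_analysis(m)
  d <- mtmps(fm)
  expect_equal(unname(d["G01"]), 0, tolerance = 1e-10)
  expect_true(all(d[-1] > 0))
})

test_that("single-factor MTMPS reduces to a 1-D distance", {
  set.seed(5)
  f <- rnorm(15)
  m <- cbind(t1 = 0.95 * f + 0.1 * rnorm(15), t2 = 0.95 * f + 0.1 * rnorm(15))
  rownames(m) <- sprintf("G%02d", 1:15)
  fm <- factor_analysis(m)
  expect_equal(fm$n_factors, 1)
  d <- mtmps(fm)
  expect_equal(unname(d),
               unname(abs(fm$scores[, 1] - fm$ideotype_scores[1])))
})

test_that("MTMPS ranking is invariant to a common positive rescaling", {
  # scaling the table and the ideotype by the same constant (a pure change
  # of units) must leave the ranking unchanged
  m <- 50 + 10 * latent_table(30, list(c("t1", "t2", "t3"), c("t4", "t5")),
                              seed = 77)
  r1 <- rank(mtmps(factor_analysis(m, ideotype = 100)))
  r2 <- rank(mtmps(factor_analysis(m * 3.7, ideotype = 370)))
  expect_equal(r1, r2)
})

test_that("selection keeps the argmin-MTMPS subset at the stated intensity", {
  set.seed(12)
  d <- setNames(runif(26, 0.5, 4), sprintf("G%02d", 1:26))
  sel <- select_genotypes(d, intensity = 0.23)
  expect_equal(sum(sel$selected), 6)            # 26 genotypes at ~23%
  expect_setequal(sel$genotype[sel$selected],
                  names(sort(d))[1:6])          # exhaustive argmin check
  expect_equal(sort(sel$rank), 1:26)
  all_sel <- select_genotypes(d, intensity = 1)
  expect_true(all(all_sel$selected))
  expect_error(select_genotypes(d[1:3], intensity = 0.1), "zero selections")
  expect_error(select_genotypes(d, intensity = 0), "intensity")
})

test_that("selection differentials follow their definition and flags", {
  means <- cbind(GY = c(11, 9, 10), GMC = c(20, 30, 25))
  rownames(means) <- c("A", "B", "C")
  wi <- cbind(GY = c(0.1, 0.4, 0.4), GMC = c(0.2, 0.1, 0.3))
  rownames(wi) <- c("A", "B", "C")
  ds <- selection_differentials(means, wi, selected = "A")
  expect_equal(ds$means$ds_pct[ds$means$trait == "GY"], 10)  # (11-10)/10
  expect_true(ds$means$desired[ds$means$trait == "GY"])      # higher GY good
  expect_true(ds$means$desired[ds$means$trait == "GMC"])     # 20 < 25
  expect_true(ds$stability$desired[ds$stability$trait == "GY"])
  # selecting everyone changes nothing
  ds0 <- selection_differentials(means, wi, selected = c("A", "B", "C"))
  expect_equal(ds0$means$ds_pct, c(0, 0))
  # zero population mean flagged undefined
  m0 <- cbind(GY = c(-1, 1)); rownames(m0) <- c("A", "B")
  w0 <- cbind(GY = c(1, 1)); rownames(w0) <- c("A", "B")
  expect_true(is.na(selection_differentials(m0, w0, "A")$means$ds_pct))
})

test_that("cross-ME membership counts selections per genotype", {
  mk <- function(sel) {
    data.frame(genotype = sprintf("G%02d", 1:4),
               mtmps = 1:4, rank = 1:4,
               selected = sprintf("G%02d", 1:4) %in% sel)
  }
  sm <- cross_me_summary(list(ME1 = mk("G01"), ME2 = mk(c("G01", "G02")),
                              ME3 = mk("G01"), ME4 = mk("G01")))
  expect_equal(sm$n_selected[sm$genotype == "G01"], 4)
  expect_equal(sm$n_selected[sm$genotype == "G03"], 0)
  expect_equal(sm$mes[sm$genotype == "G02"], "ME2")
  expect_error(cross_me_summary(list(mk("G01"))), "at least 2")
})

test_that("a planted 2-factor structure is recovered in most replicates", {
  set.seed(61)
  hits <- 0; n_sim <- 200
  for (i in 1:n_sim) {
    m <- latent_table(100, list(c("t1", "t2", "t3"), c("t4", "t5", "t6")),
                      load = 0.85)
    if (factor_analysis(m)$n_factors == 2) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("strong genotype main effects yield positive yield differentials", {
  # correlated yield-component traits driven by a shared genotypic "vigor"
  # effect that dominates interaction and plot noise
  set.seed(19)
  traits <- c("GY", "EL", "GWE")
  b <- c(GY = 1, EL = 0.6, GWE = 0.8)
  mu <- c(GY = 10.5, EL = 17.5, GWE = 180)
  hits <- 0; n_sim <- 100
  for (i in 1:n_sim) {
    d <- expand.grid(genotype = sprintf("G%02d", 1:26), year = 1:2,
                     location = c("L01", "L02"), block = 1:2,
                     stringsAsFactors = FALSE)
    d$ME <- "ME1"
    gi <- as.integer(factor(d$genotype))
    vigor <- rnorm(26, 0, 2)
    for (tr in traits) {
      gei <- matrix(rnorm(52, 0, 0.5), 26, 2)
      d[[tr]] <- mu[[tr]] + b[[tr]] * (vigor[gi] + rnorm(26)[gi]) +
        gei[cbind(gi, d$year)] + rnorm(nrow(d), 0, 0.5)
    }
    res <- me_selection(d, "ME1", traits = traits, intensity = 6 / 26)
    ds <- res$differentials$means
    if (ds$ds_pct[ds$trait == "GY"] > 0) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.90)
})

test_that("a widely adapted genotype is selected across mega-environments", {
  set.seed(55)
  hits <- 0; n_sim <- 100
  traits <- c("GY", "EL", "GWE")
  for (i in 1:n_sim) {
    # 12 genotypes x 4 MEs x 2 years; genotype G01 has a large positive
    # main effect on every trait and zero interaction
    sels <- list()
    g_eff <- replicate(3, c(3, rnorm(11, 0, 1)))
    for (me in paste0("ME", 1:4)) {
      d <- expand.grid(genotype = sprintf("G%02d", 1:12),
                       year = 1:2, block = 1:2, stringsAsFactors = FALSE)
      d$ME <- me; d$location <- paste0("L", me)
      gi <- as.integer(factor(d$genotype))
      for (t in seq_along(traits)) {
        gei <- rbind(0, matrix(rnorm(22, 0, 0.8), 11, 2))      # G01 row zero
        d[[traits[t]]] <- 20 + g_eff[gi, t] + gei[cbind(gi, d$year)] +
          rnorm(nrow(d), 0, 0.5)
      }
      sels[[me]] <- me_selection(d, me, traits = traits,
                                 intensity = 0.25)$selection
    }
    sm <- cross_me_summary(sels)
    if (sm$n_selected[sm$genotype == "G01"] == 4) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.90)
})
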