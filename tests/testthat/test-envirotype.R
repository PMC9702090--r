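cov_fixture <- function(seed = 5, years = 2019:2020, n_loc = 4,
                        arch = c(1, 1, 3, 3), noise = 1) {
  derive_covariables(simulate_weather(
    sim_config(n_locations = n_loc, me_archetypes = arch, rng_seed = seed,
               noise_scale = noise), years = years))
}

test_that("W has one descriptor per year x covariable x window", {
  cv <- cov_fixture()
  w6 <- build_w_matrix(cv, years = 2020, covariable_set = "VPD")
  expect_equal(ncol(w6$raw), 6)                 # 1 year x 1 covariable x 6
  w_all <- build_w_matrix(cv)
  expect_equal(ncol(w_all$raw), 2 * 19 * 6)
  # surviving columns are standardised across environments
  expect_true(all(abs(colMeans(w_all$W)) < 1e-9))
  expect_true(all(abs(apply(w_all$W, 2, sd) - 1) < 1e-9))
})

test_that("QC removes exactly the descriptor columns with outlier cells", {
  cv <- cov_fixture(n_loc = 10, arch = c(1, 2, 2, 2, 3, 3, 3, 3, 4, 4))
  w <- build_w_matrix(cv, years = 2020, covariable_set = c("T2M", "VPD"))
  before <- ncol(w$W)
  # plant a single extreme cell in one July T2M value so its column z > 4
  cv2 <- cv
  july <- format(as.Date(cv2$date), "%m") == "07" & cv2$location == "L01"
  cv2$T2M[july] <- cv2$T2M[july] + 40
  w2 <- build_w_matrix(cv2, years = 2020, covariable_set = c("T2M", "VPD"),
                       qc_sd = 2.5)
  removed <- setdiff(colnames(w$W), colnames(w2$W))
  expect_true("2020_T2M_07" %in% removed)
  expect_equal(ncol(w2$raw), ncol(w$raw))       # QC acts after aggregation
  expect_true(all(grepl("T2M", removed)))       # VPD columns untouched
})

test_that("degenerate W inputs are rejected", {
  cv <- cov_fixture()
  expect_error(build_w_matrix(cv[cv$location == "L01", ]),
               "at least 2 environments")
  expect_error(build_w_matrix(cv[format(as.Date(cv$date), "%m") != "07", ]),
               "every environment must cover")
})

test_that("kernel normalisation forces trace = number of environments", {
  cv <- cov_fixture()
  k <- enviromic_kernel(build_w_matrix(cv))
  expect_equal(sum(diag(k$K)), 4, tolerance = 1e-9)
  expect_equal(k$K, t(k$K))
  expect_gte(min(eigen(k$K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("2x2 identity envirotype matrix yields the identity kernel", {
  w <- diag(2)
  rownames(w) <- c("A", "B")
  k <- enviromic_kernel(w)
  expect_equal(k$K, diag(2), ignore_attr = TRUE)
  expect_error(enviromic_kernel(matrix(0, 2, 2)), "all-zero")
})

test_that("delineation behaves at the edges and under permutation", {
  cv <- cov_fixture()
  k <- enviromic_kernel(build_w_matrix(cv))
  expect_equal(unique(delineate_mega_environments(k, 1)$assignment$ME), "ME1")
  expect_error(delineate_mega_environments(k, 9), "between 1 and")

  # duplicated environments merge at height zero and share a label
  m <- build_w_matrix(cv)$W
  m2 <- rbind(m, L99 = m["L01", ])
  k2 <- enviromic_kernel(m2)
  asg <- delineate_mega_environments(k2, 3)$assignment
  expect_equal(asg$ME[asg$environment == "L99"],
               asg$ME[asg$environment == "L01"])

  # environment order only permutes labels, never the partition
  perm <- sample(nrow(m))
  k3 <- enviromic_kernel(m[perm, ])
  a1 <- delineate_mega_environments(k, 2)$assignment
  a3 <- delineate_mega_environments(k3, 2)$assignment
  a3 <- a3[match(a1$environment, a3$environment), ]
  expect_equal(mclust::adjustedRandIndex(a1$ME, a3$ME), 1)
})

test_that("well-separated archetypes are recovered exactly at k = 4", {
  cfg <- sim_config(rng_seed = 17, noise_scale = 0.1)  # offsets >> noise
  cv <- derive_covariables(simulate_weather(cfg, years = 2016:2020))
  asg <- delineate_mega_environments(
    enviromic_kernel(build_w_matrix(cv)), k = 4)$assignment
  truth <- paste0("ME", cfg$me_archetypes)
  est <- asg$ME[match(sprintf("L%02d", 1:10), asg$environment)]
  expect_equal(mclust::adjustedRandIndex(truth, est), 1)
})

test_that("silhouette diagnostic scores candidate partitions", {
  cfg <- sim_config(rng_seed = 17, noise_scale = 0.1)
  cv <- derive_covariables(simulate_weather(cfg, years = 2019:2020))
  sil <- me_silhouette(enviromic_kernel(build_w_matrix(cv)), 2:6)
  expect_equal(nrow(sil), 5)
  expect_true(all(sil$mean_silhouette >= -1 & sil$mean_silhouette <= 1))
})

test_that("environment PCA matches the correlation-matrix closed forms", {
  cv <- cov_fixture(n_loc = 6, arch = c(1, 1, 2, 3, 3, 4))
  tab <- environment_means(cv)
  pc <- environment_pca(tab)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)

  # rank-1 table: a single component carries everything
  v <- c(1, 2, 3, 4)
  r1 <- outer(v, c(1, -2, 0.5)); rownames(r1) <- paste0("E", 1:4)
  pc1 <- environment_pca(r1)
  expect_equal(pc1$explained[1], 1, tolerance = 1e-9)

  # two standardised variables with correlation rho: eigenvalues 1 +/- rho
  set.seed(4)
  x <- rnorm(200); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(200)
  rho <- cor(x, y)
  pc2 <- environment_pca(cbind(x, y))
  expect_equal(sort(pc2$eigenvalues), sort(c(1 - rho, 1 + rho)),
               tolerance = 1e-9)

  expect_error(environment_pca(tab[1:2, ]), "at least 3")
  expect_warning(environment_pca(cbind(tab, const = 1)), "constant")
})
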