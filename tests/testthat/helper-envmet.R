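# shared fixtures and independent oracles for the test suite

# a small, fast simulation configuration (4 locations over 2 archetypes)
small_config <- function(seed = 42, ...) {
  sim_config(n_genotypes = 8, n_locations = 4, n_years = 2, n_blocks = 2,
             me_archetypes = c(1, 1, 3, 3), weather_years = 2019:2020,
             rng_seed = seed, ...)
}

# straight-line re-evaluation of each daily covariable formula, written
# independently of derive_covariables() as the oracle
oracle_covariables <- function(tmean, tmax, tmin, tdew, prec, sihs, lat, doy,
                               tbase = 8, cardinal = c(9, 26, 32, 45)) {
  es <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(dec))))
  ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  N <- 24 * ws / pi
  frue <- vapply(tmean, function(t) {
    if (t <= cardinal[1] || t >= cardinal[4]) 0
    else if (t < cardinal[2]) (t - cardinal[1]) / (cardinal[2] - cardinal[1])
    else if (t <= cardinal[3]) 1
    else (cardinal[4] - t) / (cardinal[4] - cardinal[3])
  }, numeric(1))
  list(
    TRANGE = tmax - tmin,
    VPD = pmax(0, (es(tmax) + es(tmin)) / 2 - es(tdew)),
    SVP = 4098 * es(tmean) / (tmean + 237.3)^2,
    RTA = ra,
    N = N,
    n = pmin(N, pmax(0, N * (sihs / ra - 0.25) / 0.5)),
    GDD = pmax(0, (tmax + tmin) / 2 - tbase),
    FRUE = frue
  )
}

# brute-force double-loop ecovalence straight from the definition
oracle_ecovalence <- function(m) {
  gbar <- rowMeans(m); ybar <- colMeans(m); mu <- mean(m)
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    for (k in seq_len(ncol(m))) {
      out[i] <- out[i] + (m[i, k] - gbar[i] - ybar[k] + mu)^2
    }
  }
  names(out) <- rownames(m)
  out
}

# step-by-step factor scores F = Z (A' R^-1)' evaluated independently
oracle_factor_scores <- function(rM, A) {
  R <- cor(rM)
  Z <- scale(rM)
  Z %*% t(t(A) %*% solve(R))
}

# balanced one-way ANOVA closed-form variance components
oracle_oneway <- function(y, group) {
  group <- factor(group)
  r <- length(y) / nlevels(group)
  ms_g <- r * var(tapply(y, group, mean))
  ms_e <- mean(tapply(y, group, var))
  c(G = max(0, (ms_g - ms_e) / r), residual = ms_e)
}

expect_freq_sums_one <- function(typ) {
  s <- stats::aggregate(freq ~ ME + year + stage + covariable,
                        as.data.frame(typ), sum)
  expect_true(all(abs(s$freq - 1) < 1e-9))
}
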