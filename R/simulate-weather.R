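# ---- daily weather simulation -------------------------------------------

# AR(1) noise with unit marginal scale times sd, stationary initialisation
.ar1_noise <- function(n, sd, phi = 0.7) {
  if (n == 0L) return(numeric(0))
  innov <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- innov[1]
  for (t in seq_len(n)[-1]) {
    x[t] <- phi * x[t - 1] + sqrt(1 - phi^2) * innov[t]
  }
  sd * x
}

# smooth seasonal shape peaking in mid July (day of year ~196)
.seasonal <- function(doy) sin(2 * pi * (doy - 105.25) / 365.25)

#' Simulate a daily weather archive
#'
#' Generates daily weather for every location and year of the archive, for
#' the May-October growing window.  Each raw variable is a sinusoidal
#' seasonal mean (peaking in mid July) plus a location-specific AR(1) daily
#' noise process; constant per-archetype offsets make locations sharing an
#' archetype more alike, in descriptor space, than locations from different
#' archetypes.  Physical constraints hold by construction: temperatures are
#' generated as mean plus/minus half a positive diurnal range (so
#' Tmin <= Tmean <= Tmax), the dew point is the air temperature minus a
#' positive depression (so the vapour-pressure deficit is non-negative and
#' relative humidity is in (0, 100]), shortwave radiation is a clearness
#' fraction in [0.25, 0.75] of the extraterrestrial radiation, and
#' precipitation and wind are floored at zero.
#'
#' @param config a [sim_config()] object.
#' @param years integer vector of years to generate; defaults to the
#'   long-term archive years of the configuration.
#' @return a data frame of class `weather_data` with columns `location`,
#'   `lat`, `lon`, `date`, `T2M`, `T2M_MAX`, `T2M_MIN`, `T2MDEW`, `RH2M`,
#'   `PRECTOT`, `WS2M`, `SIHS`, `DTIRF`.
#' @export
simulate_weather <- function(config, years = config$weather_years) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_locations < 1) stop("at least one location is required",
                                   call. = FALSE)
  if (!length(years)) stop("at least one year is required", call. = FALSE)

  loc <- .loc_labels(config$n_locations)
  arch <- config$weather_archetypes
  ns <- config$noise_scale

  out <- vector("list", config$n_locations)
  .with_seed(.child_seed(config$rng_seed, "weather"), {
    for (li in seq_len(config$n_locations)) {
      a <- arch[match(config$me_archetypes[li], arch$archetype), ]
      days <- do.call(c, lapply(years, function(y) {
        seq(as.Date(sprintf("%d-05-01", y)),
            as.Date(sprintf("%d-10-31", y)), by = "day")
      }))
      n <- length(days)
      doy <- as.integer(strftime(days, "%j"))
      season <- .seasonal(doy)

      tmean <- a$tmean_base + a$tmean_amp * season + ns * .ar1_noise(n, 1.5)
      trange <- pmax(0.5, a$trange + ns * .ar1_noise(n, 1.5))
      tmax <- tmean + trange / 2
      tmin <- tmean - trange / 2
      tdew <- tmean - pmax(0.1, a$dew_depression + ns * .ar1_noise(n, 1.0))
      rh <- pmin(100, pmax(0, 100 * .svp(tdew) / .svp(tmean)))
      kt <- pmin(0.75, pmax(0.25, a$clearness + ns * .ar1_noise(n, 0.08)))
      ra <- .extraterrestrial_radiation(a$lat, doy)
      sihs <- kt * ra
      prec <- pmax(0, a$precip_rate * (0.6 + 0.8 * pmax(season, 0)) +
                     ns * .ar1_noise(n, 2 * a$precip_rate))
      wind <- pmax(0.1, a$wind + ns * .ar1_noise(n, 0.5))
      dtirf <- pmax(5, a$dtirf + 3 * season + ns * .ar1_noise(n, 1.0))

      out[[li]] <- data.frame(
        location = loc[li], lat = a$lat, lon = a$lon, date = days,
        T2M = tmean, T2M_MAX = tmax, T2M_MIN = tmin, T2MDEW = tdew,
        RH2M = rh, PRECTOT = prec, WS2M = wind, SIHS = sihs, DTIRF = dtirf,
        stringsAsFactors = FALSE
      )
    }
  })

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("weather_data", "data.frame"))
}
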