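# ---- environmental covariables ------------------------------------------

# saturation vapour pressure (kPa) at temperature T (deg C), Tetens form
.svp <- function(temp) 0.6108 * exp(17.27 * temp / (temp + 237.3))

# slope of the saturation vapour pressure curve (kPa / deg C)
.svp_slope <- function(temp) 4098 * .svp(temp) / (temp + 237.3)^2

# solar geometry for a latitude (degrees) and day of year: extraterrestrial
# radiation Ra (MJ m-2 day-1), daylight hours N, sunset hour angle ws
.solar_geometry <- function(lat, doy) {
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)         # inverse relative distance
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)     # solar declination
  x <- pmin(1, pmax(-1, -tan(phi) * tan(dec)))
  ws <- acos(x)
  gsc <- 0.0820                                     # MJ m-2 min-1
  ra <- (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  list(ra = pmax(0, ra), daylight = 24 * ws / pi, ws = ws)
}

.extraterrestrial_radiation <- function(lat, doy) .solar_geometry(lat, doy)$ra

# temperature effect on radiation-use efficiency: piecewise-linear response
# between cardinal temperatures, in [0, 1]
.frue <- function(temp, cardinal) {
  tb <- cardinal[1]; to1 <- cardinal[2]; to2 <- cardinal[3]; tc <- cardinal[4]
  out <- numeric(length(temp))
  ramp_up <- temp > tb & temp < to1
  out[ramp_up] <- (temp[ramp_up] - tb) / (to1 - tb)
  out[temp >= to1 & temp <= to2] <- 1
  ramp_dn <- temp > to2 & temp < tc
  out[ramp_dn] <- (tc - temp[ramp_dn]) / (tc - to2)
  out
}

#' Parameters for covariable derivation
#'
#' Tunable constants used by [derive_covariables()].
#'
#' @param tbase base temperature (deg C) for growing-degree-day accumulation;
#'   default 8 for maize.
#' @param cardinal cardinal temperatures (deg C) `c(Tb, Topt1, Topt2, Tceil)`
#'   of the piecewise-linear radiation-use-efficiency response; defaults
#'   9/26/32/45 for maize.
#' @param etp_method reference-evapotranspiration method:
#'   `"priestley-taylor"` (default) or `"penman-monteith"` (FAO-56).
#' @param alpha_pt Priestley-Taylor coefficient (default 1.26).
#' @param angstrom Angstrom coefficients `c(a, b)` linking relative sunshine
#'   duration to the shortwave/extraterrestrial radiation ratio.
#' @param albedo surface albedo used for net shortwave radiation.
#' @param elevation site elevation (m) used for the psychrometric constant
#'   and clear-sky radiation when the weather table carries no `elevation`
#'   column.
#' @return a named list of class `covariable_params`.
#' @export
covariable_params <- function(tbase = 8,
                              cardinal = c(9, 26, 32, 45),
                              etp_method = c("priestley-taylor",
                                             "penman-monteith"),
                              alpha_pt = 1.26,
                              angstrom = c(a = 0.25, b = 0.50),
                              albedo = 0.23,
                              elevation = 50) {
  etp_method <- match.arg(etp_method)
  stopifnot(length(cardinal) == 4, !is.unsorted(cardinal))
  structure(list(tbase = tbase, cardinal = cardinal,
                 etp_method = etp_method, alpha_pt = alpha_pt,
                 angstrom = angstrom, albedo = albedo,
                 elevation = elevation),
            class = "covariable_params")
}

#' Derive daily environmental covariables from raw weather
#'
#' Expands the raw daily weather series into the full set of 19
#' environmental covariables: the nine raw variables plus temperature range
#' (TRANGE), reference evapotranspiration (ETP), the precipitation-minus-ETP
#' balance (PETP), vapour pressure deficit (VPD), the slope of the
#' saturation vapour pressure curve (SVP), the temperature effect on
#' radiation-use efficiency (FRUE), growing degree days (GDD), actual
#' sunshine duration (n), daylight hours (N) and extraterrestrial radiation
#' (RTA).
#'
#' Daily formulas: `TRANGE = Tmax - Tmin`; saturation vapour pressure
#' `e_s(T) = 0.6108 exp(17.27 T / (T + 237.3))` with the actual vapour
#' pressure taken at the dew point, so
#' `VPD = max(0, (e_s(Tmax) + e_s(Tmin))/2 - e_s(Tdew))`;
#' `SVP = 4098 e_s(Tmean) / (Tmean + 237.3)^2`; RTA and N follow standard
#' solar geometry (inverse relative Earth-Sun distance and declination);
#' n inverts the Angstrom relation `Rs = (a + b n/N) RTA` and is clipped to
#' `[0, N]`; `GDD = max(0, (Tmax + Tmin)/2 - Tbase)`; FRUE is the
#' piecewise-linear cardinal-temperature response in `[0, 1]`; ETP uses the
#' configured method and `PETP = precipitation - ETP` (positive values mean
#' water supply exceeds atmospheric demand).
#'
#' @param weather a `weather_data` data frame (see [simulate_weather()] /
#'   [read_weather()]); may hold several locations.
#' @param params a [covariable_params()] object.
#' @return a data frame of class `covariable_data`: the raw columns plus the
#'   derived covariables, one row per location-day.
#' @export
derive_covariables <- function(weather, params = covariable_params()) {
  stopifnot(is.data.frame(weather))
  req <- c("location", "lat", "date", "T2M", "T2M_MAX", "T2M_MIN", "T2MDEW",
           "RH2M", "PRECTOT", "WS2M", "SIHS", "DTIRF")
  miss <- setdiff(req, names(weather))
  if (length(miss)) stop("weather table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(weather$lat < -90 | weather$lat > 90)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  # contiguous-day check per location-year
  d <- weather
  d$date <- as.Date(d$date)
  yr <- as.integer(format(d$date, "%Y"))
  for (key in split(seq_len(nrow(d)), list(d$location, yr), drop = TRUE)) {
    dt <- sort(d$date[key])
    gaps <- diff(dt) != 1
    if (any(gaps)) {
      stop("missing day(s) after ", dt[which(gaps)[1]], " for location ",
           d$location[key[1]], call. = FALSE)
    }
  }

  doy <- as.integer(strftime(d$date, "%j"))
  sol <- .solar_geometry(d$lat, doy)

  es_max <- .svp(d$T2M_MAX)
  es_min <- .svp(d$T2M_MIN)
  ea <- .svp(d$T2MDEW)
  vpd <- pmax(0, (es_max + es_min) / 2 - ea)

  d$TRANGE <- d$T2M_MAX - d$T2M_MIN
  d$VPD <- vpd
  d$SVP <- .svp_slope(d$T2M)
  d$RTA <- sol$ra
  d$N <- sol$daylight
  rel <- ifelse(sol$ra > 0, d$SIHS / sol$ra, 0)
  a <- params$angstrom[["a"]]; b <- params$angstrom[["b"]]
  d$n <- pmin(d$N, pmax(0, d$N * (rel - a) / b))
  d$GDD <- pmax(0, (d$T2M_MAX + d$T2M_MIN) / 2 - params$tbase)
  d$FRUE <- .frue(d$T2M, params$cardinal)

  z <- if ("elevation" %in% names(weather)) weather$elevation else
    params$elevation
  d$ETP <- .reference_etp(tmean = d$T2M, tmax = d$T2M_MAX, tmin = d$T2M_MIN,
                          ea = ea, rs = d$SIHS, ra = sol$ra, u2 = d$WS2M,
                          elevation = z, params = params)
  d$PETP <- d$PRECTOT - d$ETP
  structure(d, class = c("covariable_data", "data.frame"))
}

# reference evapotranspiration (mm day-1) by Priestley-Taylor or FAO-56
# Penman-Monteith, both driven by net radiation estimated from shortwave
# radiation, clear-sky transmissivity and vapour pressure
.reference_etp <- function(tmean, tmax, tmin, ea, rs, ra, u2, elevation,
                           params) {
  delta <- .svp_slope(tmean)
  press <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * press
  rns <- (1 - params$albedo) * rs
  rso <- (0.75 + 2e-5 * elevation) * ra
  rel <- ifelse(rso > 0, pmin(1, rs / rso), 1)
  sigma <- 4.903e-9
  rnl <- sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(0, ea))) * (1.35 * rel - 0.35)
  rn <- rns - rnl
  if (params$etp_method == "priestley-taylor") {
    pmax(0, params$alpha_pt * delta / (delta + gamma) * rn / 2.45)
  } else {
    es <- (.svp(tmax) + .svp(tmin)) / 2
    pmax(0, (0.408 * delta * rn +
               gamma * 900 / (tmean + 273) * u2 * (es - ea)) /
           (delta + gamma * (1 + 0.34 * u2)))
  }
}

# the 19 covariable column names, in canonical order
.covariable_names <- function() {
  c("T2M", "T2M_MAX", "T2M_MIN", "T2MDEW", "RH2M", "PRECTOT", "WS2M",
    "SIHS", "DTIRF", "TRANGE", "ETP", "PETP", "VPD", "SVP", "FRUE",
    "GDD", "n", "N", "RTA")
}

# covariables accumulated over a window (summed); the rest are averaged
.flux_covariables <- function() c("PRECTOT", "ETP", "PETP", "GDD", "n", "N",
                                  "RTA")
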