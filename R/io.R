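# ---- file ingestion and emission ----------------------------------------

#' Read a plot-level phenotype table
#'
#' Reads the phenotype CSV dialect
#' `genotype,location,year,block[,ME],<trait columns...>`, validates it and
#' returns a typed `trial_data` frame.
#'
#' @param path CSV file path.
#' @param traits optional trait column names; default: every column beyond
#'   the design columns.
#' @return a `trial_data` data frame.
#' @export
read_phenotypes <- function(path, traits = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("genotype", "location", "year", "block")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("phenotype file lacks required column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  design_cols <- c(req, "ME")
  if (is.null(traits)) traits <- setdiff(names(d), design_cols)
  if (!length(traits)) stop("phenotype file holds no trait columns",
                            call. = FALSE)
  for (tr in traits) {
    v <- suppressWarnings(as.numeric(d[[tr]]))
    bad <- which(is.na(v) & !is.na(d[[tr]]) & nzchar(trimws(d[[tr]])))
    if (length(bad)) {
      stop("non-numeric value(s) for trait '", tr, "' at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    d[[tr]] <- v
  }
  key <- paste(d$genotype, d$location, d$year, d$block, sep = "/")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicated plot key(s): ", paste(utils::head(dup, 5),
                                           collapse = "; "), call. = FALSE)
  }
  structure(d, class = c("trial_data", "data.frame"))
}

#' Read a daily weather archive
#'
#' Reads the weather CSV dialect
#' `location,lat,lon,date,T2M,T2M_MAX,T2M_MIN,T2MDEW,RH2M,PRECTOT,WS2M,SIHS,DTIRF`
#' (ISO dates), validates physical invariants (Tmin <= Tmax, relative
#' humidity in [0, 100], non-negative precipitation) and reports calendar
#' gaps per location-year in attribute `"gaps"`.
#'
#' @param path CSV file path.
#' @return a `weather_data` data frame.
#' @export
read_weather <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("location", "lat", "lon", "date", "T2M", "T2M_MAX", "T2M_MIN",
           "T2MDEW", "RH2M", "PRECTOT", "WS2M", "SIHS", "DTIRF")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("weather file lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dt <- as.Date(d$date, format = "%Y-%m-%d")
  bad <- which(is.na(dt))
  if (length(bad)) stop("unparsable date(s) at data row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  d$date <- dt
  bad <- which(d$T2M_MIN > d$T2M_MAX)
  if (length(bad)) stop("Tmin > Tmax at data row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  bad <- which(d$RH2M < 0 | d$RH2M > 100)
  if (length(bad)) stop("relative humidity outside [0, 100] at data row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  bad <- which(d$PRECTOT < 0)
  if (length(bad)) stop("negative precipitation at data row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  # gap report: missing calendar days inside each location-year span
  yr <- format(d$date, "%Y")
  gaps <- list()
  for (key in split(seq_len(nrow(d)), list(d$location, yr), drop = TRUE)) {
    dd <- sort(d$date[key])
    full <- seq(min(dd), max(dd), by = "day")
    missing_days <- setdiff(as.character(full), as.character(dd))
    if (length(missing_days)) {
      gaps[[paste(d$location[key[1]], yr[key[1]], sep = "/")]] <- missing_days
    }
  }
  structure(d, gaps = gaps, class = c("weather_data", "data.frame"))
}

#' Write a table as CSV
#'
#' Plain CSV writer (no row names, no quoting surprises) used for every
#' tabular artefact so that outputs round-trip through the package readers.
#'
#' @param x data frame or matrix (matrices are written with a leading `id`
#'   column holding the row names).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), as.data.frame(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  }
  df <- as.data.frame(x)
  if ("date" %in% names(df)) df$date <- as.character(df$date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
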