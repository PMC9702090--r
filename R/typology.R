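# ---- environmental typology ---------------------------------------------

#' Default crop-stage windows (days after sowing)
#'
#' Five maize phenological windows: initial growth (0-14 DAS), leaf
#' expansion I (15-35), leaf expansion II (36-65), flowering (66-90) and
#' grain filling (91-120).
#'
#' @return named list of `c(start, end)` DAS windows.
#' @export
crop_stages <- function() {
  list(
    "initial"         = c(0, 14),
    "leaf_expansion1" = c(15, 35),
    "leaf_expansion2" = c(36, 65),
    "flowering"       = c(66, 90),
    "grain_filling"   = c(91, 120)
  )
}

#' Quantile-based environmental typology per crop stage
#'
#' Classifies every trial day of each covariable into quantile-bounded
#' classes and tabulates, for every (year, mega-environment, crop stage)
#' combination, the relative frequency of days falling in each class.
#' Class breakpoints are the global quantiles of the covariable across all
#' trial days (all locations, years and stages pooled), so a class such as
#' "above the 0.975 quantile" identifies extreme events comparably across
#' environments.
#'
#' @param covariables a `covariable_data` frame covering the trial seasons.
#' @param assignment an `me_assignment` (or a data frame with columns
#'   `environment`, `ME`) mapping locations to mega-environments.
#' @param sowing sowing dates: either a single `"MM-DD"` string applied to
#'   every location-year, or a data frame `location, year, sowing` with
#'   `Date` sowing values.
#' @param stages named list of `c(start, end)` DAS windows (default
#'   [crop_stages()]).
#' @param quantiles probabilities defining the class breakpoints (default
#'   0.01, 0.25, 0.50, 0.75, 0.975, 0.99).
#' @param covariable_set covariables to type (default the 19).
#' @return a data frame of class `env_typology` with columns `ME`, `year`,
#'   `stage`, `covariable`, `class` (interval label), `freq` and `n_days`;
#'   frequencies sum to 1 within each (ME, year, stage, covariable) group.
#'   Empty groups are omitted and listed in attribute `"skipped"`.
#' @export
env_typing <- function(covariables, assignment, sowing = "06-10",
                       stages = crop_stages(),
                       quantiles = c(0.01, 0.25, 0.50, 0.75, 0.975, 0.99),
                       covariable_set = .covariable_names()) {
  d <- covariables
  d$date <- as.Date(d$date)
  d$year <- as.integer(format(d$date, "%Y"))
  asg <- if (inherits(assignment, "me_assignment")) assignment$assignment
         else as.data.frame(assignment)
  d$ME <- asg$ME[match(d$location, asg$environment)]
  if (anyNA(d$ME)) {
    stop("no mega-environment assignment for location(s): ",
         paste(unique(d$location[is.na(d$ME)]), collapse = ", "),
         call. = FALSE)
  }

  # days after sowing for each row
  if (is.character(sowing) && length(sowing) == 1L) {
    sow <- as.Date(sprintf("%d-%s", d$year, sowing))
  } else {
    sow_tab <- as.data.frame(sowing)
    i <- match(paste(d$location, d$year), paste(sow_tab$location, sow_tab$year))
    if (anyNA(i)) stop("missing sowing date for some location-year",
                       call. = FALSE)
    sow <- as.Date(sow_tab$sowing)[i]
  }
  d$das <- as.integer(d$date - sow)

  stage_of <- rep(NA_character_, nrow(d))
  for (st in names(stages)) {
    w <- stages[[st]]
    stage_of[d$das >= w[1] & d$das <= w[2]] <- st
  }
  d$stage <- factor(stage_of, levels = names(stages))
  d <- d[!is.na(d$stage), , drop = FALSE]
  if (!nrow(d)) stop("no trial days fall inside the stage windows",
                     call. = FALSE)

  out <- list()
  skipped <- character(0)
  grp_key <- interaction(d$ME, d$year, d$stage, drop = FALSE, sep = "\r")
  for (cv in covariable_set) {
    x <- d[[cv]]
    br <- unique(stats::quantile(x, probs = quantiles, names = FALSE))
    breaks <- unique(c(-Inf, br, Inf))
    cls <- cut(x, breaks = breaks, include.lowest = TRUE)
    tab <- table(grp_key, cls)
    n_by_grp <- rowSums(tab)
    present <- n_by_grp > 0
    skipped <- union(skipped, rownames(tab)[!present])
    freq <- tab[present, , drop = FALSE] / n_by_grp[present]
    ids <- do.call(rbind, strsplit(rownames(freq), "\r", fixed = TRUE))
    out[[cv]] <- data.frame(
      ME = rep(ids[, 1], ncol(freq)),
      year = rep(as.integer(ids[, 2]), ncol(freq)),
      stage = rep(ids[, 3], ncol(freq)),
      covariable = cv,
      class = rep(colnames(freq), each = nrow(freq)),
      freq = as.vector(freq),
      n_days = rep(unname(n_by_grp[present]), ncol(freq)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$covariable, res$ME, res$year, res$stage), ]
  structure(res, skipped = gsub("\r", "/", skipped, fixed = TRUE),
            class = c("env_typology", "data.frame"))
}
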