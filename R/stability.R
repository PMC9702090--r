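# ---- mean performance and stability within mega-environments ------------

#' Genotype x year mean matrix within a mega-environment
#'
#' Averages plot values over the locations and blocks of the
#' mega-environment, separately per year, giving the two-way table on which
#' year-to-year stability is measured.  Pooling is over raw plots (not over
#' location means), which coincides with averaging location means under a
#' balanced design.
#'
#' @param data a `trial_data` frame with an `ME` column.
#' @param me mega-environment label to subset.
#' @param trait trait column name.
#' @return numeric matrix, genotypes x years, with attribute `"dropped"`
#'   listing genotypes excluded for missing a year (their stability is
#'   undefined).
#' @export
genotype_year_means <- function(data, me, trait) {
  stopifnot(is.data.frame(data))
  if (!"ME" %in% names(data)) stop("data lacks an 'ME' column", call. = FALSE)
  d <- data[data$ME == me, , drop = FALSE]
  if (!nrow(d)) stop("no records for mega-environment '", me, "'",
                     call. = FALSE)
  gt <- factor(d$genotype)
  yr <- factor(d$year)
  m <- tapply(d[[trait]], list(gt, yr), mean)
  dropped <- rownames(m)[apply(is.na(m), 1, any)]
  if (length(dropped)) {
    warning("excluding genotype(s) missing a year in ", me, ": ",
            paste(dropped, collapse = ", "))
    m <- m[!rownames(m) %in% dropped, , drop = FALSE]
  }
  attr(m, "dropped") <- dropped
  m
}

#' Wricke's ecovalence
#'
#' The contribution of each genotype to the genotype x year interaction sum
#' of squares of a genotype x year mean matrix:
#' \deqn{W_i = \sum_k (\bar Y_{ik} - \bar Y_{i.} - \bar Y_{.k} + \bar Y_{..})^2}
#' Smaller values indicate genotypes whose year-to-year deviations track
#' the average response, i.e. more stable genotypes.  By construction
#' `sum(W_i)` equals the interaction sum of squares of the double-centred
#' matrix.
#'
#' @param means numeric genotype x year matrix (at least 2 x 2).
#' @return named numeric vector of `W_i` values (all `>= 0`).
#' @export
ecovalence <- function(means) {
  m <- as.matrix(means)
  if (nrow(m) < 2) stop("at least 2 genotypes are required", call. = FALSE)
  if (ncol(m) < 2) stop("stability is undefined with a single year",
                        call. = FALSE)
  if (anyNA(m)) stop("mean matrix contains missing cells", call. = FALSE)
  res <- m - outer(rowMeans(m), colMeans(m), "+") + mean(m)
  rowSums(res^2)
}

#' Direction-aware 0-100 rescaling
#'
#' Linear map of a vector onto [0, 100] following the desired direction of
#' selection: with `direction = "increase"` the largest original value maps
#' to 100; with `direction = "decrease"` the smallest maps to 100 (the rule
#' always applied to ecovalence, where small is good).  The map is
#' `r_i = (nma - nmi)/(oma - omi) * (o_i - oma) + nma` with
#' `(nma, nmi) = (100, 0)` for increase and `(0, 100)` for decrease, where
#' `oma`/`omi` are the original extremes.
#'
#' @param values finite numeric vector.
#' @param direction `"increase"` or `"decrease"`.
#' @return numeric vector in [0, 100].  When all values are equal the map
#'   is degenerate and every value is set to 50 with a warning.
#' @export
rescale_index <- function(values, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  oma <- max(values); omi <- min(values)
  if (oma == omi) {
    warning("all values identical: rescaling is degenerate, returning 50s")
    return(rep(50, length(values)))
  }
  if (direction == "increase") { nma <- 100; nmi <- 0 } else { nma <- 0; nmi <- 100 }
  (nma - nmi) / (oma - omi) * (values - oma) + nma
}

#' Mean-performance-and-stability index
#'
#' Weighted combination of the rescaled mean performance `rY` and rescaled
#' ecovalence `rW`:
#' \deqn{MPS_i = (rY_i \theta_Y + rW_i \theta_S) / (\theta_Y + \theta_S)}
#' The defaults weight mean performance over stability 70/30.
#'
#' @param r_y,r_w aligned rescaled vectors in [0, 100].
#' @param theta_y,theta_s non-negative weights with a positive sum.
#' @return numeric vector in [0, 100]; 100 is ideal.
#' @export
mps <- function(r_y, r_w, theta_y = 70, theta_s = 30) {
  if (length(r_y) != length(r_w)) stop("'r_y' and 'r_w' lengths differ",
                                       call. = FALSE)
  if (theta_y < 0 || theta_s < 0 || theta_y + theta_s <= 0) {
    stop("weights must be non-negative with a positive sum", call. = FALSE)
  }
  (r_y * theta_y + r_w * theta_s) / (theta_y + theta_s)
}

#' Genotype ranks across performance/stability weight scenarios
#'
#' Recomputes the MPS index and the genotype ranking over a grid of
#' `theta_Y / theta_S` weight ratios; the default grid runs 100/0, 95/5,
#' ..., 0/100 (21 scenarios).  Rank 1 is the highest MPS; ties receive
#' average ranks.
#'
#' @param r_y,r_w rescaled mean-performance and stability vectors (named by
#'   genotype).
#' @param ratios two-column matrix or data frame of `(theta_y, theta_s)`
#'   pairs; default the 21-step grid.
#' @return data frame with columns `scenario` (label `"thetaY/thetaS"`),
#'   `theta_y`, `theta_s`, `genotype`, `mps`, `rank`.
#' @export
weight_scenarios <- function(r_y, r_w, ratios = NULL) {
  if (is.null(ratios)) {
    ty <- seq(100, 0, by = -5)
    ratios <- cbind(theta_y = ty, theta_s = 100 - ty)
  }
  ratios <- as.matrix(ratios)
  if (!nrow(ratios)) stop("'ratios' must be non-empty", call. = FALSE)
  geno <- names(r_y)
  if (is.null(geno)) geno <- sprintf("G%02d", seq_along(r_y))
  out <- lapply(seq_len(nrow(ratios)), function(i) {
    ty <- unname(ratios[i, 1]); ts <- unname(ratios[i, 2])
    m <- mps(r_y, r_w, ty, ts)
    data.frame(scenario = sprintf("%g/%g", ty, ts),
               theta_y = ty, theta_s = ts,
               genotype = geno, mps = unname(m),
               rank = unname(rank(-m, ties.method = "average")),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-mega-environment mean/stability table for one trait
#'
#' Convenience wrapper chaining [genotype_year_means()], [ecovalence()],
#' [rescale_index()] and [mps()] for a single trait within one
#' mega-environment.  Mean performance is rescaled along the trait's
#' registered direction; ecovalence is always rescaled with
#' `direction = "decrease"` (lower is more stable).
#'
#' @param data a `trial_data` frame with `ME` labels.
#' @param me mega-environment label.
#' @param trait trait name.
#' @param directions trait-direction registry (default
#'   [trait_directions()]).
#' @param theta_y,theta_s MPS weights.
#' @return data frame: `genotype`, `mean`, `ecovalence`, `r_y`, `r_w`,
#'   `mps`, `rank`.
#' @export
trait_mean_stability <- function(data, me, trait,
                                 directions = trait_directions(),
                                 theta_y = 70, theta_s = 30) {
  m <- genotype_year_means(data, me, trait)
  w <- ecovalence(m)
  dir <- .direction_of(trait, directions)
  r_y <- rescale_index(rowMeans(m), dir)
  r_w <- rescale_index(w, "decrease")
  idx <- mps(r_y, r_w, theta_y, theta_s)
  data.frame(genotype = rownames(m), mean = unname(rowMeans(m)),
             ecovalence = unname(w), r_y = unname(r_y), r_w = unname(r_w),
             mps = unname(idx),
             rank = rank(-idx, ties.method = "average"),
             stringsAsFactors = FALSE)
}

#' MPS table across traits (the rM matrix)
#'
#' Builds the genotype x trait table of MPS values within one
#' mega-environment -- the input of the factor-analytic multi-trait index.
#'
#' @inheritParams trait_mean_stability
#' @param traits trait names (default: every registered trait present in
#'   `data`).
#' @return list with `rM` (genotypes x traits MPS matrix), `means`
#'   (genotype x trait mean matrix) and `ecovalence` (genotype x trait
#'   `W_i` matrix).
#' @export
mps_table <- function(data, me, traits = NULL,
                      directions = trait_directions(),
                      theta_y = 70, theta_s = 30) {
  if (is.null(traits)) traits <- intersect(directions$trait, names(data))
  if (!length(traits)) stop("no registered trait columns found in data",
                            call. = FALSE)
  tabs <- lapply(traits, function(tr) {
    trait_mean_stability(data, me, tr, directions, theta_y, theta_s)
  })
  geno <- Reduce(intersect, lapply(tabs, `[[`, "genotype"))
  pull <- function(col) {
    m <- vapply(tabs, function(tb) tb[[col]][match(geno, tb$genotype)],
                numeric(length(geno)))
    dimnames(m) <- list(geno, traits)
    m
  }
  list(rM = pull("mps"), means = pull("mean"), ecovalence = pull("ecovalence"))
}
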