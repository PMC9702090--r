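# ---- envirotype matrix, enviromic kernel, mega-environments -------------

#' Build the envirotype descriptor matrix W
#'
#' Aggregates daily covariables into one descriptor column per
#' (year, covariable, monthly window) and one row per environment
#' (location).  State variables (temperatures, humidity, VPD, radiation
#' fluxes, FRUE, wind) are averaged over the window; accumulation variables
#' (precipitation, ETP, PETP, GDD, sunshine and daylight hours,
#' extraterrestrial radiation) are summed.  Columns are standardised across
#' environments (mean 0, SD 1); any column containing a standardised cell
#' beyond `qc_sd` standard deviations -- and any zero-variance column -- is
#' removed as quality control and recorded.
#'
#' With 20 years, 19 covariables and the default May-October monthly
#' windows, the matrix holds 20 x 19 x 6 = 2280 descriptors before QC.
#'
#' @param covariables a `covariable_data` frame from [derive_covariables()].
#' @param years years to include (default: all present).
#' @param months integer months defining the windows (default May-October).
#' @param qc_sd quality-control threshold in standard deviations (default 3).
#' @param covariable_set descriptor columns to use (default the 19).
#' @return an object of class `envirotype_matrix`: list with `W` (the
#'   standardised environments x descriptors matrix), `raw` (unstandardised
#'   aggregates), `center`, `scale`, `removed` (named list of QC-dropped
#'   columns with reasons) and `key` (descriptor metadata).
#' @export
build_w_matrix <- function(covariables, years = NULL, months = 5:10,
                           qc_sd = 3, covariable_set = .covariable_names()) {
  stopifnot(is.data.frame(covariables))
  miss <- setdiff(covariable_set, names(covariables))
  if (length(miss)) stop("covariable table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d <- covariables
  d$date <- as.Date(d$date)
  d$year <- as.integer(format(d$date, "%Y"))
  d$month <- as.integer(format(d$date, "%m"))
  if (is.null(years)) years <- sort(unique(d$year))
  d <- d[d$year %in% years & d$month %in% months, , drop = FALSE]

  envs <- sort(unique(d$location))
  if (length(envs) < 2) {
    stop("at least 2 environments are required to standardise descriptors",
         call. = FALSE)
  }
  # coverage check: every environment must cover every year x window
  cover <- table(d$location, paste(d$year, d$month, sep = "_"))
  expected <- length(years) * length(months)
  if (ncol(cover) != expected || any(cover == 0)) {
    stop("every environment must cover every requested year x window",
         call. = FALSE)
  }

  flux <- .flux_covariables()
  key <- expand.grid(month = months, covariable = covariable_set,
                     year = years, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  key <- key[, c("year", "covariable", "month")]
  key$column <- sprintf("%d_%s_%02d", key$year, key$covariable, key$month)

  loc_f <- factor(d$location, levels = envs)
  ym <- sprintf("%d_%02d", d$year, d$month)
  ym_f <- factor(ym, levels = sort(unique(ym)))
  key$ym <- sprintf("%d_%02d", key$year, key$month)

  raw <- matrix(NA_real_, nrow = length(envs), ncol = nrow(key),
                dimnames = list(envs, key$column))
  for (cv in covariable_set) {
    f <- if (cv %in% flux) sum else mean
    m <- tapply(d[[cv]], list(loc_f, ym_f), f)   # envs x year_month cells
    cols <- which(key$covariable == cv)
    raw[, cols] <- m[, key$ym[cols], drop = FALSE]
  }

  ctr <- colMeans(raw)
  scl <- apply(raw, 2, stats::sd)
  const <- scl == 0 | !is.finite(scl)
  scl_safe <- ifelse(const, 1, scl)
  z <- sweep(sweep(raw, 2, ctr), 2, scl_safe, "/")
  outl <- !const & apply(abs(z) > qc_sd, 2, any)
  removed <- c(
    stats::setNames(as.list(rep("zero variance across environments",
                                sum(const))), colnames(raw)[const]),
    stats::setNames(as.list(rep(sprintf("cell beyond %.4g SD", qc_sd),
                                sum(outl))), colnames(raw)[outl])
  )
  keep <- !const & !outl
  if (!any(keep)) stop("quality control removed every descriptor column",
                       call. = FALSE)

  structure(list(
    W = z[, keep, drop = FALSE],
    raw = raw,
    center = ctr, scale = scl,
    removed = removed,
    key = key,
    qc_sd = qc_sd
  ), class = "envirotype_matrix")
}

#' @export
print.envirotype_matrix <- function(x, ...) {
  cat(sprintf("Envirotype matrix: %d environments x %d descriptors (%d before QC, %d removed)\n",
              nrow(x$W), ncol(x$W), ncol(x$raw), length(x$removed)))
  invisible(x)
}

#' Enviromic kernel between environments
#'
#' Computes the environmental relationship matrix
#' \deqn{K_E = \frac{WW'}{\mathrm{trace}(WW')/n}}
#' from the (standardised) envirotype matrix `W` with `n` environments --
#' the environmental analogue of a genomic relationship matrix.  The
#' normalisation forces `trace(K_E)` to equal the number of environments.
#'
#' @param w an `envirotype_matrix` or a plain numeric matrix
#'   (environments x descriptors).
#' @return an object of class `enviromic_kernel`: list with `K`, the
#'   normalisation constant, and the environment names.
#' @export
enviromic_kernel <- function(w) {
  m <- if (inherits(w, "envirotype_matrix")) w$W else as.matrix(w)
  if (nrow(m) < 2) stop("at least 2 environments are required", call. = FALSE)
  ww <- tcrossprod(m)
  tr <- sum(diag(ww))
  if (tr <= 0) stop("all-zero envirotype matrix: kernel normalisation undefined",
                    call. = FALSE)
  norm <- tr / nrow(m)
  structure(list(K = ww / norm, normalization = norm,
                 environments = rownames(m)),
            class = "enviromic_kernel")
}

#' @export
print.enviromic_kernel <- function(x, ...) {
  cat(sprintf("Enviromic kernel over %d environments (trace = %.6g)\n",
              nrow(x$K), sum(diag(x$K))))
  invisible(x)
}

#' Delineate mega-environments from the enviromic kernel
#'
#' Converts the kernel to its induced Euclidean distance
#' `d(i,j) = sqrt(K_ii + K_jj - 2 K_ij)`, builds an average-linkage (UPGMA)
#' dendrogram and cuts it into `k` groups.  Labels `ME1..MEk` are assigned
#' in order of first appearance over the (alphabetically sorted)
#' environments, so the result is invariant to input ordering up to label
#' names.
#'
#' @param kernel an `enviromic_kernel`.
#' @param k number of mega-environments (default 4).
#' @return an object of class `me_assignment`: list with `assignment`
#'   (data frame `environment`, `ME`), the `hclust` tree, and `k`.
#' @export
delineate_mega_environments <- function(kernel, k = 4) {
  stopifnot(inherits(kernel, "enviromic_kernel"))
  K <- kernel$K
  n <- nrow(K)
  if (k < 1 || k > n) stop("'k' must be between 1 and the number of environments",
                           call. = FALSE)
  ord <- order(rownames(K))
  K <- K[ord, ord]
  dii <- diag(K)
  d2 <- outer(dii, dii, "+") - 2 * K
  d2[d2 < 0] <- 0                       # clip tiny negative rounding errors
  dd <- stats::as.dist(sqrt(d2))
  tree <- stats::hclust(dd, method = "average")
  grp <- stats::cutree(tree, k = k)
  labels <- paste0("ME", match(grp, unique(grp)))
  structure(list(
    assignment = data.frame(environment = names(grp), ME = labels,
                            stringsAsFactors = FALSE),
    tree = tree, k = k
  ), class = "me_assignment")
}

#' @export
print.me_assignment <- function(x, ...) {
  cat(sprintf("Mega-environment assignment (k = %d):\n", x$k))
  print(split(x$assignment$environment, x$assignment$ME))
  invisible(x)
}

#' Silhouette diagnostic for a candidate number of mega-environments
#'
#' Mean silhouette width of the UPGMA partition at each candidate `k`,
#' using the kernel-induced distance.  Offered as a diagnostic only; the
#' pipeline never auto-selects `k`.
#'
#' @param kernel an `enviromic_kernel`.
#' @param k_range candidate cluster counts.
#' @return data frame with columns `k` and `mean_silhouette`.
#' @export
me_silhouette <- function(kernel, k_range = 2:6) {
  stopifnot(inherits(kernel, "enviromic_kernel"))
  K <- kernel$K
  dii <- diag(K)
  d2 <- outer(dii, dii, "+") - 2 * K
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)
  res <- vapply(k_range, function(k) {
    asg <- delineate_mega_environments(kernel, k)$assignment
    lab <- asg$ME[match(rownames(dm), asg$environment)]
    sil <- vapply(seq_along(lab), function(i) {
      own <- lab == lab[i]
      a <- if (sum(own) > 1) mean(dm[i, own & seq_along(lab) != i]) else 0
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(g) mean(dm[i, lab == g]), numeric(1)))
      if (sum(own) == 1) return(0)
      (b - a) / max(a, b)
    }, numeric(1))
    mean(sil)
  }, numeric(1))
  data.frame(k = k_range, mean_silhouette = res)
}

#' Principal component ordination of environments
#'
#' Eigen-decomposition of the correlation matrix of an
#' environment x mean-covariable table, exporting scores, loadings and
#' explained-variance shares for biplots relating covariables to
#' environments.
#'
#' @param table numeric matrix or data frame, environments in rows and
#'   covariable means in columns.
#' @return list with `scores`, `loadings`, `eigenvalues`, `explained`
#'   (proportions summing to 1) and `dropped` (constant columns removed).
#' @export
environment_pca <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 3) stop("at least 3 environments are required", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  list(scores = pc$x, loadings = pc$rotation, eigenvalues = ev,
       explained = ev / sum(ev), dropped = dropped)
}

#' Mean-covariable table for ordination
#'
#' Per-environment means of each covariable over the growing window, the
#' two-way table fed to [environment_pca()].
#'
#' @param covariables a `covariable_data` frame.
#' @param covariable_set columns to include.
#' @return numeric matrix, environments x covariables.
#' @export
environment_means <- function(covariables,
                              covariable_set = .covariable_names()) {
  d <- covariables
  envs <- sort(unique(d$location))
  out <- vapply(covariable_set, function(cv) {
    tapply(d[[cv]], factor(d$location, levels = envs), mean)
  }, numeric(length(envs)))
  rownames(out) <- envs
  out
}
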