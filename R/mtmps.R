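# ---- factor-analytic multi-trait index (MTMPS) --------------------------

#' Exploratory factor analysis of the MPS table
#'
#' Principal-component extraction on the correlation matrix `R` of the
#' genotype x trait MPS table: initial loadings are the eigenvectors scaled
#' by the square roots of their eigenvalues; factors with eigenvalue above
#' the retention threshold (default 1) are kept and varimax-rotated (with
#' Kaiser row normalisation) into the canonical loadings `A`.  Genotype
#' scores are `F = Z (A' R^{-1})'` where `Z` is the column-standardised
#' table.  The ideotype -- the hypothetical genotype with MPS 100 for every
#' trait -- is passed through the same standardisation and scoring map.
#'
#' @param rM numeric genotype x trait matrix of MPS values (at least 2
#'   non-constant traits).  Constant columns are dropped with a warning.
#' @param retention eigenvalue threshold for factor retention (strictly
#'   greater than; default 1).  If no eigenvalue exceeds it, a single
#'   factor is retained with a warning.
#' @param ideotype target value per trait (default 100 for all).
#' @return an object of class `factor_model`: `R`, `eigenvalues`,
#'   `explained` (cumulative share of the retained factors),
#'   `loadings_initial`, `loadings` (rotated `A`), `communalities`,
#'   `scores` (`q x f`), `ideotype_scores`, `Z`, `center`, `scale`,
#'   `n_factors`, and `singular` (whether a pseudo-inverse of `R` was
#'   needed).
#' @export
factor_analysis <- function(rM, retention = 1, ideotype = 100) {
  m <- as.matrix(rM)
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%02d", seq_len(nrow(m)))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant trait column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  p <- ncol(m)
  if (p < 2) stop("factor analysis needs at least 2 non-constant traits",
                  call. = FALSE)
  if (nrow(m) <= p) {
    warning("fewer genotypes than traits + 1; factor solution may be unstable")
  }
  R <- stats::cor(m)
  eg <- eigen(R, symmetric = TRUE)
  ev <- eg$values
  f <- sum(ev > retention)
  if (f == 0) {
    warning("no eigenvalue exceeds the retention threshold; keeping 1 factor")
    f <- 1L
  }
  L <- eg$vectors[, seq_len(f), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(f)]), f, f)
  rownames(L) <- colnames(m)
  colnames(L) <- paste0("FA", seq_len(f))
  A <- if (f >= 2) {
    rot <- stats::varimax(L, normalize = TRUE)
    unclass(rot$loadings)
  } else L
  dimnames(A) <- dimnames(L)

  singular <- FALSE
  Rinv <- tryCatch(solve(R), error = function(e) {
    singular <<- TRUE
    # Moore-Penrose pseudo-inverse via the eigendecomposition of R
    pos <- ev > max(ev) * 1e-10
    eg$vectors[, pos, drop = FALSE] %*% diag(1 / ev[pos], sum(pos)) %*%
      t(eg$vectors[, pos, drop = FALSE])
  })

  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  Z <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  beta <- t(t(A) %*% Rinv)                 # p x f scoring coefficients
  scores <- Z %*% beta
  ideo <- rep_len(ideotype, p)
  z_ideo <- (ideo - ctr) / scl
  ideo_scores <- drop(z_ideo %*% beta)

  structure(list(
    R = R, eigenvalues = ev,
    explained = cumsum(ev)[f] / sum(ev),
    loadings_initial = L, loadings = A,
    communalities = rowSums(A^2),
    scores = scores, ideotype_scores = ideo_scores,
    Z = Z, center = ctr, scale = scl,
    n_factors = f, singular = singular
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Factor model: %d factors retained, %.1f%% of variance\n",
              x$n_factors, 100 * x$explained))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Multi-trait mean-performance-and-stability index
#'
#' Euclidean distance, in rotated factor-score space, between each genotype
#' and the ideotype (the all-100 MPS genotype):
#' \deqn{MTMPS_i = \left[\sum_{j=1}^f (F_{ij} - F_j^{ideo})^2\right]^{1/2}}
#' Lower values are better; a genotype whose MPS row equals the ideotype
#' scores 0.
#'
#' @param model a `factor_model` from [factor_analysis()].
#' @return named numeric vector of MTMPS values.
#' @export
mtmps <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  dev <- sweep(model$scores, 2, model$ideotype_scores)
  sqrt(rowSums(dev^2))
}

#' Select genotypes by MTMPS rank
#'
#' Sorts genotypes by ascending MTMPS (closest to the ideotype first) and
#' selects the top `round(intensity * q)`.  Ties are broken by genotype
#' label so the selection is deterministic.
#'
#' @param mtmps_values named MTMPS vector.
#' @param intensity selection intensity in (0, 1]; the default 6/26
#'   (about 23%) selects six genotypes out of 26.
#' @return data frame of class `me_selection`: `genotype`, `mtmps`, `rank`,
#'   `selected`, with the intensity as an attribute.
#' @export
select_genotypes <- function(mtmps_values, intensity = 6 / 26) {
  if (intensity <= 0 || intensity > 1) {
    stop("'intensity' must be in (0, 1]", call. = FALSE)
  }
  q <- length(mtmps_values)
  n_sel <- round(intensity * q)
  if (n_sel < 1) stop("selection intensity yields zero selections",
                      call. = FALSE)
  geno <- names(mtmps_values)
  if (is.null(geno)) geno <- sprintf("G%02d", seq_len(q))
  ord <- order(mtmps_values, geno)
  rk <- integer(q); rk[ord] <- seq_len(q)
  out <- data.frame(genotype = geno, mtmps = unname(mtmps_values),
                    rank = rk, selected = rk <= n_sel,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  structure(out, intensity = intensity, n_selected = n_sel,
            class = c("me_selection", "data.frame"))
}

#' Selection differentials for means and stability
#'
#' Percent change of the selected subset's mean relative to the population
#' mean, `dS% = (X_s - X_o) / X_o * 100`, computed per trait both on the
#' genotype trait means and on the ecovalence values (where negative
#' differentials -- increased stability -- are desired).  Each cell carries
#' a `desired` flag: the differential's sign agrees with the trait's
#' registered direction (means) or is negative (ecovalence).
#'
#' @param means genotype x trait matrix of within-ME means.
#' @param ecovalences genotype x trait matrix of `W_i` values.
#' @param selected character vector of selected genotype labels.
#' @param directions trait-direction registry.
#' @return list of two data frames (`means`, `stability`) with columns
#'   `trait`, `selected_mean`, `population_mean`, `ds_pct`, `desired`.
#' @export
selection_differentials <- function(means, ecovalences, selected,
                                    directions = trait_directions()) {
  means <- as.matrix(means)
  ecovalences <- as.matrix(ecovalences)
  if (!all(selected %in% rownames(means))) {
    stop("'selected' contains genotypes absent from the tables",
         call. = FALSE)
  }
  one <- function(mat, want_sign) {
    xs <- colMeans(mat[selected, , drop = FALSE])
    xo <- colMeans(mat)
    ds <- ifelse(xo == 0, NA_real_, (xs - xo) / xo * 100)
    dirs <- vapply(colnames(mat), .direction_of, character(1),
                   directions = directions)
    want <- if (is.null(want_sign)) ifelse(dirs == "increase", 1, -1)
            else rep(want_sign, ncol(mat))
    data.frame(trait = colnames(mat), selected_mean = unname(xs),
               population_mean = unname(xo), ds_pct = unname(ds),
               desired = unname(ifelse(is.na(ds), NA,
                                       ds == 0 | sign(ds) == want)),
               stringsAsFactors = FALSE)
  }
  list(means = one(means, NULL), stability = one(ecovalences, -1))
}

#' Cross-mega-environment selection membership
#'
#' Summarises, over a set of per-ME selections, in which MEs each genotype
#' is selected and how often -- the tabular analogue of a Venn diagram of
#' selected genotypes.
#'
#' @param selections named list of `me_selection` objects (names are ME
#'   labels).
#' @return data frame: `genotype`, `n_selected`, `mes`
#'   (comma-separated ME labels), sorted by descending membership.
#' @export
cross_me_summary <- function(selections) {
  if (length(selections) < 2) {
    stop("at least 2 mega-environments are required", call. = FALSE)
  }
  if (is.null(names(selections))) {
    names(selections) <- paste0("ME", seq_along(selections))
  }
  sel_sets <- lapply(selections, function(s) s$genotype[s$selected])
  geno <- sort(unique(unlist(lapply(selections, `[[`, "genotype"))))
  mes <- vapply(geno, function(g) {
    paste(names(sel_sets)[vapply(sel_sets, function(s) g %in% s, logical(1))],
          collapse = ",")
  }, character(1))
  n <- vapply(strsplit(mes, ","), function(x) sum(nzchar(x)), integer(1))
  out <- data.frame(genotype = geno, n_selected = n, mes = mes,
                    stringsAsFactors = FALSE)
  out[order(-out$n_selected, out$genotype), ]
}

#' Full within-mega-environment selection
#'
#' Chains [mps_table()], [factor_analysis()], [mtmps()],
#' [select_genotypes()] and [selection_differentials()] for one
#' mega-environment.
#'
#' @inheritParams mps_table
#' @param intensity selection intensity (default 6/26).
#' @param retention factor-retention threshold.
#' @return list with `tables` (from [mps_table()]), `model`, `mtmps`,
#'   `selection` and `differentials`.
#' @export
me_selection <- function(data, me, traits = NULL,
                         directions = trait_directions(),
                         theta_y = 70, theta_s = 30,
                         intensity = 6 / 26, retention = 1) {
  tabs <- mps_table(data, me, traits, directions, theta_y, theta_s)
  model <- factor_analysis(tabs$rM, retention = retention)
  dist <- mtmps(model)
  sel <- select_genotypes(dist, intensity)
  diffs <- selection_differentials(tabs$means, tabs$ecovalence,
                                   sel$genotype[sel$selected], directions)
  list(me = me, tables = tabs, model = model, mtmps = dist,
       selection = sel, differentials = diffs)
}
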