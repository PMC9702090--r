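#' @keywords internal
"_PACKAGE"

# Registry of the nine default agronomic traits and the direction in which
# selection improves each one.  Lower grain moisture, plant/ear height and
# bare tip length are desirable; all other traits are maximised.
.trait_registry <- data.frame(
  trait = c("GY", "GMC", "PH", "EH", "EL", "ER", "BTL", "GWE", "HSW"),
  direction = c("increase", "decrease", "decrease", "decrease",
                "increase", "increase", "decrease", "increase", "increase"),
  stringsAsFactors = FALSE
)

#' Default trait-direction registry
#'
#' Returns the registry mapping each analysed trait to the desired direction
#' of selection (`"increase"` or `"decrease"`).  Grain yield (GY), ear length
#' (EL), ear row number (ER), grain weight per ear (GWE) and 100-seed weight
#' (HSW) are maximised; grain moisture content (GMC), plant height (PH),
#' ear height (EH) and bare tip length (BTL) are minimised.
#'
#' @param traits optional character vector restricting (and ordering) the
#'   registry to a subset of traits.
#' @return a data frame with columns `trait` and `direction`.
#' @export
trait_directions <- function(traits = NULL) {
  reg <- .trait_registry
  if (is.null(traits)) return(reg)
  missing <- setdiff(traits, reg$trait)
  if (length(missing)) {
    stop("no registered direction for trait(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  reg[match(traits, reg$trait), , drop = FALSE]
}

# look up a single trait's direction, validating it exists
.direction_of <- function(trait, directions = trait_directions()) {
  i <- match(trait, directions$trait)
  if (is.na(i)) {
    stop("trait '", trait, "' has no registered selection direction",
         call. = FALSE)
  }
  directions$direction[i]
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# derive a bounded child seed from a base seed and a stage label, so that
# every pipeline stage consumes an independent, reproducible stream
.child_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + offs * 1009) %% .Machine$integer.max)
}
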