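#' Multivariate environmental similarity: single-variable component
#'
#' Similarity of a projection value `p` to a reference sample of one
#' climate variable. With `f` the percentage of reference values strictly
#' below `p` (ties at `p` count as not-below):
#' \itemize{
#'   \item `f = 0`: `100 * (p - min) / (max - min)` (negative below the
#'     reference minimum),
#'   \item `0 < f <= 50`: `2 f`,
#'   \item `50 < f < 100`: `2 (100 - f)`,
#'   \item `f = 100`: `100 * (max - p) / (max - min)` (negative above the
#'     reference maximum).
#' }
#' Values are `<= 100`, with 100 only at the reference median; negative
#' values flag non-analogue conditions.
#'
#' @param reference_values Numeric reference sample (non-empty).
#' @param p Numeric projection value(s); vectorised.
#' @return Numeric component value(s). A degenerate constant reference gives
#'   0 where `p` equals the constant and a `-1e9` sentinel (with a warning)
#'   elsewhere.
#' @export
mess_component <- function(reference_values, p) {
  reference_values <- reference_values[!is.na(reference_values)]
  if (!length(reference_values)) stop("empty reference sample")
  lo <- min(reference_values); hi <- max(reference_values)
  if (hi == lo) {
    out <- ifelse(p == lo, 0, -1e9)
    if (any(p != lo, na.rm = TRUE)) {
      warning("constant reference sample: non-matching points set to -1e9")
    }
    return(out)
  }
  srt <- sort(reference_values)
  n <- length(srt)
  f <- 100 * findInterval(p, srt, left.open = TRUE) / n  # strictly below
  out <- numeric(length(p))
  out[f == 0] <- 100 * (p[f == 0] - lo) / (hi - lo)
  mid_lo <- f > 0 & f <= 50
  out[mid_lo] <- 2 * f[mid_lo]
  mid_hi <- f > 50 & f < 100
  out[mid_hi] <- 2 * (100 - f[mid_hi])
  out[f == 100] <- 100 * (hi - p[f == 100]) / (hi - lo)
  out[is.na(p)] <- NA_real_
  out
}

#' Multivariate environmental similarity surface (MESS)
#'
#' Screens projection climate against the calibration climate sample. The
#' per-cell similarity is the minimum over variables of [mess_component];
#' negative similarity flags non-analogue climate (at least one variable
#' outside the calibration range). Used chiefly to qualify reference-area
#' projections, whose calibration climate space is deliberately restricted.
#'
#' @param calibration_layers [climate_layers] providing the reference
#'   sample; optionally restricted via `calibration_cells`.
#' @param projection_layers [climate_layers] to screen (same variable
#'   names; need not share the grid with the calibration sample).
#' @param calibration_cells Optional cell ids restricting the calibration
#'   sample (e.g. the model-building cells of the approach under scrutiny).
#' @return An object of class `mess_map`: list with `grid` (projection
#'   grid), `similarity` (per-cell minimum), `components` (cells x
#'   variables matrix), and `most_dissimilar` (argmin variable per cell,
#'   ties broken lexicographically).
#' @export
mess_map <- function(calibration_layers, projection_layers,
                     calibration_cells = NULL) {
  stopifnot(inherits(calibration_layers, "climate_layers"),
            inherits(projection_layers, "climate_layers"))
  vars <- names(calibration_layers$variables)
  if (!setequal(vars, names(projection_layers$variables))) {
    stop("variable names differ between calibration and projection layers")
  }
  ref_idx <- if (is.null(calibration_cells)) {
    which(calibration_layers$observed)
  } else {
    i <- match(calibration_cells, calibration_layers$grid$cell_ids)
    if (anyNA(i)) stop("unknown calibration cell id(s)")
    i[calibration_layers$observed[i]]
  }
  if (!length(ref_idx)) stop("empty calibration sample")
  vars <- sort(vars)  # lexicographic order fixes argmin tie-breaks
  comp <- sapply(vars, function(v) {
    mess_component(calibration_layers$variables[[v]][ref_idx],
                   projection_layers$variables[[v]])
  })
  comp <- matrix(as.vector(comp), ncol = length(vars),
                 dimnames = list(NULL, vars))
  sim <- apply(comp, 1L, function(r) if (all(is.na(r))) NA_real_ else min(r))
  worst <- apply(comp, 1L, function(r) {
    if (all(is.na(r))) NA_character_ else vars[which.min(r)]
  })
  structure(list(grid = projection_layers$grid, similarity = sim,
                 components = comp, most_dissimilar = worst),
            class = "mess_map")
}

#' @export
print.mess_map <- function(x, ...) {
  neg <- mean(x$similarity < 0, na.rm = TRUE)
  cat("<mess_map> ", ncol(x$components), " variable(s); ",
      round(100 * neg, 1), "% of cells non-analogue (similarity < 0)\n",
      sep = "")
  invisible(x)
}
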