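#' Regular analysis grid
#'
#' A grid is the common spatial frame shared by every layer, occurrence map
#' and projection in an analysis. Cells are stored in row-major order with
#' 0-based (row, col) indices; all range sizes downstream are cell counts
#' (cells are treated as equal-weight).
#'
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param cell_ids Optional character vector of unique cell identifiers in
#'   row-major order; defaults to `"r<row>_c<col>"`.
#' @param geo_transform Optional numeric vector of length 6
#'   `(x0, dx_col, dx_row, y0, dy_col, dy_row)` mapping (row, col) to map
#'   coordinates. Purely metadata; never used in computation.
#' @return An object of class `sdm_grid`.
#' @export
sdm_grid <- function(n_rows, n_cols, cell_ids = NULL, geo_transform = NULL) {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L,
            n_rows >= 1, n_cols >= 1,
            n_rows == as.integer(n_rows), n_cols == as.integer(n_cols))
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  if (is.null(cell_ids)) {
    rc <- cell_row_col(n_rows, n_cols)
    cell_ids <- sprintf("r%d_c%d", rc$row, rc$col)
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n) {
    stop("grid requires ", n, " cell_ids (n_rows x n_cols), got ",
         length(cell_ids))
  }
  if (anyDuplicated(cell_ids)) {
    stop("cell_ids must be unique; duplicated: ",
         paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 5L),
               collapse = ", "))
  }
  if (!is.null(geo_transform)) {
    stopifnot(is.numeric(geo_transform), length(geo_transform) == 6L)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_ids = cell_ids,
                 geo_transform = geo_transform),
            class = "sdm_grid")
}

#' Number of cells in a grid or gridded object
#' @param x An `sdm_grid` or any gridded object.
#' @return Integer cell count.
#' @export
n_cells <- function(x) {
  g <- grid_of(x)
  g$n_rows * g$n_cols
}

# 0-based (row, col) for each cell in row-major order
cell_row_col <- function(n_rows, n_cols) {
  idx <- seq_len(n_rows * n_cols) - 1L
  list(row = idx %/% n_cols, col = idx %% n_cols)
}

#' Extract the grid of a gridded object
#' @param x A gridded object (`sdm_grid`, `climate_layers`, `occurrence_map`,
#'   `suitability_map`, `binary_range_map`, or `mess_map`).
#' @return The underlying `sdm_grid`.
#' @export
grid_of <- function(x) {
  if (inherits(x, "sdm_grid")) return(x)
  if (!is.null(x$grid) && inherits(x$grid, "sdm_grid")) return(x$grid)
  stop("not a gridded object: ", paste(class(x), collapse = "/"))
}

#' Assert that two gridded objects share the same grid
#'
#' All cross-layer arithmetic in the package goes through this check, so no
#' operation can silently combine values from different grids. The error
#' names the first discrepancy (dimensions, then cell ids).
#'
#' @param a,b Gridded objects.
#' @return Invisibly `TRUE` on success; otherwise an error.
#' @export
assert_aligned <- function(a, b) {
  ga <- grid_of(a); gb <- grid_of(b)
  if (ga$n_rows != gb$n_rows || ga$n_cols != gb$n_cols) {
    stop("grid alignment error: dimensions ", ga$n_rows, "x", ga$n_cols,
         " vs ", gb$n_rows, "x", gb$n_cols)
  }
  neq <- which(ga$cell_ids != gb$cell_ids)
  if (length(neq)) {
    i <- neq[1L]
    stop("grid alignment error: cell_ids differ first at position ", i,
         " ('", ga$cell_ids[i], "' vs '", gb$cell_ids[i], "')")
  }
  invisible(TRUE)
}

#' Set of co-registered climate layers
#'
#' Holds one value per cell for each named climate variable, tagged with a
#' period label. Missing values propagate across variables: a cell missing
#' any variable is masked in all of them, so a cell is either fully observed
#' or excluded.
#'
#' @param grid An `sdm_grid`.
#' @param period Period label, e.g. `"current"` or `"future"`.
#' @param variables Named list (or data.frame) of numeric vectors, one value
#'   per cell in row-major order.
#' @return An object of class `climate_layers` with elements `grid`,
#'   `period`, `variables` (named list of numeric vectors with unified NA
#'   mask) and `observed` (logical per-cell mask).
#' @export
climate_layers <- function(grid, period, variables) {
  stopifnot(inherits(grid, "sdm_grid"))
  variables <- lapply(variables, as.numeric)
  if (is.null(names(variables)) || any(!nzchar(names(variables))) ||
      anyDuplicated(names(variables))) {
    stop("variables must have unique non-empty names")
  }
  n <- grid$n_rows * grid$n_cols
  bad <- names(variables)[vapply(variables, length, 1L) != n]
  if (length(bad)) {
    stop("variable(s) ", paste(bad, collapse = ", "),
         " do not have one value per cell (", n, ")")
  }
  observed <- Reduce(`&`, lapply(variables, function(v) !is.na(v)),
                     rep(TRUE, n))
  variables <- lapply(variables, function(v) { v[!observed] <- NA_real_; v })
  structure(list(grid = grid, period = as.character(period)[1L],
                 variables = variables, observed = observed),
            class = "climate_layers")
}

#' Add or replace a variable in a climate layer set
#'
#' Used by the explanatory-variable coupling scheme to append a host
#' occurrence-probability layer as an ordinary predictor.
#'
#' @param layers A `climate_layers` object.
#' @param name Variable name.
#' @param values Numeric vector, one value per cell.
#' @return A new `climate_layers` with the variable added (mask re-unified).
#' @export
add_variable <- function(layers, name, values) {
  stopifnot(inherits(layers, "climate_layers"))
  v <- layers$variables
  v[[name]] <- values
  climate_layers(layers$grid, layers$period, v)
}

#' Presence/absence occurrence map for one species
#'
#' @param grid An `sdm_grid`.
#' @param species Species label.
#' @param status Character (or factor) vector with one entry per cell, each
#'   `"present"`, `"absent"` or `"unknown"`. Unknown cells are excluded from
#'   model fitting and prevalence but may still receive projections.
#' @return An object of class `occurrence_map`.
#' @export
occurrence_map <- function(grid, species, status) {
  stopifnot(inherits(grid, "sdm_grid"))
  status <- as.character(status)
  n <- grid$n_rows * grid$n_cols
  if (length(status) != n) {
    stop("status must have one entry per cell (", n, "), got ", length(status))
  }
  bad <- setdiff(unique(status), c("present", "absent", "unknown"))
  if (length(bad)) {
    stop("invalid status value(s): ", paste(bad, collapse = ", "))
  }
  structure(list(grid = grid, species = as.character(species)[1L],
                 status = status),
            class = "occurrence_map")
}

#' Prevalence of an occurrence map
#'
#' Fraction of present cells among surveyed (present or absent) cells,
#' optionally restricted to a subset of cell ids.
#'
#' @param occurrence An `occurrence_map`.
#' @param cells Optional character vector of cell ids to restrict to.
#' @return Prevalence in `[0, 1]`.
#' @export
prevalence <- function(occurrence, cells = NULL) {
  st <- occurrence_subset_status(occurrence, cells)
  known <- st != "unknown"
  if (!any(known)) stop("no surveyed cells")
  sum(st == "present") / sum(known)
}

occurrence_subset_status <- function(occurrence, cells = NULL) {
  stopifnot(inherits(occurrence, "occurrence_map"))
  if (is.null(cells)) return(occurrence$status)
  idx <- match(cells, occurrence$grid$cell_ids)
  if (anyNA(idx)) {
    stop("unknown cell id(s): ",
         paste(utils::head(cells[is.na(idx)], 5L), collapse = ", "))
  }
  occurrence$status[idx]
}

#' Per-cell occurrence probability map
#'
#' @param grid An `sdm_grid`.
#' @param species Species label.
#' @param period Period label.
#' @param probability Numeric vector of probabilities in `[0, 1]` (NA at
#'   missing cells), one per cell.
#' @param source Model or ensemble identifier.
#' @return An object of class `suitability_map`.
#' @export
suitability_map <- function(grid, species, period, probability,
                            source = "unspecified") {
  stopifnot(inherits(grid, "sdm_grid"))
  probability <- as.numeric(probability)
  n <- grid$n_rows * grid$n_cols
  if (length(probability) != n) {
    stop("probability must have one value per cell (", n, ")")
  }
  ok <- is.na(probability) | (probability >= 0 & probability <= 1)
  if (!all(ok)) {
    stop("probabilities outside [0, 1] at ", sum(!ok), " cell(s)")
  }
  structure(list(grid = grid, species = as.character(species)[1L],
                 period = as.character(period)[1L],
                 probability = probability, source = as.character(source)[1L]),
            class = "suitability_map")
}

#' Thresholded presence/absence range map
#'
#' @param grid An `sdm_grid`.
#' @param species Species label.
#' @param period Period label.
#' @param presence Logical vector per cell (NA at missing cells).
#' @param threshold The probability cutoff that produced the map.
#' @return An object of class `binary_range_map`.
#' @export
binary_range_map <- function(grid, species, period, presence, threshold) {
  stopifnot(inherits(grid, "sdm_grid"), is.numeric(threshold),
            length(threshold) == 1L)
  presence <- as.logical(presence)
  n <- grid$n_rows * grid$n_cols
  if (length(presence) != n) {
    stop("presence must have one value per cell (", n, ")")
  }
  structure(list(grid = grid, species = as.character(species)[1L],
                 period = as.character(period)[1L],
                 presence = presence, threshold = as.numeric(threshold)),
            class = "binary_range_map")
}

#' @export
print.sdm_grid <- function(x, ...) {
  cat("<sdm_grid> ", x$n_rows, " x ", x$n_cols, " (",
      x$n_rows * x$n_cols, " cells)\n", sep = "")
  invisible(x)
}

#' @export
print.climate_layers <- function(x, ...) {
  cat("<climate_layers> period=", x$period, ", ",
      length(x$variables), " variable(s): ",
      paste(names(x$variables), collapse = ", "),
      "; ", sum(!x$observed), " masked cell(s) of ",
      length(x$observed), "\n", sep = "")
  invisible(x)
}

#' @export
print.occurrence_map <- function(x, ...) {
  tab <- table(factor(x$status, c("present", "absent", "unknown")))
  cat("<occurrence_map> ", x$species, ": ", tab[["present"]], " present, ",
      tab[["absent"]], " absent, ", tab[["unknown"]], " unknown\n", sep = "")
  invisible(x)
}

#' @export
print.suitability_map <- function(x, ...) {
  cat("<suitability_map> ", x$species, " [", x$period, "] from ", x$source,
      "; mean p=", signif(mean(x$probability, na.rm = TRUE), 3), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.binary_range_map <- function(x, ...) {
  cat("<binary_range_map> ", x$species, " [", x$period, "] threshold=",
      signif(x$threshold, 3), "; ", sum(x$presence, na.rm = TRUE),
      " presence cell(s)\n", sep = "")
  invisible(x)
}
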