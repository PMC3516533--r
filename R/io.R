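#' Read a climate layer set from disk
#'
#' CSV layout: one row per cell with columns `cell_id`, `row`, `col`
#' (0-based) and one column per variable, in row-major order or any order
#' (rows are sorted by (row, col)). The `tiff` format stores one 32-bit
#' float plane per variable, min-max scaled to `[0, 1]`, with a JSON sidecar
#' (`<path>.json`) carrying variable names, scaling, the missing mask, cell
#' ids and the period label.
#'
#' @param path File path.
#' @param format `"csv"` or `"tiff"`.
#' @return A [climate_layers] object.
#' @export
read_layers <- function(path, format = c("csv", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_layers_csv(path) else read_layers_tiff(path)
}

read_cell_table <- function(path, value_cols_required = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "row", "col", value_cols_required)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id(s): ",
         paste(utils::head(unique(df$cell_id[duplicated(df$cell_id)]), 5L),
               collapse = ", "))
  }
  n_rows <- max(df$row) + 1L
  n_cols <- max(df$col) + 1L
  # detect ragged grids before constructing anything
  have <- paste(df$row, df$col)
  rc <- cell_row_col(n_rows, n_cols)
  want <- paste(rc$row, rc$col)
  missing_pos <- setdiff(want, have)
  if (length(missing_pos)) {
    stop("ragged grid: ", length(missing_pos), " missing cell(s) at (row col): ",
         paste(utils::head(missing_pos, 10L), collapse = "; "))
  }
  df <- df[order(df$row, df$col), , drop = FALSE]
  list(df = df, n_rows = n_rows, n_cols = n_cols)
}

read_layers_csv <- function(path) {
  tab <- read_cell_table(path)
  df <- tab$df
  grid <- sdm_grid(tab$n_rows, tab$n_cols, cell_ids = df$cell_id)
  vars <- setdiff(names(df), c("cell_id", "row", "col"))
  if (!length(vars)) stop("CSV contains no variable columns")
  meta <- read_sidecar(path, required = FALSE)
  period <- if (!is.null(meta$period)) meta$period else "unspecified"
  climate_layers(grid, period, df[vars])
}

#' Write a gridded object to disk
#'
#' Dispatches on the object type: [climate_layers], [suitability_map] and
#' [binary_range_map] are all supported, in both formats. Binary maps are
#' written as 0/1 with the threshold recorded in the JSON sidecar; CSV
#' round-trips are lossless, TIFF round-trips preserve values to about
#' 1e-9 of the variable range.
#'
#' @param x The object to write.
#' @param path Output file path (sidecar written as `<path>.json`).
#' @param format `"csv"` or `"tiff"`.
#' @return Invisibly, `path`.
#' @export
write_layers <- function(x, path, format = c("csv", "tiff")) {
  if (!is.character(format) || !all(format %in% c("csv", "tiff"))) {
    stop("unsupported format: ", paste(format, collapse = ", "))
  }
  format <- match.arg(format)
  UseMethod("write_layers")
}

grid_cols_df <- function(grid) {
  rc <- cell_row_col(grid$n_rows, grid$n_cols)
  data.frame(cell_id = grid$cell_ids, row = rc$row, col = rc$col,
             stringsAsFactors = FALSE)
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path, required = TRUE) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) {
    if (required) stop("sidecar not found: ", sc)
    return(NULL)
  }
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' @export
write_layers.climate_layers <- function(x, path, format = c("csv", "tiff")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- cbind(grid_cols_df(x$grid), as.data.frame(x$variables))
    utils::write.csv(df, path, row.names = FALSE)
    write_sidecar(path, list(type = "climate_layers", period = x$period,
                             geo_transform = x$grid$geo_transform))
  } else {
    write_tiff_planes(x$grid, x$variables, path,
                      list(type = "climate_layers", period = x$period))
  }
  invisible(path)
}

#' @export
write_layers.suitability_map <- function(x, path, format = c("csv", "tiff")) {
  format <- match.arg(format)
  meta <- list(type = "suitability_map", species = x$species,
               period = x$period, source = x$source)
  if (format == "csv") {
    df <- cbind(grid_cols_df(x$grid),
                data.frame(probability = x$probability))
    utils::write.csv(df, path, row.names = FALSE)
    write_sidecar(path, meta)
  } else {
    write_tiff_planes(x$grid, list(probability = x$probability), path, meta)
  }
  invisible(path)
}

#' @export
write_layers.binary_range_map <- function(x, path, format = c("csv", "tiff")) {
  format <- match.arg(format)
  meta <- list(type = "binary_range_map", species = x$species,
               period = x$period, threshold = x$threshold)
  if (format == "csv") {
    df <- cbind(grid_cols_df(x$grid),
                data.frame(presence = as.integer(x$presence)))
    utils::write.csv(df, path, row.names = FALSE)
    write_sidecar(path, meta)
  } else {
    write_tiff_planes(x$grid, list(presence = as.numeric(x$presence)),
                      path, meta)
  }
  invisible(path)
}

#' Read a suitability map written by [write_layers]
#' @param path File path.
#' @param format `"csv"` or `"tiff"`.
#' @return A [suitability_map].
#' @export
read_suitability <- function(path, format = c("csv", "tiff")) {
  format <- match.arg(format)
  meta <- read_sidecar(path)
  if (!identical(meta$type, "suitability_map")) {
    stop("sidecar does not describe a suitability_map")
  }
  if (format == "csv") {
    tab <- read_cell_table(path, "probability")
    grid <- sdm_grid(tab$n_rows, tab$n_cols, cell_ids = tab$df$cell_id)
    p <- tab$df$probability
  } else {
    dat <- read_tiff_planes(path)
    grid <- dat$grid
    p <- dat$variables[["probability"]]
    p <- pmin(pmax(p, 0), 1)  # undo float round-off at the boundaries
  }
  suitability_map(grid, meta$species, meta$period, p, meta$source)
}

#' Read a binary range map written by [write_layers]
#' @param path File path.
#' @param format `"csv"` or `"tiff"`.
#' @return A [binary_range_map].
#' @export
read_binary <- function(path, format = c("csv", "tiff")) {
  format <- match.arg(format)
  meta <- read_sidecar(path)
  if (!identical(meta$type, "binary_range_map")) {
    stop("sidecar does not describe a binary_range_map")
  }
  if (format == "csv") {
    tab <- read_cell_table(path, "presence")
    grid <- sdm_grid(tab$n_rows, tab$n_cols, cell_ids = tab$df$cell_id)
    pres <- as.logical(tab$df$presence)
  } else {
    dat <- read_tiff_planes(path)
    grid <- dat$grid
    pres <- as.logical(round(dat$variables[["presence"]]))
  }
  binary_range_map(grid, meta$species, meta$period, pres, meta$threshold)
}

# ---- TIFF backend ---------------------------------------------------------
# Multi-plane 32-bit float TIFF; float TIFF safely stores [0,1] only, so
# each plane is min-max scaled and the scaling recorded in the sidecar.

write_tiff_planes <- function(grid, variables, path, meta) {
  nr <- grid$n_rows; nc <- grid$n_cols
  arr <- array(0, dim = c(nr, nc, length(variables)))
  scaling <- vector("list", length(variables))
  missing_idx <- which(Reduce(`|`, lapply(variables, is.na),
                              rep(FALSE, nr * nc)))
  for (i in seq_along(variables)) {
    v <- variables[[i]]
    lo <- suppressWarnings(min(v, na.rm = TRUE))
    hi <- suppressWarnings(max(v, na.rm = TRUE))
    if (!is.finite(lo)) { lo <- 0; hi <- 1 }
    s <- if (hi > lo) (v - lo) / (hi - lo) else rep(0.5, length(v))
    s[is.na(s)] <- 0
    arr[, , i] <- matrix(s, nr, nc, byrow = TRUE)
    scaling[[i]] <- list(name = names(variables)[i], lo = lo, hi = hi)
  }
  suppressWarnings(tiff::writeTIFF(arr, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  meta$variables <- scaling
  meta$n_rows <- nr
  meta$n_cols <- nc
  meta$cell_ids <- grid$cell_ids
  meta$missing_idx <- missing_idx
  meta$geo_transform <- grid$geo_transform
  write_sidecar(path, meta)
}

read_tiff_planes <- function(path) {
  meta <- read_sidecar(path)
  arr <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  nr <- meta$n_rows; nc <- meta$n_cols
  gt <- meta$geo_transform
  grid <- sdm_grid(nr, nc, cell_ids = meta$cell_ids,
                   geo_transform = if (length(gt)) gt else NULL)
  vars <- list()
  specs <- meta$variables
  if (is.data.frame(specs)) {
    specs <- lapply(seq_len(nrow(specs)), function(i) as.list(specs[i, ]))
  }
  for (i in seq_along(specs)) {
    s <- as.vector(t(arr[, , i]))
    lo <- specs[[i]]$lo; hi <- specs[[i]]$hi
    v <- if (hi > lo) lo + s * (hi - lo) else rep(lo, length(s))
    if (length(meta$missing_idx)) v[meta$missing_idx] <- NA_real_
    vars[[specs[[i]]$name]] <- v
  }
  list(grid = grid, variables = vars, meta = meta)
}

read_layers_tiff <- function(path) {
  dat <- read_tiff_planes(path)
  period <- if (!is.null(dat$meta$period)) dat$meta$period else "unspecified"
  climate_layers(dat$grid, period, dat$variables)
}

#' Write an occurrence map to CSV
#'
#' One row per cell with a `status` column (`present`/`absent`/`unknown`)
#' and a JSON sidecar recording the species.
#'
#' @param x An [occurrence_map].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_occurrence <- function(x, path) {
  stopifnot(inherits(x, "occurrence_map"))
  df <- cbind(grid_cols_df(x$grid), data.frame(status = x$status))
  utils::write.csv(df, path, row.names = FALSE)
  write_sidecar(path, list(type = "occurrence_map", species = x$species))
  invisible(path)
}

#' Read an occurrence map written by [write_occurrence]
#' @param path File path.
#' @return An [occurrence_map].
#' @export
read_occurrence <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "occurrence_map")) {
    stop("sidecar does not describe an occurrence_map")
  }
  tab <- read_cell_table(path, "status")
  grid <- sdm_grid(tab$n_rows, tab$n_cols, cell_ids = tab$df$cell_id)
  occurrence_map(grid, meta$species, tab$df$status)
}
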