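#' Range-change accounting against the observed current range
#'
#' Gains are projected-suitable future cells where the species is currently
#' absent; losses are currently occupied cells projected unsuitable; both
#' are reported relative to the number of currently occupied cells, so
#' percentages above 100 are expected under strong expansion. Cells with
#' unknown current status are excluded from gains/losses; those of them
#' projected suitable are reported separately as `n_gain_unknown`.
#'
#' @param current_observed Observed current [occurrence_map].
#' @param future_binary Projected future [binary_range_map].
#' @return An object of class `range_change_summary`: `n_current` (C),
#'   `n_gain` (G), `n_loss` (L), `n_stable` (C - L), `gain_pct` (100 G / C),
#'   `loss_pct` (100 L / C), `relative_change` ((G - L) / C), and
#'   `n_gain_unknown`.
#' @export
range_change <- function(current_observed, future_binary) {
  stopifnot(inherits(current_observed, "occurrence_map"),
            inherits(future_binary, "binary_range_map"))
  assert_aligned(current_observed, future_binary)
  st <- current_observed$status
  fut <- future_binary$presence
  fut[is.na(fut)] <- FALSE
  C <- sum(st == "present")
  if (C == 0L) stop("no currently occupied cells; percentages undefined")
  G <- sum(st == "absent" & fut)
  L <- sum(st == "present" & !fut)
  structure(list(n_current = C, n_gain = G, n_loss = L, n_stable = C - L,
                 gain_pct = 100 * G / C, loss_pct = 100 * L / C,
                 relative_change = (G - L) / C,
                 n_gain_unknown = sum(st == "unknown" & fut)),
            class = "range_change_summary")
}

#' @export
print.range_change_summary <- function(x, ...) {
  cat("<range_change> C=", x$n_current, " gain=", x$n_gain, " (",
      round(x$gain_pct, 1), "%) loss=", x$n_loss, " (",
      round(x$loss_pct, 1), "%) relative change=",
      round(x$relative_change, 3), "\n", sep = "")
  invisible(x)
}

#' 2-D binned gain/loss summary over two climate variables
#'
#' Counts gained and lost cells in an `n_bins x n_bins` grid of equal-width
#' bins spanning each variable's observed range (all non-missing cells);
#' the final bin is right-closed. Intended for the two most
#' range-influencing variables as ranked by [rank_variables].
#'
#' @param current_observed Observed current [occurrence_map].
#' @param future_binary Projected future [binary_range_map].
#' @param layers [climate_layers] providing the binning variables.
#' @param v1,v2 Variable names in `layers`.
#' @param n_bins Number of bins per variable (default 20).
#' @return An object of class `binned_gain_loss`: variable names, bin
#'   `edges1`/`edges2`, and integer matrices `gain` and `loss`
#'   (`v1` bins x `v2` bins).
#' @export
binned_gain_loss <- function(current_observed, future_binary, layers,
                             v1, v2, n_bins = 20L) {
  stopifnot(inherits(layers, "climate_layers"))
  assert_aligned(current_observed, layers)
  assert_aligned(future_binary, layers)
  for (v in c(v1, v2)) {
    if (!v %in% names(layers$variables)) stop("variable not in layers: ", v)
  }
  edges_of <- function(v) {
    x <- layers$variables[[v]]
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
    if (hi == lo) {
      warning("constant variable '", v, "': single bin")
      return(c(lo, lo))
    }
    seq(lo, hi, length.out = n_bins + 1L)
  }
  e1 <- edges_of(v1); e2 <- edges_of(v2)
  nb1 <- length(e1) - 1L; nb2 <- length(e2) - 1L
  bin_of <- function(x, e) {
    pmin(pmax(findInterval(x, e, rightmost.closed = TRUE), 1L),
         length(e) - 1L)
  }
  st <- current_observed$status
  fut <- future_binary$presence
  fut[is.na(fut)] <- FALSE
  obs <- layers$observed
  gain_cells <- which(st == "absent" & fut & obs)
  loss_cells <- which(st == "present" & !fut & obs)
  count_bins <- function(cells) {
    m <- matrix(0L, nb1, nb2)
    if (length(cells)) {
      b1 <- bin_of(layers$variables[[v1]][cells], e1)
      b2 <- bin_of(layers$variables[[v2]][cells], e2)
      for (i in seq_along(cells)) m[b1[i], b2[i]] <- m[b1[i], b2[i]] + 1L
    }
    m
  }
  structure(list(v1 = v1, v2 = v2, edges1 = e1, edges2 = e2,
                 gain = count_bins(gain_cells),
                 loss = count_bins(loss_cells)),
            class = "binned_gain_loss")
}

#' Long-format data frame of a binned gain/loss summary
#' @param x A `binned_gain_loss` object.
#' @param ... Unused.
#' @return data.frame with bin bounds and per-bin gain/loss counts.
#' @export
as.data.frame.binned_gain_loss <- function(x, ...) {
  nb1 <- nrow(x$gain); nb2 <- ncol(x$gain)
  idx <- expand.grid(i = seq_len(nb1), j = seq_len(nb2))
  data.frame(v1_bin_lo = x$edges1[idx$i], v1_bin_hi = x$edges1[idx$i + 1L],
             v2_bin_lo = x$edges2[idx$j], v2_bin_hi = x$edges2[idx$j + 1L],
             n_gain = x$gain[cbind(idx$i, idx$j)],
             n_loss = x$loss[cbind(idx$i, idx$j)])
}

#' Plot a binned gain/loss summary
#'
#' Convenience image of per-bin gains (upper panel) and losses (lower
#' panel) over the two binning variables.
#'
#' @param x A `binned_gain_loss` object.
#' @param ... Passed to [graphics::image].
#' @return Invisibly, `x`.
#' @export
plot.binned_gain_loss <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  mids <- function(e) (e[-1] + e[-length(e)]) / 2
  graphics::image(mids(x$edges1), mids(x$edges2), x$gain,
                  xlab = x$v1, ylab = x$v2, main = "gained cells", ...)
  graphics::image(mids(x$edges1), mids(x$edges2), x$loss,
                  xlab = x$v1, ylab = x$v2, main = "lost cells", ...)
  invisible(x)
}

#' Range-change table across approaches
#'
#' One [range_change] row per approach result, against a common observed
#' current range.
#'
#' @param results Named list of `approach_result` objects (names used as
#'   the approach column when present).
#' @param current_observed Observed current [occurrence_map].
#' @return data.frame with columns approach, n_current, n_gain, n_loss,
#'   gain_pct, loss_pct, relative_change.
#' @export
change_table <- function(results, current_observed) {
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    s <- range_change(current_observed, r$binary$future)
    data.frame(approach = if (!is.null(names(results)) &&
                              nzchar(names(results)[i])) {
                 names(results)[i]
               } else r$approach,
               n_current = s$n_current, n_gain = s$n_gain,
               n_loss = s$n_loss, gain_pct = s$gain_pct,
               loss_pct = s$loss_pct, relative_change = s$relative_change)
  })
  do.call(rbind, rows)
}
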