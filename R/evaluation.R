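#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = (#concordant pairs + 0.5 #tied pairs) / (n_presences * n_absences)`,
#' computed from average ranks in O(n log n).
#'
#' @param scores Numeric scores (probabilities) per cell.
#' @param labels Character vector of `"present"`/`"absent"` (or logical),
#'   same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "present", "absent")
  keep <- !is.na(scores) & labels %in% c("present", "absent")
  scores <- scores[keep]; labels <- labels[keep]
  n_p <- sum(labels == "present")
  n_a <- sum(labels == "absent")
  if (n_p == 0L || n_a == 0L) {
    stop("AUC requires at least one presence and one absence")
  }
  r <- rank(scores)  # average ranks handle ties as 0.5
  (sum(r[labels == "present"]) - n_p * (n_p + 1) / 2) / (n_p * n_a)
}

#' Prevalence threshold from model-building data
#'
#' The occurrence threshold equal to the prevalence of the model-building
#' cells: `#present / (#present + #absent)`.
#'
#' @param occurrence An [occurrence_map].
#' @param cells Model-building cell ids; all must have known status.
#' @return Threshold in `[0, 1]`.
#' @export
prevalence_threshold <- function(occurrence, cells) {
  if (!length(cells)) stop("empty cell set")
  st <- occurrence_subset_status(occurrence, cells)
  if (any(st == "unknown")) {
    stop("prevalence threshold requires cells with known status")
  }
  sum(st == "present") / length(st)
}

#' Mean-predicted-probability threshold
#'
#' The alternative thresholding rule: choose the cutoff so that the
#' resulting prevalence (fraction of cells predicted present) equals the
#' mean predicted occurrence probability as closely as possible. Implemented
#' by exhaustive scan over the observed probability values: returns the
#' cutoff `t` minimising `|fraction(p >= t) - mean(p)|`, ties broken toward
#' the smaller `t`.
#'
#' @param suitability A [suitability_map] (or numeric probability vector).
#' @return The selected threshold.
#' @export
mean_probability_threshold <- function(suitability) {
  p <- if (inherits(suitability, "suitability_map")) {
    suitability$probability
  } else {
    as.numeric(suitability)
  }
  p <- p[!is.na(p)]
  if (!length(p)) stop("no non-missing probabilities")
  m <- mean(p)
  cand <- sort(unique(p))
  n <- length(p)
  frac <- vapply(cand, function(t) sum(p >= t) / n, 0)
  d <- abs(frac - m)
  cand[which(d == min(d))[1L]]  # candidates sorted ascending: first = smallest
}

#' Threshold a suitability map into a presence/absence map
#'
#' Presence wherever `probability >= threshold` (presence on ties); missing
#' cells stay NA; the threshold is recorded on the result.
#'
#' @param suitability A [suitability_map].
#' @param threshold Cutoff in `[0, 1]`.
#' @return A [binary_range_map].
#' @export
binarize <- function(suitability, threshold) {
  stopifnot(inherits(suitability, "suitability_map"),
            threshold >= 0, threshold <= 1)
  binary_range_map(suitability$grid, suitability$species,
                   suitability$period,
                   suitability$probability >= threshold, threshold)
}

#' Omission and commission rates
#'
#' Omission: fraction of observed presences projected as absences
#' (`FN / (FN + TP)`). Commission: fraction of observed absences projected
#' as presences (`FP / (FP + TN)`). Returned as proportions; multiply by
#' 100 for the tabular percentage form.
#'
#' @param predicted A [binary_range_map].
#' @param observed An [occurrence_map].
#' @param cells Evaluation cell ids with known observed status.
#' @return Named numeric `c(omission, commission)`.
#' @export
omission_commission <- function(predicted, observed, cells) {
  assert_aligned(predicted, observed)
  idx <- match(cells, observed$grid$cell_ids)
  if (anyNA(idx)) stop("unknown evaluation cell id(s)")
  st <- observed$status[idx]
  if (any(st == "unknown")) {
    stop("evaluation cells must have known observed status")
  }
  pred <- predicted$presence[idx]
  pres <- st == "present"
  abs_ <- st == "absent"
  if (!any(pres)) stop("omission undefined: no observed presences")
  if (!any(abs_)) stop("commission undefined: no observed absences")
  pred[is.na(pred)] <- FALSE  # a missing projection cannot claim presence
  c(omission = sum(pres & !pred) / sum(pres),
    commission = sum(abs_ & pred) / sum(abs_))
}

#' Evaluate a model's suitability map against observed occurrence
#'
#' Computes AUC on the given cells, derives (or accepts) a threshold,
#' binarizes, and reports omission/commission at that threshold.
#'
#' @param suitability Current-period [suitability_map].
#' @param observed Observed [occurrence_map].
#' @param cells Evaluation (test) cell ids.
#' @param threshold The occurrence threshold to use.
#' @param threshold_method Label recorded in the report, `"prevalence"` or
#'   `"mean_probability"`.
#' @return An object of class `evaluation_report`: list with `auc`,
#'   `omission_rate`, `commission_rate`, `threshold`, `threshold_method`,
#'   `n_test_presences`, `n_test_absences`.
#' @export
evaluate_model <- function(suitability, observed, cells, threshold,
                           threshold_method = c("prevalence",
                                                "mean_probability")) {
  threshold_method <- match.arg(threshold_method)
  assert_aligned(suitability, observed)
  idx <- match(cells, observed$grid$cell_ids)
  st <- observed$status[idx]
  a <- auc(suitability$probability[idx], st)
  bin <- binarize(suitability, threshold)
  oc <- omission_commission(bin, observed, cells)
  structure(list(auc = a,
                 omission_rate = unname(oc["omission"]),
                 commission_rate = unname(oc["commission"]),
                 threshold = threshold, threshold_method = threshold_method,
                 n_test_presences = sum(st == "present"),
                 n_test_absences = sum(st == "absent")),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> AUC=", round(x$auc, 3),
      ", omission=", round(100 * x$omission_rate, 2), "%",
      ", commission=", round(100 * x$commission_rate, 2), "%",
      ", threshold=", signif(x$threshold, 3),
      " (", x$threshold_method, ")\n", sep = "")
  invisible(x)
}
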