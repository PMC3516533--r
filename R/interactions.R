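#' @title Biotic-interaction coupling schemes
#' @description Four modelling schemes project the dependent species: a
#'   climate-only baseline and three ways of coupling its projection to the
#'   host it obligately depends on — intersecting both species' thresholded
#'   future ranges ("overlap"), feeding the host's modelled occurrence
#'   probability into the dependent model as an additional predictor
#'   ("explanatory"), and calibrating the dependent model only within the
#'   host's observed range and multiplying the resulting conditional
#'   probability by the host's modelled probability ("reference_area").
#' @name interaction-approaches
NULL

approach_result <- function(approach, species, suitability, binary,
                            threshold, evaluation, split,
                            host = NULL, host_threshold = NULL,
                            ensemble = NULL, calibration_cells = NULL,
                            non_analogue = NULL, provenance = list()) {
  structure(list(approach = approach, species = species,
                 suitability = suitability, binary = binary,
                 threshold = threshold, evaluation = evaluation,
                 split = split, host = host, host_threshold = host_threshold,
                 ensemble = ensemble, calibration_cells = calibration_cells,
                 non_analogue = non_analogue, provenance = provenance),
            class = "approach_result")
}

#' @export
print.approach_result <- function(x, ...) {
  cat("<approach_result> '", x$approach, "' for ", x$species,
      "; threshold=", signif(x$threshold, 3), sep = "")
  if (!is.null(x$evaluation)) cat(", AUC=", round(x$evaluation$auc, 3), sep = "")
  cat("\n")
  invisible(x)
}

choose_threshold <- function(method, occurrence, training_cells, suit_cur) {
  if (method == "prevalence") {
    prevalence_threshold(occurrence, training_cells)
  } else {
    mean_probability_threshold(suit_cur)
  }
}

# evaluation needs both classes among the test cells; a degenerate test
# split downgrades to an NA report instead of aborting the whole approach
safe_evaluate <- function(suitability, observed, cells, threshold,
                          threshold_method) {
  tryCatch(
    evaluate_model(suitability, observed, cells, threshold,
                   threshold_method),
    error = function(e) {
      warning("evaluation skipped: ", conditionMessage(e), call. = FALSE)
      structure(list(auc = NA_real_, omission_rate = NA_real_,
                     commission_rate = NA_real_, threshold = threshold,
                     threshold_method = threshold_method,
                     n_test_presences = NA_integer_,
                     n_test_absences = NA_integer_),
                class = "evaluation_report")
    })
}

member_aucs <- function(ensemble, layers, occurrence, cells,
                        extra_predictors = NULL) {
  idx <- match(cells, layers$grid$cell_ids)
  st <- occurrence$status[idx]
  vapply(ensemble$members, function(m) {
    p <- predict_prob(m, layers, extra_predictors)
    tryCatch(auc(p$probability[idx], st), error = function(e) NA_real_)
  }, 0)
}

#' Climate-only baseline model (no interaction)
#'
#' Fits the ensemble on climate alone, projects both periods, thresholds at
#' the species' prevalence in the model-building (training) cells, and
#' evaluates AUC and omission/commission on the held-out test cells.
#'
#' @param occurrence Observed current [occurrence_map] of the species.
#' @param climate_current,climate_future [climate_layers] for both periods.
#' @param learner_specs List of [learner_spec]s forming the ensemble.
#' @param split_fraction Training fraction for [split_data].
#' @param seed Integer RNG seed (drives the split).
#' @param threshold_method `"prevalence"` (default) or `"mean_probability"`.
#' @return An `approach_result` with approach `"none"`.
#' @export
model_no_interaction <- function(occurrence, climate_current, climate_future,
                                 learner_specs, split_fraction = 0.7,
                                 seed = 1L,
                                 threshold_method = "prevalence") {
  assert_aligned(climate_current, climate_future)
  assert_aligned(occurrence, climate_current)
  split <- split_data(occurrence, split_fraction, seed)
  ens <- fit_ensemble(learner_specs, climate_current, occurrence,
                      split$training)
  suit_cur <- predict_prob(ens, climate_current, species = occurrence$species)
  suit_fut <- predict_prob(ens, climate_future, species = occurrence$species)
  thr <- choose_threshold(threshold_method, occurrence, split$training,
                          suit_cur)
  ens$member_auc <- member_aucs(ens, climate_current, occurrence, split$test)
  ev <- safe_evaluate(suit_cur, occurrence, split$test, thr,
                      threshold_method)
  approach_result("none", occurrence$species,
                  suitability = list(current = suit_cur, future = suit_fut),
                  binary = list(current = binarize(suit_cur, thr),
                                future = binarize(suit_fut, thr)),
                  threshold = thr, evaluation = ev, split = split,
                  ensemble = ens,
                  provenance = list(learners = vapply(learner_specs,
                                                      `[[`, "", "name"),
                                    seed = seed,
                                    threshold_method = threshold_method))
}

and_presence <- function(a, b) {
  # NA & FALSE is a definite absence; NA & TRUE stays unknown
  p <- a & b
  p[is.na(a) & !is.na(b) & !b] <- FALSE
  p[is.na(b) & !is.na(a) & !a] <- FALSE
  p
}

#' Overlap approach: intersect the two species' thresholded ranges
#'
#' Each species is modelled separately on climate and thresholded at its
#' own prevalence; the dependent species' projected range is the cellwise
#' intersection (AND) of the two binary maps, per period. Suitability maps
#' pass through unchanged for reporting. Omission/commission are
#' re-computed against the intersected current map on the dependent
#' species' test cells; the AUC reported is the dependent model's.
#'
#' @param dep_result Climate-only `approach_result` for the dependent
#'   species (from [model_no_interaction]).
#' @param host_result Climate-only `approach_result` for the host.
#' @param dep_occurrence Observed dependent [occurrence_map] (for the
#'   re-evaluation of error rates).
#' @return An `approach_result` with approach `"overlap"`.
#' @export
approach_overlap <- function(dep_result, host_result,
                             dep_occurrence = NULL) {
  assert_aligned(dep_result$binary$future, host_result$binary$future)
  inter <- function(period) {
    d <- dep_result$binary[[period]]
    h <- host_result$binary[[period]]
    binary_range_map(d$grid, d$species, d$period,
                     and_presence(d$presence, h$presence), d$threshold)
  }
  binary <- list(current = inter("current"), future = inter("future"))
  ev <- dep_result$evaluation
  if (!is.null(dep_occurrence)) {
    oc <- tryCatch(omission_commission(binary$current, dep_occurrence,
                                       dep_result$split$test),
                   error = function(e) c(omission = NA_real_,
                                         commission = NA_real_))
    ev$omission_rate <- unname(oc["omission"])
    ev$commission_rate <- unname(oc["commission"])
  }
  approach_result("overlap", dep_result$species,
                  suitability = dep_result$suitability, binary = binary,
                  threshold = dep_result$threshold, evaluation = ev,
                  split = dep_result$split,
                  host = list(suitability = host_result$suitability,
                              binary = host_result$binary),
                  host_threshold = host_result$threshold,
                  ensemble = dep_result$ensemble,
                  provenance = c(dep_result$provenance,
                                 list(host_threshold = host_result$threshold)))
}

#' Explanatory-variable approach: host probability as a predictor
#'
#' The dependent ensemble is fitted on climate plus the host's modelled
#' current occurrence probability as one additional predictor; the future
#' projection substitutes the host's future probability. Thresholding and
#' evaluation follow the climate-only baseline. If the host layer is
#' constant it is dropped as a zero-variance predictor and the result
#' equals the baseline for the same seed.
#'
#' @inheritParams model_no_interaction
#' @param host_suitability_current,host_suitability_future Host
#'   [suitability_map]s for the two periods (modelled probabilities, not
#'   observed presence).
#' @param host_var Predictor name given to the host layer.
#' @return An `approach_result` with approach `"explanatory"`.
#' @export
approach_explanatory <- function(occurrence, climate_current, climate_future,
                                 host_suitability_current,
                                 host_suitability_future,
                                 learner_specs, split_fraction = 0.7,
                                 seed = 1L, threshold_method = "prevalence",
                                 host_var = "host_prob") {
  if (is.null(host_suitability_current) || is.null(host_suitability_future)) {
    stop("explanatory approach requires host suitability maps")
  }
  assert_aligned(climate_current, host_suitability_current)
  assert_aligned(climate_future, host_suitability_future)
  aug_cur <- add_variable(climate_current, host_var,
                          host_suitability_current$probability)
  aug_fut <- add_variable(climate_future, host_var,
                          host_suitability_future$probability)
  res <- model_no_interaction(occurrence, aug_cur, aug_fut, learner_specs,
                              split_fraction, seed, threshold_method)
  res$approach <- "explanatory"
  res$host <- list(suitability = list(current = host_suitability_current,
                                      future = host_suitability_future))
  res$provenance$host_var <- host_var
  res
}

#' Reference-area approach: conditional model within the host's range
#'
#' The dependent model is calibrated only on cells where the host is
#' observed present, so it estimates the conditional probability of the
#' dependent species given host presence. That conditional surface is
#' projected over the full grid for both periods and multiplied by the
#' host's modelled occurrence probability; the threshold is the dependent
#' species' prevalence within the calibration model-building cells.
#' Because the calibration climate space is deliberately restricted, the
#' future layers are screened by [mess_map] against the calibration
#' sample and the resulting non-analogue mask is attached to the result.
#'
#' @inheritParams approach_explanatory
#' @param host_occurrence Observed host [occurrence_map]; its presences
#'   define the calibration (reference) area.
#' @return An `approach_result` with approach `"reference_area"`, carrying
#'   `conditional` suitability maps, the final (product) maps, the
#'   calibration cell set and the non-analogue mask.
#' @export
approach_reference_area <- function(occurrence, host_occurrence,
                                    climate_current, climate_future,
                                    host_suitability_current,
                                    host_suitability_future,
                                    learner_specs, split_fraction = 0.7,
                                    seed = 1L,
                                    threshold_method = "prevalence") {
  if (is.null(host_occurrence) || !any(host_occurrence$status == "present")) {
    stop("reference-area approach requires host presences")
  }
  assert_aligned(occurrence, host_occurrence)
  assert_aligned(climate_current, climate_future)
  assert_aligned(climate_current, host_suitability_current)
  calib_mask <- host_occurrence$status == "present" &
    occurrence$status != "unknown" & climate_current$observed
  if (!any(calib_mask)) stop("empty calibration area")
  st <- occurrence$status
  st[!calib_mask] <- "unknown"
  occ_cal <- occurrence_map(occurrence$grid, occurrence$species, st)
  if (!any(st == "present") || !any(st == "absent")) {
    stop("calibration area lacks both presence and absence records")
  }
  split <- split_data(occ_cal, split_fraction, seed)
  ens <- fit_ensemble(learner_specs, climate_current, occ_cal,
                      split$training)
  cond_cur <- predict_prob(ens, climate_current, species = occurrence$species)
  cond_fut <- predict_prob(ens, climate_future, species = occurrence$species)
  product_map <- function(cond, host) {
    suitability_map(cond$grid, cond$species, cond$period,
                    cond$probability * host$probability,
                    source = paste0(cond$source, " x host"))
  }
  final_cur <- product_map(cond_cur, host_suitability_current)
  final_fut <- product_map(cond_fut, host_suitability_future)
  thr <- choose_threshold(threshold_method, occ_cal, split$training,
                          final_cur)
  ens$member_auc <- member_aucs(ens, climate_current, occ_cal, split$test)
  ev <- safe_evaluate(final_cur, occ_cal, split$test, thr, threshold_method)
  mess <- mess_map(climate_current, climate_future,
                   calibration_cells = split$training)
  res <- approach_result("reference_area", occurrence$species,
                         suitability = list(current = final_cur,
                                            future = final_fut),
                         binary = list(current = binarize(final_cur, thr),
                                       future = binarize(final_fut, thr)),
                         threshold = thr, evaluation = ev, split = split,
                         host = list(suitability =
                                       list(current = host_suitability_current,
                                            future = host_suitability_future)),
                         ensemble = ens,
                         calibration_cells = occurrence$grid$cell_ids[calib_mask],
                         non_analogue = mess$similarity < 0,
                         provenance = list(learners = vapply(learner_specs,
                                                             `[[`, "", "name"),
                                           seed = seed,
                                           threshold_method = threshold_method))
  res$conditional <- list(current = cond_cur, future = cond_fut)
  res$mess <- mess
  res
}

#' Run all four approaches on one data bundle
#'
#' Fits the host's climate-only ensemble once, then the dependent species
#' under the climate-only baseline and the three coupling schemes, all with
#' the same learner specs and seed policy.
#'
#' @param dep_occurrence,host_occurrence Observed current occurrence maps.
#' @param climate_current,climate_future [climate_layers] for both periods.
#' @param learner_specs List of [learner_spec]s.
#' @param split_fraction Training fraction.
#' @param seed Integer base seed; the host model uses `seed + 1`.
#' @param threshold_method `"prevalence"` or `"mean_probability"`.
#' @param approaches Which approaches to run.
#' @return Named list of `approach_result`s (plus element `host` with the
#'   host's climate-only result).
#' @export
run_approaches <- function(dep_occurrence, host_occurrence,
                           climate_current, climate_future, learner_specs,
                           split_fraction = 0.7, seed = 1L,
                           threshold_method = "prevalence",
                           approaches = c("none", "overlap", "explanatory",
                                          "reference_area")) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  host_res <- model_no_interaction(host_occurrence, climate_current,
                                   climate_future, learner_specs,
                                   split_fraction, seed + 1L,
                                   threshold_method)
  out <- list()
  dep_none <- NULL
  if (any(c("none", "overlap") %in% approaches)) {
    dep_none <- model_no_interaction(dep_occurrence, climate_current,
                                     climate_future, learner_specs,
                                     split_fraction, seed, threshold_method)
  }
  if ("none" %in% approaches) out$none <- dep_none
  if ("overlap" %in% approaches) {
    out$overlap <- approach_overlap(dep_none, host_res, dep_occurrence)
  }
  if ("explanatory" %in% approaches) {
    out$explanatory <- approach_explanatory(
      dep_occurrence, climate_current, climate_future,
      host_res$suitability$current, host_res$suitability$future,
      learner_specs, split_fraction, seed, threshold_method)
  }
  if ("reference_area" %in% approaches) {
    out$reference_area <- approach_reference_area(
      dep_occurrence, host_occurrence, climate_current, climate_future,
      host_res$suitability$current, host_res$suitability$future,
      learner_specs, split_fraction, seed, threshold_method)
  }
  out$host <- host_res
  out
}

#' Table-1-style evaluation summary across approaches
#'
#' @param results Named list of `approach_result`s (e.g. from
#'   [run_approaches]); a `host` element is reported as its own row.
#' @return data.frame with columns approach, auc, omission_rate_pct,
#'   commission_rate_pct, occurrence_threshold.
#' @export
evaluation_table <- function(results) {
  rows <- lapply(names(results), function(nm) {
    ev <- results[[nm]]$evaluation
    data.frame(approach = nm, auc = ev$auc,
               omission_rate_pct = 100 * ev$omission_rate,
               commission_rate_pct = 100 * ev$commission_rate,
               occurrence_threshold = ev$threshold)
  })
  do.call(rbind, rows)
}
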