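#' Configuration of a full comparison experiment
#'
#' Bundles every knob of the end-to-end pipeline: the virtual scenario (or
#' paths to pre-built inputs), the learner ensemble, the split, the
#' thresholding rule, the approaches, and output settings. The resolved
#' configuration (all defaults and seeds materialised) is written to the
#' output directory for provenance.
#'
#' @param scenario A [scenario_config] used to simulate inputs, or `NULL`
#'   when `inputs` is given.
#' @param inputs Optional named list of file paths (`climate_current`,
#'   `climate_future`, `dependent`, `host`) read with [read_layers] /
#'   [read_occurrence] instead of simulating.
#' @param learners Character vector of registered learner names.
#' @param split_fraction Training fraction.
#' @param threshold_method `"prevalence"` or `"mean_probability"`.
#' @param approaches Approaches to run.
#' @param n_perm Permutations for [variable_importance].
#' @param n_bins Bins per variable for [binned_gain_loss].
#' @param seed Integer base seed for the whole experiment.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = scenario_config(), inputs = NULL,
                       learners = c("glm_poly2", "sre"),
                       split_fraction = 0.7,
                       threshold_method = c("prevalence",
                                            "mean_probability"),
                       approaches = c("none", "overlap", "explanatory",
                                      "reference_area"),
                       n_perm = 10L, n_bins = 20L, seed = 1L) {
  threshold_method <- match.arg(threshold_method)
  approaches <- match.arg(approaches, several.ok = TRUE)
  if (is.null(scenario) && is.null(inputs)) {
    stop("either a scenario or input paths must be given")
  }
  if (!is.null(inputs)) {
    need <- c("climate_current", "climate_future", "dependent")
    if ("reference_area" %in% approaches ||
        "overlap" %in% approaches ||
        "explanatory" %in% approaches) {
      need <- c(need, "host")
    }
    miss <- setdiff(need, names(inputs))
    if (length(miss)) {
      stop("inputs missing required path(s): ", paste(miss, collapse = ", "))
    }
  }
  for (l in learners) get_learner(l)
  stopifnot(split_fraction > 0, split_fraction <= 1, n_perm >= 1,
            n_bins >= 1)
  structure(list(scenario = scenario, inputs = inputs, learners = learners,
                 split_fraction = split_fraction,
                 threshold_method = threshold_method,
                 approaches = approaches, n_perm = as.integer(n_perm),
                 n_bins = as.integer(n_bins), seed = as.integer(seed)),
            class = "run_config")
}

load_experiment_inputs <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    fmt <- function(p) if (grepl("\\.tiff?$", p)) "tiff" else "csv"
    list(climate = list(current = read_layers(inp$climate_current,
                                              fmt(inp$climate_current)),
                        future = read_layers(inp$climate_future,
                                             fmt(inp$climate_future))),
         dependent = read_occurrence(inp$dependent),
         host = if (!is.null(inp$host)) read_occurrence(inp$host))
  } else {
    sc <- generate_scenario(config$scenario, config$seed)
    list(climate = sc$climate, dependent = sc$dependent, host = sc$host,
         truth = sc$truth)
  }
}

#' Re-run every approach with each learner as a single-member ensemble
#'
#' Produces the per-algorithm projections feeding the uncertainty
#' partition: one `approach_result` per (learner, approach) pair, all from
#' the same seed so splits are shared across learners.
#'
#' @inheritParams run_approaches
#' @param learners Character vector of registered learner names.
#' @return Nested named list `out[[learner]][[approach]]` suitable for
#'   [build_outcome_table].
#' @export
run_factorial <- function(dep_occurrence, host_occurrence, climate_current,
                          climate_future, learners, split_fraction = 0.7,
                          seed = 1L, threshold_method = "prevalence",
                          approaches = c("none", "overlap", "explanatory",
                                         "reference_area")) {
  out <- list()
  for (l in learners) {
    res <- run_approaches(dep_occurrence, host_occurrence, climate_current,
                          climate_future, list(learner_spec(l)),
                          split_fraction, seed, threshold_method,
                          approaches)
    res$host <- NULL
    out[[l]] <- res
  }
  out
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full comparison experiment
#'
#' Orchestrates the whole pipeline: simulate (or load) inputs, fit the host
#' and the dependent species under every requested approach, evaluate,
#' screen the reference-area projection for non-analogue climate, compute
#' the change table and 2-D binned gain/loss summaries over the two most
#' important climate variables, build the per-learner factorial outcome
#' table, and partition its variance. Every produced file is listed in a
#' JSON manifest with md5 checksums; the resolved seeds and thresholds are
#' logged.
#'
#' @param config A [run_config].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log progress to stderr.
#' @return Invisibly, the manifest (named list of file paths and
#'   checksums, plus headline results).
#' @export
run_experiment <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[hostsdm] ", ...)
  files <- character(0)
  add <- function(p) { files[[length(files) + 1L]] <<- p; p }

  stage <- "configure"
  on_fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    resolved <- config
    resolved$scenario <- unclass(resolved$scenario)
    jsonlite::write_json(unclass(resolved),
                         add(file.path(out_dir, "config.json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)

    stage <- "simulate"
    say("stage: ", stage, " (seed ", config$seed, ")")
    dat <- load_experiment_inputs(config)
    if (("reference_area" %in% config$approaches ||
         "overlap" %in% config$approaches) && is.null(dat$host)) {
      stop("host occurrence required for the requested approaches")
    }
    write_layers(dat$climate$current,
                 add(file.path(out_dir, "climate_current.csv")))
    write_layers(dat$climate$future,
                 add(file.path(out_dir, "climate_future.csv")))
    write_occurrence(dat$dependent,
                     add(file.path(out_dir, "occurrence_dependent.csv")))
    if (!is.null(dat$host)) {
      write_occurrence(dat$host,
                       add(file.path(out_dir, "occurrence_host.csv")))
    }

    stage <- "fit_approaches"
    say("stage: ", stage, " (learners: ",
        paste(config$learners, collapse = ", "), ")")
    specs <- lapply(config$learners, learner_spec)
    results <- run_approaches(dat$dependent, dat$host, dat$climate$current,
                              dat$climate$future, specs,
                              config$split_fraction, config$seed,
                              config$threshold_method, config$approaches)
    host_res <- results$host
    results$host <- NULL
    for (nm in names(results)) {
      r <- results[[nm]]
      write_layers(r$suitability$future,
                   add(file.path(out_dir,
                                 paste0("suitability_future_", nm, ".csv"))))
      write_layers(r$binary$future,
                   add(file.path(out_dir,
                                 paste0("range_future_", nm, ".csv"))))
      say("  approach '", nm, "': threshold=", signif(r$threshold, 3),
          ", AUC=", round(r$evaluation$auc, 3))
    }

    stage <- "evaluate"
    eval_tab <- evaluation_table(c(results, list(host = host_res)))
    add(write_table(eval_tab, file.path(out_dir, "evaluation.csv")))

    stage <- "variable_importance"
    say("stage: ", stage)
    base_res <- if (!is.null(results$none)) results$none else results[[1L]]
    imp <- variable_importance(base_res$ensemble, dat$climate$current,
                               n_perm = config$n_perm,
                               seed = config$seed + 11L)
    ranked <- rank_variables(imp)
    imp_tab <- data.frame(variable = names(imp),
                          importance = unname(imp),
                          rank = match(names(imp), ranked))
    add(write_table(imp_tab[order(imp_tab$rank), ],
                    file.path(out_dir, "importance.csv")))

    stage <- "mess"
    if (!is.null(results$reference_area)) {
      mm <- results$reference_area$mess
      mess_df <- cbind(grid_cols_df(mm$grid),
                       data.frame(similarity = mm$similarity,
                                  most_dissimilar = mm$most_dissimilar),
                       as.data.frame(mm$components))
      add(write_table(mess_df, file.path(out_dir, "mess_future.csv")))
      say("stage: mess (", round(100 * mean(mm$similarity < 0, na.rm = TRUE), 1),
          "% non-analogue)")
    }

    stage <- "change_metrics"
    chg <- change_table(results, dat$dependent)
    add(write_table(chg, file.path(out_dir, "change_table.csv")))
    top2 <- intersect(ranked, names(dat$climate$current$variables))[1:2]
    if (length(top2) == 2L && !anyNA(top2)) {
      for (nm in names(results)) {
        b <- binned_gain_loss(dat$dependent, results[[nm]]$binary$future,
                              dat$climate$future, top2[1L], top2[2L],
                              config$n_bins)
        add(write_table(as.data.frame(b),
                        file.path(out_dir,
                                  paste0("binned_gain_loss_", nm, ".csv"))))
      }
    }

    stage <- "uncertainty"
    say("stage: ", stage)
    fact <- run_factorial(dat$dependent, dat$host, dat$climate$current,
                          dat$climate$future, config$learners,
                          config$split_fraction, config$seed,
                          config$threshold_method, config$approaches)
    outcome <- build_outcome_table(fact, dat$dependent)
    add(write_table(as.data.frame(outcome),
                    file.path(out_dir, "outcome_table.csv")))
    part <- hierarchical_partition(outcome)
    part_json <- list(r2_full = part$r2_full)
    for (i in seq_len(nrow(part$partition))) {
      row <- part$partition[i, ]
      part_json[[row$factor]] <- list(independent = row$independent,
                                      joint = row$joint,
                                      share_pct = row$share_pct)
    }
    jsonlite::write_json(part_json, add(file.path(out_dir, "partition.json")),
                         auto_unbox = TRUE, digits = NA)

    stage <- "manifest"
    checksums <- as.list(tools::md5sum(unlist(files)))
    names(checksums) <- basename(names(checksums))
    manifest <- list(files = checksums,
                     seed = config$seed,
                     learners = config$learners,
                     thresholds = lapply(results, `[[`, "threshold"),
                     top_variables = ranked)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    say("done: ", length(files), " artifact(s) + manifest in ", out_dir)
    manifest$results <- results
    manifest$host <- host_res
    manifest$outcome_table <- outcome
    manifest$partition <- part
    manifest$change_table <- chg
    invisible(manifest)
  }, error = on_fail)
}
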