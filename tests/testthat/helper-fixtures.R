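# Small gridded fixtures built in code; every test builds what it needs.

make_layers <- function(n_rows = 2, n_cols = 2, vars = NULL,
                        period = "current") {
  g <- sdm_grid(n_rows, n_cols)
  if (is.null(vars)) {
    n <- n_rows * n_cols
    vars <- list(t = seq_len(n), p = rev(seq_len(n)))
  }
  climate_layers(g, period, vars)
}

make_occurrence <- function(status, n_rows = NULL, n_cols = NULL,
                            species = "sp") {
  n <- length(status)
  if (is.null(n_rows)) { n_rows <- 1L; n_cols <- n }
  occurrence_map(sdm_grid(n_rows, n_cols), species, status)
}

make_suitability <- function(p, n_rows = NULL, n_cols = NULL,
                             species = "sp", period = "current") {
  n <- length(p)
  if (is.null(n_rows)) { n_rows <- 1L; n_cols <- n }
  suitability_map(sdm_grid(n_rows, n_cols), species, period, p)
}

# A small, fast scenario for module-level tests (same climate value ranges
# and species responses as the packaged default, smaller grid).
small_scenario <- function(seed = 1L, n_rows = 40, n_cols = 40) {
  generate_scenario(scenario_config(n_rows = n_rows, n_cols = n_cols),
                    seed = seed)
}

# Minimal approach_result wrapper for tests exercising set operations.
fake_result <- function(binary_current, binary_future, threshold = 0.5,
                        approach = "none", species = "sp") {
  hostsdm:::approach_result(
    approach, species,
    suitability = list(current = NULL, future = NULL),
    binary = list(current = binary_current, future = binary_future),
    threshold = threshold, evaluation = NULL,
    split = list(training = character(0), test = character(0)))
}
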