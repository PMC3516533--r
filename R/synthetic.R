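#' Configuration for a virtual two-species scenario
#'
#' Describes synthetic current/future climate on a regular grid plus a host
#' species and an obligately dependent species with known logistic climatic
#' responses. Each climate variable is a linear gradient along one grid
#' axis, rescaled to a given range, plus spatially smooth Gaussian noise;
#' the future layer adds a per-variable shift (redrawing the noise field),
#' emulating a poleward displacement of suitable climate.
#'
#' The default configuration is the packaged study scenario: a 60x60 grid
#' with a temperature gradient along rows (warm edge at row 0) that warms by
#' +2 in the future, a stationary habitat-quality gradient (`soil`) along
#' the same axis, and a stationary moisture gradient along columns. The
#' host responds to soil and moisture only — it occupies a fixed band of
#' habitat that cannot track the warming — while the dependent species
#' tracks a thermal optimum whose band is partially truncated poleward by
#' the host's habitat edge. Under the future shift the dependent's thermal
#' envelope moves well beyond the host's stationary range, so the host's
#' future range limits the dependent species' climatically suitable area.
#'
#' @param n_rows,n_cols Grid size.
#' @param variables List of variable specs, each a list with `name`,
#'   `direction` (`"row"` or `"col"`), `range` (length-2 numeric, value at
#'   index 0 and at the last index; may be decreasing), `noise_sd` (>= 0)
#'   and `noise_scale` (Gaussian smoothing length in cells).
#' @param future_shift Named numeric vector of additive per-variable changes.
#' @param host_coefficients,dependent_coefficients Logistic response
#'   coefficients: a list with `intercept`, and named numeric vectors
#'   `linear` and `quadratic` over variable names.
#' @param obligate If `TRUE` the dependent species can only occur where the
#'   host is present.
#' @param detection Per-species detection probability applied to true
#'   occupancy when realizing observed presences.
#' @param sample_fraction Fraction of cells surveyed; unsurveyed cells get
#'   status `"unknown"`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_rows = 60, n_cols = 60,
                            variables = list(
                              list(name = "temp", direction = "row",
                                   range = c(14, 0), noise_sd = 1.0,
                                   noise_scale = 3),
                              list(name = "soil", direction = "row",
                                   range = c(0, 10), noise_sd = 0.8,
                                   noise_scale = 3),
                              list(name = "prec", direction = "col",
                                   range = c(300, 900), noise_sd = 30,
                                   noise_scale = 3)),
                            future_shift = c(temp = 2, soil = 0, prec = 0),
                            host_coefficients = list(
                              intercept = -20.9,
                              linear = c(soil = 7.326, prec = 0.0277),
                              quadratic = c(soil = -0.9, prec = -2.13e-5)),
                            dependent_coefficients = list(
                              intercept = -28.225,
                              linear = c(temp = 10, prec = 0.013),
                              quadratic = c(temp = -1.0, prec = -1e-5)),
                            obligate = TRUE,
                            detection = 1,
                            sample_fraction = 1) {
  cfg <- list(n_rows = n_rows, n_cols = n_cols, variables = variables,
              future_shift = future_shift,
              host_coefficients = host_coefficients,
              dependent_coefficients = dependent_coefficients,
              obligate = isTRUE(obligate), detection = detection,
              sample_fraction = sample_fraction)
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  stopifnot(cfg$n_rows >= 2, cfg$n_cols >= 2, length(cfg$variables) >= 1)
  for (v in cfg$variables) {
    if (!all(c("name", "direction", "range") %in% names(v))) {
      stop("each variable spec needs name, direction and range")
    }
    if (!v$direction %in% c("row", "col")) {
      stop("gradient direction must be 'row' or 'col', got: ", v$direction)
    }
    if (!all(is.finite(v$range)) || length(v$range) != 2L) {
      stop("gradient range must be two finite values")
    }
    sd <- if (is.null(v$noise_sd)) 0 else v$noise_sd
    if (sd < 0) stop("noise_sd must be >= 0")
  }
  if (cfg$detection < 0 || cfg$detection > 1) {
    stop("detection must be in [0, 1]")
  }
  if (cfg$sample_fraction <= 0 || cfg$sample_fraction > 1) {
    stop("sample_fraction must be in (0, 1]")
  }
  invisible(TRUE)
}

# Smooth a white-noise matrix with a separable Gaussian kernel
# (reflected edges), then rescale to unit sd so noise_sd is meaningful.
smooth_noise <- function(n_rows, n_cols, scale) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (scale <= 0) return(z)
  half <- max(1L, ceiling(3 * scale))
  k <- stats::dnorm(-half:half, sd = scale)
  k <- k / sum(k)
  pad_reflect <- function(x, h) {
    n <- length(x)
    c(x[pmin(h:1, n)], x, x[pmax(n - (1:h) + 1, 1L)])
  }
  conv1 <- function(x) {
    xp <- pad_reflect(x, half)
    stats::filter(xp, k, sides = 2)[(half + 1):(half + length(x))]
  }
  z <- apply(z, 2L, conv1)
  z <- t(apply(z, 1L, conv1))
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

gradient_field <- function(n_rows, n_cols, direction, range) {
  if (direction == "row") {
    idx <- (seq_len(n_rows) - 1) / (n_rows - 1)
    vals <- range[1] + (range[2] - range[1]) * idx
    matrix(vals, n_rows, n_cols)
  } else {
    idx <- (seq_len(n_cols) - 1) / (n_cols - 1)
    vals <- range[1] + (range[2] - range[1]) * idx
    matrix(vals, n_rows, n_cols, byrow = TRUE)
  }
}

#' Generate current and future climate layers for a scenario
#'
#' Each variable is its axis gradient plus smoothed, rescaled Gaussian noise;
#' the future layer applies the per-variable additive shift and redraws the
#' noise field from a sub-seed, so current and future differ by the shift
#' plus independent (but equally smooth) noise.
#'
#' @param config A [scenario_config].
#' @param seed Integer RNG seed.
#' @return A list with `climate_layers` elements `current` and `future` on
#'   the same grid.
#' @export
generate_climate <- function(config, seed = 1L) {
  validate_scenario_config(config)
  grid <- sdm_grid(config$n_rows, config$n_cols)
  make_period <- function(sub_seed, shift) {
    set.seed(sub_seed)
    vars <- list()
    for (v in config$variables) {
      base <- gradient_field(config$n_rows, config$n_cols, v$direction,
                             v$range)
      sd <- if (is.null(v$noise_sd)) 0 else v$noise_sd
      scl <- if (is.null(v$noise_scale)) 0 else v$noise_scale
      noise <- if (sd > 0) {
        sd * smooth_noise(config$n_rows, config$n_cols, scl)
      } else 0
      sh <- if (v$name %in% names(shift)) shift[[v$name]] else 0
      vars[[v$name]] <- as.vector(t(base + noise + sh))
    }
    vars
  }
  cur <- make_period(seed, stats::setNames(numeric(0), character(0)))
  fut <- make_period(seed + 1L, config$future_shift)
  list(current = climate_layers(grid, "current", cur),
       future = climate_layers(grid, "future", fut))
}

#' Logistic suitability from quadratic climatic responses
#'
#' Ground-truth response surface of a virtual species:
#' `p = plogis(intercept + sum_v(b1_v x_v + b2_v x_v^2))`.
#'
#' @param coefficients List with `intercept` and named numeric vectors
#'   `linear` and `quadratic`; names must be variables of `layers`.
#' @param layers A [climate_layers].
#' @param species,source Labels for the returned map.
#' @return A [suitability_map] for `layers$period`.
#' @export
logistic_suitability <- function(coefficients, layers, species = "virtual",
                                 source = "truth") {
  stopifnot(inherits(layers, "climate_layers"))
  vs <- union(names(coefficients$linear), names(coefficients$quadratic))
  unknown <- setdiff(vs, names(layers$variables))
  if (length(unknown)) {
    stop("coefficients reference unknown variable(s): ",
         paste(unknown, collapse = ", "))
  }
  eta <- rep(coefficients$intercept, n_cells(layers))
  for (v in vs) {
    x <- layers$variables[[v]]
    b1 <- if (v %in% names(coefficients$linear)) coefficients$linear[[v]] else 0
    b2 <- if (v %in% names(coefficients$quadratic)) {
      coefficients$quadratic[[v]]
    } else 0
    eta <- eta + b1 * x + b2 * x^2
  }
  suitability_map(layers$grid, species, layers$period, stats::plogis(eta),
                  source)
}

#' Realize an observed occurrence map from a suitability surface
#'
#' True occupancy is Bernoulli in the suitability; under obligacy it is
#' additionally masked to host-present cells. Observed presence thins true
#' occupancy by the detection probability; a seeded fraction
#' `1 - sample_fraction` of cells is left unsurveyed (`"unknown"`). The true
#' occupancy vector is attached as attribute `"occupancy"`.
#'
#' @param suitability A [suitability_map].
#' @param host Optional host [occurrence_map] (required when `obligate`).
#' @param obligate If `TRUE`, occupancy is restricted to host presences.
#' @param detection Detection probability in `[0, 1]`.
#' @param sample_fraction Fraction of cells surveyed, in `(0, 1]`.
#' @param seed Integer RNG seed.
#' @param species Species label (defaults to the suitability map's).
#' @return An [occurrence_map] with attribute `occupancy` (logical).
#' @export
realize_occurrence <- function(suitability, host = NULL, obligate = FALSE,
                               detection = 1, sample_fraction = 1, seed = 1L,
                               species = suitability$species) {
  stopifnot(inherits(suitability, "suitability_map"))
  if (detection < 0 || detection > 1) stop("detection must be in [0, 1]")
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop("sample_fraction must be in (0, 1]")
  }
  if (obligate) {
    if (is.null(host)) stop("obligate realization requires a host map")
    assert_aligned(suitability, host)
  }
  n <- n_cells(suitability)
  p <- suitability$probability
  set.seed(seed)
  occ <- rep(FALSE, n)
  ok <- !is.na(p)
  occ[ok] <- stats::runif(sum(ok)) < p[ok]
  if (obligate) occ <- occ & (host$status == "present")
  detected <- occ
  if (detection < 1) detected <- occ & (stats::runif(n) < detection)
  status <- ifelse(detected, "present", "absent")
  status[!ok] <- "unknown"
  if (sample_fraction < 1) {
    n_unsurveyed <- round((1 - sample_fraction) * n)
    if (n_unsurveyed > 0) {
      status[sample.int(n, n_unsurveyed)] <- "unknown"
    }
  }
  out <- occurrence_map(suitability$grid, species, status)
  attr(out, "occupancy") <- occ
  out
}

#' Generate a full virtual scenario with ground truth
#'
#' Composes [generate_climate], [logistic_suitability] and
#' [realize_occurrence]: current/future climate, the host's and the
#' dependent species' true suitability surfaces and occupancies for both
#' periods, and observed occurrence maps for the current period. Fully
#' reproducible from `(config, seed)`; per-stage sub-seeds are derived from
#' `seed` by small offsets.
#'
#' @param config A [scenario_config].
#' @param seed Integer RNG seed.
#' @return A list with elements `climate` (list current/future), `host` and
#'   `dependent` (observed current [occurrence_map]s), and `truth` — a list
#'   with true suitabilities and occupancy maps per species and period.
#' @export
generate_scenario <- function(config = scenario_config(), seed = 1L) {
  validate_scenario_config(config)
  clim <- generate_climate(config, seed)
  host_suit <- list(
    current = logistic_suitability(config$host_coefficients, clim$current,
                                   species = "host"),
    future = logistic_suitability(config$host_coefficients, clim$future,
                                  species = "host"))
  dep_suit <- list(
    current = logistic_suitability(config$dependent_coefficients,
                                   clim$current, species = "dependent"),
    future = logistic_suitability(config$dependent_coefficients, clim$future,
                                  species = "dependent"))
  host_occ <- list(
    current = realize_occurrence(host_suit$current, detection = config$detection,
                                 sample_fraction = config$sample_fraction,
                                 seed = seed + 101L),
    future = realize_occurrence(host_suit$future, detection = 1,
                                sample_fraction = 1, seed = seed + 102L))
  dep_occ <- list(
    current = realize_occurrence(dep_suit$current, host = host_occ$current,
                                 obligate = config$obligate,
                                 detection = config$detection,
                                 sample_fraction = config$sample_fraction,
                                 seed = seed + 103L),
    future = realize_occurrence(dep_suit$future, host = host_occ$future,
                                obligate = config$obligate, detection = 1,
                                sample_fraction = 1, seed = seed + 104L))
  truth <- structure(list(host_suitability = host_suit,
                          dependent_suitability = dep_suit,
                          host_occupancy = host_occ,
                          dependent_occupancy = dep_occ),
                     class = "virtual_truth")
  list(climate = clim, host = host_occ$current, dependent = dep_occ$current,
       truth = truth, config = config, seed = seed)
}

#' Occupancy centroid of an occurrence map
#'
#' Mean (row, col) position of present cells; used to verify directional
#' range shifts in virtual scenarios.
#'
#' @param occurrence An [occurrence_map].
#' @return Named numeric `c(row, col)` (0-based indices).
#' @export
range_centroid <- function(occurrence) {
  stopifnot(inherits(occurrence, "occurrence_map"))
  rc <- cell_row_col(occurrence$grid$n_rows, occurrence$grid$n_cols)
  pres <- occurrence$status == "present"
  if (!any(pres)) stop("no presences")
  c(row = mean(rc$row[pres]), col = mean(rc$col[pres]))
}
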