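zero_noise_config <- function(...) {
  args <- utils::modifyList(list(
    n_rows = 11, n_cols = 5,
    variables = list(list(name = "t", direction = "row", range = c(0, 10),
                          noise_sd = 0, noise_scale = 0)),
    future_shift = c(t = 0),
    host_coefficients = list(intercept = 0, linear = c(t = 0),
                             quadratic = c(t = 0)),
    dependent_coefficients = list(intercept = 0, linear = c(t = 0),
                                  quadratic = c(t = 0))),
    list(...))
  do.call(scenario_config, args)
}

test_that("zero noise and zero shift give an exact gradient, future == current", {
  clim <- generate_climate(zero_noise_config(), seed = 7)
  expect_identical(clim$current$variables$t, clim$future$variables$t)
  # row gradient [0, 10] on 11 rows: row r has value r
  rows <- hostsdm:::cell_row_col(11, 5)$row
  expect_equal(clim$current$variables$t, as.numeric(rows))
})

test_that("climate generation is deterministic in (config, seed)", {
  cfg <- scenario_config(n_rows = 20, n_cols = 20)
  a <- generate_climate(cfg, seed = 3)
  b <- generate_climate(cfg, seed = 3)
  expect_identical(a, b)
  c <- generate_climate(cfg, seed = 4)
  expect_false(identical(a$current$variables$temp, c$current$variables$temp))
})

test_that("future shift adds the configured per-variable offset", {
  cfg <- zero_noise_config(future_shift = c(t = 2.5))
  clim <- generate_climate(cfg, seed = 1)
  expect_equal(clim$future$variables$t, clim$current$variables$t + 2.5)
})

test_that("logistic suitability matches closed forms", {
  ly <- make_layers(2, 2, vars = list(x = c(0, 1, 2, 3)))
  flat <- logistic_suitability(list(intercept = 0, linear = c(x = 0),
                                    quadratic = c(x = 0)), ly)
  expect_equal(flat$probability, rep(0.5, 4))
  tail <- logistic_suitability(list(intercept = -50, linear = c(x = 0),
                                    quadratic = c(x = 0)), ly)
  expect_true(all(tail$probability < 1e-20))
  # eta = ln 3 at every cell -> p = 3/4
  ln3 <- logistic_suitability(list(intercept = log(3), linear = c(x = 0),
                                   quadratic = c(x = 0)), ly)
  expect_equal(ln3$probability, rep(0.75, 4), tolerance = 1e-12)
  expect_error(
    logistic_suitability(list(intercept = 0, linear = c(y = 1),
                              quadratic = c(y = 0)), ly),
    "unknown variable")
})

test_that("occurrence realization honours certainty, obligacy and validation", {
  s1 <- make_suitability(rep(1, 9), 3, 3)
  occ <- realize_occurrence(s1, detection = 1, sample_fraction = 1, seed = 2)
  expect_true(all(occ$status == "present"))
  host0 <- make_occurrence(rep("absent", 9), 3, 3)
  occ0 <- realize_occurrence(s1, host = host0, obligate = TRUE, seed = 2)
  expect_true(all(occ0$status == "absent"))
  expect_error(realize_occurrence(s1, detection = 1.2), "detection")
})

test_that("realized prevalence is binomially consistent with suitability", {
  s <- make_suitability(rep(0.3, 10000), 100, 100)
  occ <- realize_occurrence(s, detection = 1, seed = 11)
  prev <- prevalence(occ)
  expect_lt(abs(prev - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("unsurveyed fraction produces unknown status", {
  s <- make_suitability(rep(0.5, 400), 20, 20)
  occ <- realize_occurrence(s, sample_fraction = 0.8, seed = 5)
  expect_equal(sum(occ$status == "unknown"), 80L)
})

test_that("scenarios respect obligacy and differ across seeds", {
  sc <- small_scenario(seed = 9)
  dep_pres <- sc$dependent$status == "present"
  expect_true(all(sc$host$status[dep_pres] == "present"))
  # true occupancy is nested too, both periods
  expect_true(all(attr(sc$truth$host_occupancy$current, "occupancy")[
    attr(sc$truth$dependent_occupancy$current, "occupancy")]))
  expect_true(all(attr(sc$truth$host_occupancy$future, "occupancy")[
    attr(sc$truth$dependent_occupancy$future, "occupancy")]))
  sc2 <- small_scenario(seed = 10)
  expect_gt(sum(sc$dependent$status != sc2$dependent$status), 0)
  expect_identical(small_scenario(seed = 9)$dependent$status,
                   sc$dependent$status)
})

test_that("a warming shift moves the true range centroid up-gradient", {
  # noise-free thermally limited species; temp decreases with row index,
  # so a +2 warming moves the optimal band toward higher rows
  cfg <- scenario_config(
    n_rows = 50, n_cols = 10,
    variables = list(list(name = "temp", direction = "row",
                          range = c(14, 0), noise_sd = 0, noise_scale = 0)),
    future_shift = c(temp = 2),
    host_coefficients = list(intercept = -11.5, linear = c(temp = 5),
                             quadratic = c(temp = -0.5)),
    dependent_coefficients = list(intercept = -11.5, linear = c(temp = 5),
                                  quadratic = c(temp = -0.5)),
    obligate = FALSE)
  sc <- generate_scenario(cfg, seed = 21)
  cur <- range_centroid(sc$truth$host_occupancy$current)
  fut <- range_centroid(sc$truth$host_occupancy$future)
  expect_gt(fut[["row"]], cur[["row"]])
})

test_that("mean true suitability matches realized prevalence (calibration)", {
  sc <- small_scenario(seed = 31)
  p <- sc$truth$host_suitability$current$probability
  prev <- prevalence(sc$host)
  mc_sd <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(prev - mean(p)), 3 * mc_sd)
})

test_that("config validation rejects bad fields", {
  expect_error(scenario_config(sample_fraction = 0), "sample_fraction")
  expect_error(scenario_config(detection = -0.1), "detection")
  expect_error(scenario_config(variables = list(
    list(name = "a", direction = "diag", range = c(0, 1)))), "direction")
})
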