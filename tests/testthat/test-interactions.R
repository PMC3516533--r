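test_that("climate-only model discriminates a climate-driven species well", {
  sc <- small_scenario(seed = 41)
  specs <- list(learner_spec("glm_poly2"), learner_spec("sre"))
  res <- model_no_interaction(sc$host, sc$climate$current,
                              sc$climate$future, specs, seed = 41)
  expect_s3_class(res, "approach_result")
  expect_gt(res$evaluation$auc, 0.9)
  expect_equal(res$threshold,
               prevalence_threshold(sc$host, res$split$training))
  expect_length(res$ensemble$member_auc, 2L)
})

test_that("identical current and future climate give identical range maps", {
  sc <- small_scenario(seed = 43)
  res <- model_no_interaction(sc$host, sc$climate$current,
                              sc$climate$current,
                              list(learner_spec("glm_poly2")), seed = 43)
  expect_identical(res$binary$current$presence, res$binary$future$presence)
})

test_that("overlap is the cellwise intersection of the two range maps", {
  g <- sdm_grid(1, 4)
  mk <- function(pres, period) binary_range_map(g, "sp", period, pres, 0.5)
  dep <- fake_result(mk(c(TRUE, TRUE, TRUE, FALSE), "current"),
                     mk(c(TRUE, TRUE, TRUE, FALSE), "future"))
  host_all <- fake_result(mk(rep(TRUE, 4), "current"),
                          mk(rep(TRUE, 4), "future"))
  ov <- approach_overlap(dep, host_all)
  expect_identical(ov$binary$future$presence, dep$binary$future$presence)
  host_none <- fake_result(mk(rep(FALSE, 4), "current"),
                           mk(rep(FALSE, 4), "future"))
  expect_false(any(approach_overlap(dep, host_none)$binary$future$presence))
  host_bcd <- fake_result(mk(c(FALSE, TRUE, TRUE, TRUE), "current"),
                          mk(c(FALSE, TRUE, TRUE, TRUE), "future"))
  expect_identical(approach_overlap(dep, host_bcd)$binary$future$presence,
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("overlap future range is contained in the baseline's", {
  sc <- small_scenario(seed = 47)
  specs <- list(learner_spec("glm_poly2"), learner_spec("sre"))
  res <- suppressWarnings(
    run_approaches(sc$dependent, sc$host, sc$climate$current,
                   sc$climate$future, specs, seed = 47))
  ov <- res$overlap$binary$future$presence
  no <- res$none$binary$future$presence
  expect_true(all(no[ov %in% TRUE]))
})

test_that("a constant host layer reduces explanatory to the baseline", {
  sc <- small_scenario(seed = 53)
  g <- sc$climate$current$grid
  const_host <- suitability_map(g, "host", "current",
                                rep(0.4, n_cells(g)))
  const_host_f <- suitability_map(g, "host", "future",
                                  rep(0.4, n_cells(g)))
  specs <- list(learner_spec("glm_poly2"))
  expect_warning(
    ex <- approach_explanatory(sc$dependent, sc$climate$current,
                               sc$climate$future, const_host, const_host_f,
                               specs, seed = 53),
    "zero-variance")
  base <- model_no_interaction(sc$dependent, sc$climate$current,
                               sc$climate$future, specs, seed = 53)
  expect_equal(ex$suitability$future$probability,
               base$suitability$future$probability, tolerance = 1e-12)
  expect_equal(ex$threshold, base$threshold)
})

test_that("the host predictor earns positive importance for an obligate", {
  sc <- small_scenario(seed = 59)
  specs <- list(learner_spec("glm_poly2"))
  host_res <- model_no_interaction(sc$host, sc$climate$current,
                                   sc$climate$future, specs, seed = 60)
  ex <- approach_explanatory(sc$dependent, sc$climate$current,
                             sc$climate$future,
                             host_res$suitability$current,
                             host_res$suitability$future, specs, seed = 59)
  aug <- add_variable(sc$climate$current, "host_prob",
                      host_res$suitability$current$probability)
  imp <- variable_importance(ex$ensemble, aug, n_perm = 5, seed = 59)
  expect_gt(imp[["host_prob"]], 0)
})

test_that("zeroing future host probability cannot raise future projections", {
  sc <- small_scenario(seed = 61)
  g <- sc$climate$current$grid
  specs <- list(learner_spec("glm_poly2"))
  host_res <- model_no_interaction(sc$host, sc$climate$current,
                                   sc$climate$future, specs, seed = 62)
  zero_host <- suitability_map(g, "host", "future", rep(0, n_cells(g)))
  # future climate kept equal to current so only the host layer differs
  ex <- approach_explanatory(sc$dependent, sc$climate$current,
                             sc$climate$current,
                             host_res$suitability$current, zero_host,
                             specs, seed = 61)
  member <- ex$ensemble$members[[1]]
  cf <- coef(member)
  b1 <- cf[["host_prob"]]; b2 <- cf[["I(host_prob^2)"]]
  h <- host_res$suitability$current$probability
  monotone_up <- b1 * h + b2 * h^2 >= 0  # eta(h) >= eta(0) cellwise
  cur <- ex$suitability$current$probability
  fut <- ex$suitability$future$probability
  expect_true(all(fut[monotone_up] <= cur[monotone_up] + 1e-10))
})

test_that("reference-area result is the product of conditional and host maps", {
  sc <- small_scenario(seed = 67)
  specs <- list(learner_spec("glm_poly2"), learner_spec("sre"))
  host_res <- model_no_interaction(sc$host, sc$climate$current,
                                   sc$climate$future, specs, seed = 68)
  ra <- approach_reference_area(sc$dependent, sc$host, sc$climate$current,
                                sc$climate$future,
                                host_res$suitability$current,
                                host_res$suitability$future, specs,
                                seed = 67)
  for (period in c("current", "future")) {
    fin <- ra$suitability[[period]]$probability
    cond <- ra$conditional[[period]]$probability
    hst <- host_res$suitability[[period]]$probability
    expect_equal(fin, cond * hst, tolerance = 1e-12)
    expect_true(all(fin <= pmin(cond, hst) + 1e-12, na.rm = TRUE))
  }
  # calibration area is exactly the host's observed presences
  expect_setequal(ra$calibration_cells,
                  sc$host$grid$cell_ids[sc$host$status == "present"])
  # training restricted to the calibration area
  expect_true(all(ra$split$training %in% ra$calibration_cells))
  expect_length(ra$non_analogue, n_cells(sc$host))
})

test_that("a saturated host probability map leaves the conditional model", {
  sc <- small_scenario(seed = 71)
  g <- sc$climate$current$grid
  ones_c <- suitability_map(g, "host", "current", rep(1, n_cells(g)))
  ones_f <- suitability_map(g, "host", "future", rep(1, n_cells(g)))
  specs <- list(learner_spec("glm_poly2"))
  ra <- approach_reference_area(sc$dependent, sc$host, sc$climate$current,
                                sc$climate$future, ones_c, ones_f, specs,
                                seed = 71)
  expect_equal(ra$suitability$future$probability,
               ra$conditional$future$probability)
})

test_that("reference area requires host presences and two classes", {
  sc <- small_scenario(seed = 73)
  g <- sc$climate$current$grid
  empty_host <- occurrence_map(g, "host", rep("absent", n_cells(g)))
  hs <- suitability_map(g, "host", "current", rep(0.5, n_cells(g)))
  expect_error(
    approach_reference_area(sc$dependent, empty_host, sc$climate$current,
                            sc$climate$future, hs, hs,
                            list(learner_spec("glm_poly2")), seed = 73),
    "host presences")
})

test_that("evaluation table mirrors the per-approach reports", {
  sc <- small_scenario(seed = 79)
  specs <- list(learner_spec("glm_poly2"), learner_spec("sre"))
  res <- suppressWarnings(
    run_approaches(sc$dependent, sc$host, sc$climate$current,
                   sc$climate$future, specs, seed = 79))
  tab <- evaluation_table(res)
  expect_setequal(tab$approach, c("none", "overlap", "explanatory",
                                  "reference_area", "host"))
  i <- which(tab$approach == "none")
  expect_equal(tab$auc[i], res$none$evaluation$auc)
  expect_equal(tab$omission_rate_pct[i],
               100 * res$none$evaluation$omission_rate)
})
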