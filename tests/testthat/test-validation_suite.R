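test_that("accuracy and precision follow the guideline arithmetic", {
  fit <- exact_fit(1, 0)
  cell <- accuracy_precision(area_records(c(100, 100, 100)), fit, 100)
  expect_equal(cell$accuracy, 100)
  expect_equal(cell$precision, 0)
  expect_true(cell$pass)

  cell <- accuracy_precision(area_records(c(90, 100, 110)), fit, 100)
  expect_equal(cell$accuracy, 100)
  expect_equal(cell$precision, 10, tolerance = 1e-12)  # sd = 10, mean = 100
  expect_true(cell$pass)

  # 117 % fails the QC window (85-115 %) but passes the LLOQ window (80-120 %)
  cell <- accuracy_precision(area_records(rep(117, 3)), fit, 100)
  expect_equal(cell$accuracy, 117)
  expect_false(cell$pass)
  cell <- accuracy_precision(area_records(rep(117, 3)), fit, 100,
                             lloq_level = TRUE)
  expect_true(cell$pass)

  expect_error(accuracy_precision(area_records(100), fit, 100),
               class = "otval_insufficient_replicates_error")
})

test_that("between-run pooling over identical runs matches within-run", {
  fit <- exact_fit(1, 0)
  one_run <- area_records(c(92, 101, 105, 98, 99))
  runs <- dplyr::bind_rows(
    one_run,
    dplyr::mutate(one_run, run_id = "run2"),
    dplyr::mutate(one_run, run_id = "run3")
  )
  within <- accuracy_precision(one_run, fit, 100, "within_run")
  between <- accuracy_precision(runs, fit, 100, "between_run")
  expect_equal(between$accuracy, within$accuracy)
  # pooled CV over k identical copies shrinks sd by the (n-1) denominator only
  expect_equal(between$precision,
               100 * sd(rep(c(92, 101, 105, 98, 99), 3)) / mean(c(92, 101, 105, 98, 99)))
  expect_equal(between$n, 15)
  expect_error(accuracy_precision(runs, fit, 100, "within_run"),
               class = "otval_contract_error")
})

test_that("selectivity is the blank-to-LLOQ area ratio with IS threshold 5 %", {
  cfg <- study_config()
  lloq <- area_records(rep(1000, 5), level = 1, role = "calibrant")
  zero_blanks <- area_records(rep(0, 6), level = NA, role = "blank")
  out <- selectivity(zero_blanks, lloq, cfg)
  expect_equal(out$selectivity, 0)
  expect_true(out$pass)

  blanks <- area_records(61 * c(0.5, 0.8, 1.0, 1.2, 1.5, 1.0),
                         level = NA, role = "blank")
  out <- selectivity(blanks, lloq, cfg)
  expect_equal(out$selectivity, 6.1, tolerance = 1e-10)
  expect_true(out$pass)

  is_blanks <- area_records(rep(60, 6), level = NA, role = "blank",
                            analyte = "TBT_d27")
  is_lloq <- area_records(rep(1000, 5), level = 1, role = "calibrant",
                          analyte = "TBT_d27")
  out <- selectivity(is_blanks, is_lloq, cfg)
  expect_equal(out$selectivity, 6)
  expect_false(out$pass)   # IS threshold is 5 %

  expect_error(selectivity(blanks, area_records(rep(0, 2), level = 1,
                                                role = "calibrant"), cfg),
               class = "otval_degenerate_error")
})

test_that("carry-over is the blank/LLOQ area ratio and is scale invariant", {
  expect_equal(carry_over(0, 1000), 0)
  expect_equal(carry_over(12.1, 1000), 1.21)
  expect_equal(carry_over(250, 1000), 25)
  expect_error(carry_over(5, 0), class = "otval_degenerate_error")
  set.seed(5)
  for (i in 1:10) {
    a <- stats::runif(1, 1, 100); b <- stats::runif(1, 500, 5000)
    k <- stats::runif(1, 0.01, 100)
    expect_equal(carry_over(k * a, k * b), carry_over(a, b))
  }
})

test_that("stability compares condition sets to fresh references", {
  ref <- area_records(rep(200, 5), level = 4000, role = "stability",
                      condition = "reference")
  same <- dplyr::mutate(ref, condition = "freeze_thaw")
  out <- stability(same, ref, "freeze_thaw")
  expect_equal(out$stability, 100)
  expect_true(out$pass)

  up <- dplyr::mutate(ref, peak_area = peak_area * 1.06, condition = "stock_30d")
  out <- stability(up, ref, "stock_30d")
  expect_equal(out$stability, 106)
  expect_true(out$pass)

  down <- dplyr::mutate(ref, peak_area = peak_area * 0.80, condition = "freeze_thaw")
  out <- stability(down, ref, "freeze_thaw")
  expect_equal(out$stability, 80)
  expect_false(out$pass)

  zero_ref <- dplyr::mutate(ref, peak_area = 0)
  expect_error(stability(same, zero_ref, "x"), class = "otval_degenerate_error")
})

test_that("selectivity and carry-over are invariant to detector rescaling", {
  cfg <- study_config()
  lloq <- area_records(c(980, 1010, 1000), level = 1, role = "calibrant")
  blanks <- area_records(c(40, 70, 55, 62, 48, 66), level = NA, role = "blank")
  base <- selectivity(blanks, lloq, cfg)$selectivity
  for (k in c(0.01, 3.7, 1e4)) {
    scaled <- selectivity(dplyr::mutate(blanks, peak_area = peak_area * k),
                          dplyr::mutate(lloq, peak_area = peak_area * k), cfg)
    expect_equal(scaled$selectivity, base, tolerance = 1e-12)
  }
})

test_that("acceptance verdict is a pure conjunction over blocks", {
  cfg <- study_config()
  ap <- tibble::tibble(pass = c(TRUE, TRUE, TRUE))
  st <- tibble::tibble(pass = TRUE)
  v <- evaluate_acceptance(list(accuracy_precision = ap, stability = st), cfg)
  expect_true(v$pass[v$block == "overall"])
  expect_true(is.na(v$pass[v$block == "carry_over"]))  # not run

  st_bad <- tibble::tibble(pass = c(TRUE, FALSE))
  v2 <- evaluate_acceptance(list(accuracy_precision = ap, stability = st_bad), cfg)
  expect_false(v2$pass[v2$block == "stability"])
  expect_false(v2$pass[v2$block == "overall"])

  # purity: same cells, same verdict
  expect_identical(v, evaluate_acceptance(list(accuracy_precision = ap,
                                               stability = st), cfg))
})

test_that("panel helpers reproduce the single-cell results on a full study", {
  sim <- simulate_study(simulation_truth(seed = 21), scenario_spec())
  cfg <- study_config()
  fits <- calibrate_study(sim$measurements, cfg)
  limits <- purrr::map_dfr(fits, decide_limits,
                           calibrant_records = sim$measurements, config = cfg)
  ap <- accuracy_precision_panel(sim$measurements, fits, limits, cfg)
  expect_true(all(c("within_run", "between_run") %in% ap$scope))
  # every configured QC level appears for both analytes
  for (an in cfg$analytes) {
    expect_true(all(cfg$qc_levels[[an]] %in% ap$level[ap$analyte == an]))
  }
  between <- ap[ap$scope == "between_run" & ap$analyte == "TBT" & ap$level == 2500, ]
  expect_equal(between$n, 15)
  direct <- accuracy_precision(
    dplyr::filter(sim$measurements, role == "qc", analyte == "TBT",
                  nominal_conc == 2500),
    fits$TBT, 2500, "between_run", config = cfg)
  expect_equal(between$accuracy, direct$accuracy)

  co <- carry_over_panel(sim$measurements, limits, cfg)
  expect_setequal(co$analyte, c("TBT", "TPhT", "TBT_d27"))
  expect_true(all(co$pass))
  sel <- selectivity_panel(sim$measurements, limits, cfg)
  expect_true(all(sel$pass))
  st <- stability_panel(sim$measurements, fits, cfg)
  expect_equal(nrow(st), 2 * 2 * 5)  # analytes x levels x conditions
  expect_true(all(st$pass))
})
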