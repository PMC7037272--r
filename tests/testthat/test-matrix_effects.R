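test_that("extraction recovery is the mean pre/ref area ratio", {
  expect_equal(extraction_recovery(c(70, 80), c(70, 80)), 100)
  expect_equal(extraction_recovery(c(50, 60), c(100, 100)), 55)
  pre <- vec_with(932, 61, 10); ref <- vec_with(1000, 40, 10)
  expect_equal(extraction_recovery(pre, ref), 93.2, tolerance = 1e-10)
  expect_error(extraction_recovery(c(1, 2), c(0, 0)),
               class = "otval_degenerate_error")
  expect_error(extraction_recovery(numeric(), c(1)),
               class = "otval_insufficient_data_error")
})

test_that("absolute matrix effect is the matrix/water slope ratio", {
  water <- exact_fit(1000, 5)
  expect_equal(absolute_matrix_effect(water, water), 100)
  expect_equal(absolute_matrix_effect(exact_fit(580, 5), water), 58)
  expect_equal(absolute_matrix_effect(exact_fit(1200, 5), water), 120)
  ratio_fit <- exact_fit(0.02, 0, response_kind = "is_ratio")
  expect_error(absolute_matrix_effect(ratio_fit, water),
               class = "otval_contract_error")
  zero <- water; zero$slope <- 0
  expect_error(absolute_matrix_effect(water, zero),
               class = "otval_degenerate_error")
})

test_that("relative matrix effect is the CV of analyte/IS ME ratios", {
  out <- relative_matrix_effect(c(58, 70, 90), c(58, 70, 90))
  expect_equal(out$me_r, 0)   # IS tracks the analyte exactly
  expect_true(out$pass)

  out <- relative_matrix_effect(c(90, 100, 110), c(100, 100, 100))
  expect_equal(out$me_r, 10, tolerance = 1e-12)
  expect_true(out$pass)

  out <- relative_matrix_effect(c(50, 100, 150), c(100, 100, 100))
  expect_equal(out$me_r, 50, tolerance = 1e-12)
  expect_false(out$pass)

  expect_error(relative_matrix_effect(c(1, 2), c(1, 0)),
               class = "otval_degenerate_error")
  expect_error(relative_matrix_effect(1, 1),
               class = "otval_insufficient_data_error")
})

test_that("matrix effects and recovery are scale invariant in detector units", {
  set.seed(17)
  x <- c(50, 100, 500, 1000, 2500)
  y_w <- 900 * x + rnorm(5, 0, 20)
  y_m <- 600 * x + rnorm(5, 0, 20)
  me <- function(k) {
    absolute_matrix_effect(
      fit_weighted_line(x, k * y_m, "one_over_x", response_kind = "raw_area"),
      fit_weighted_line(x, k * y_w, "one_over_x", response_kind = "raw_area"))
  }
  expect_equal(me(1), me(37.5), tolerance = 1e-10)
  expect_equal(extraction_recovery(c(5, 6), c(10, 10)),
               extraction_recovery(1e4 * c(5, 6), 1e4 * c(10, 10)))
})

test_that("trueness verdict follows the expanded uncertainty of the bias", {
  m <- vec_with(480, 25, 6)
  out <- trueness_vs_crm(m, 480, u_ref = 0, k = 2)
  expect_equal(out$delta, 0)
  expect_true(out$compatible)

  m <- vec_with(450, 30, 6)
  out <- trueness_vs_crm(m, 480, u_ref = 40, k = 2)
  expect_equal(out$delta, 30)
  expect_equal(out$u_delta, 2 * sqrt(40^2 + 30^2 / 6), tolerance = 1e-12)
  expect_true(out$compatible)

  m <- vec_with(30, 2, 6)
  out <- trueness_vs_crm(m, 29, u_ref = 5.5, k = 2)
  expect_equal(out$delta, 1)
  expect_true(out$compatible)

  expect_error(trueness_vs_crm(c(480), 480, 40),
               class = "otval_insufficient_replicates_error")
})

test_that("compatibility is monotone nondecreasing in u_ref and k", {
  m <- vec_with(430, 20, 6)   # delta = 50
  for (u in c(0, 10, 20, 26, 40, 80)) {
    for (k in c(1, 2, 3)) {
      out <- trueness_vs_crm(m, 480, u, k)
      if (out$compatible) {
        expect_true(trueness_vs_crm(m, 480, u + 15, k)$compatible)
        expect_true(trueness_vs_crm(m, 480, u, k + 1)$compatible)
      }
    }
  }
  # boundary counts as compatible
  m0 <- vec_with(470, 0, 4)
  expect_true(trueness_vs_crm(m0, 480, u_ref = 5, k = 2)$compatible)
})

test_that("sieving comparison matches the paired-t oracle", {
  before <- c(80, 75, 77, 70, 84); after <- c(70, 65, 66, 62, 65)
  out <- compare_sieving(before, after, matrix_id = paste0("S", 1:5))
  oracle <- t.test(before, after, paired = TRUE)
  expect_equal(out$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(out$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(out$mean_before, mean(before))
  expect_equal(out$sd_after, sd(after))

  same <- compare_sieving(c(70, 80, 90), c(70, 80, 90))
  expect_equal(same$p_value, 1)
  expect_equal(same$t, 0)

  expect_error(compare_sieving(70, 60), class = "otval_pairing_error")
  set.seed(9)
  for (i in 1:10) {
    a <- stats::runif(6, 50, 100); b <- a - stats::runif(6, -5, 15)
    expect_equal(compare_sieving(a, b)$p_value,
                 t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("study-level matrix-effect table recovers the latent factors", {
  truth <- simulation_truth(seed = 31)
  sim <- simulate_study(truth, scenario_spec())
  me <- matrix_effect_table(sim$measurements, study_config())
  tbt <- me$per_matrix[me$per_matrix$analyte == "TBT", ]
  tbt <- tbt[match(truth$matrices$matrix_id, tbt$matrix_id), ]
  expect_equal(tbt$me_a, 100 * truth$matrices$suppression_TBT, tolerance = 0.08)
  expect_equal(tbt$re, 100 * truth$matrices$recovery, tolerance = 0.08)
  expect_equal(tbt$is_me_a, 100 * truth$matrices$suppression_IS, tolerance = 0.08)
  expect_true(all(me$me_r$me_r < 15))
})
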