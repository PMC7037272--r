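test_that("noiseless points are fit exactly under every weighting", {
  x <- c(1, 10, 100)
  for (w in c("none", "one_over_x", "one_over_x2")) {
    fit <- fit_weighted_line(x, 2 * x + 1, weighting = w)
    expect_equal(fit$slope, 2, tolerance = 1e-12)
    expect_equal(fit$intercept, 1, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
  expect_error(fit_weighted_line(c(1, 1, 2), c(1, 1, 2)),
               class = "otval_insufficient_data_error")
  expect_error(fit_weighted_line(c(0, 1, 2), c(0, 1, 2), "one_over_x"),
               class = "otval_domain_error")
})

test_that("weighted fit equals the closed-form normal equations on random instances", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    x <- sort(stats::runif(n, 0.5, 4000))
    y <- 0.8 * x + 5 + rnorm(n, 0, 0.05 * (x + 10))
    for (w in c("none", "one_over_x", "one_over_x2")) {
      wts <- switch(w, none = rep(1, n), one_over_x = 1 / x, one_over_x2 = 1 / x^2)
      oracle <- wls_oracle(x, y, wts)
      fit <- fit_weighted_line(x, y, weighting = w)
      expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
      expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
      expect_equal(fit$slope_se, oracle$slope_se, tolerance = 1e-8)
      expect_equal(fit$intercept_se, oracle$intercept_se, tolerance = 1e-8)
      # p-values from the t distribution with n - 2 df
      expect_equal(fit$p_slope,
                   2 * pt(-abs(oracle$slope / oracle$slope_se), n - 2),
                   tolerance = 1e-10)
    }
  }
})

test_that("back-calculation inverts the line, including the round trip", {
  fit <- exact_fit(2, 1)
  expect_equal(back_calculate(fit, 21), 10)
  expect_equal(back_calculate(fit, fit$intercept), 0)
  for (x in c(1, 50, 4000)) {
    expect_equal(back_calculate(fit, fit$slope * x + fit$intercept), x)
  }
  broken <- fit; broken$slope <- 0
  expect_error(back_calculate(broken, 10), class = "otval_degenerate_error")
})

test_that("slopes are significant across replicate heteroscedastic curves", {
  set.seed(202)
  levels <- c(1, 5, 25, 100, 500, 2000, 4000)
  for (i in 1:6) {
    y <- 0.00073 * levels * (1 + rnorm(7, 0, 0.05)) + 0.005
    fit <- fit_weighted_line(levels, y, weighting = "one_over_x")
    expect_lt(fit$p_slope, 0.05)
  }
})

test_that("1/x weighting tightens low-level back-calculated accuracy", {
  set.seed(303)
  levels <- c(1, 5, 25, 100, 500, 2000, 4000)
  acc_w <- acc_u <- numeric(200)
  for (i in 1:200) {
    y <- 1000 * levels * (1 + rnorm(7, 0, 0.05))
    fw <- fit_weighted_line(levels, y, weighting = "one_over_x")
    fu <- fit_weighted_line(levels, y, weighting = "none")
    acc_w[i] <- back_calculate(fw, y[1])
    acc_u[i] <- back_calculate(fu, y[1])
  }
  expect_lt(sd(acc_w), sd(acc_u))
})

test_that("limit decision applies S/N, precision and accuracy gates", {
  fit <- exact_fit(1000, 0)
  mk <- function(level, areas, noise) {
    area_records(areas, level = level, role = "calibrant", noise_sd = noise)
  }
  # level 1: S/N 5.3, CV ~1.9 %, accuracy ~102 % -> accepted
  areas1 <- 1000 * 1.02 * c(0.98, 0.99, 1.00, 1.01, 1.02)
  rec <- dplyr::bind_rows(
    mk(1, areas1, noise = mean(areas1) / 5.3),
    mk(5, 5000 * c(0.97, 1.0, 1.03), noise = 100)
  )
  lim <- decide_limits(rec, fit, study_config())
  expect_equal(lim$lloq, 1)
  expect_equal(lim$sn_at_lloq, 5.3, tolerance = 1e-10)
  expect_equal(lim$lod, 1 * 3 / 5.3, tolerance = 1e-10)
  expect_equal(lim$lloq_accuracy, 102, tolerance = 0.1)

  # S/N 5.0 exactly at 1 ng/g -> LOD 0.6
  areas_sn5 <- rep(1000, 5) * c(0.99, 1.0, 1.0, 1.0, 1.01)
  lim2 <- decide_limits(mk(1, areas_sn5, noise = mean(areas_sn5) / 5),
                        fit, study_config())
  expect_equal(lim2$lod, 0.6, tolerance = 1e-12)

  # CV 25 % is rejected on precision regardless of S/N; the next level wins
  noisy <- 1000 * c(0.7, 0.85, 1.0, 1.15, 1.3)   # CV ~ 24 %
  rec3 <- dplyr::bind_rows(
    mk(1, noisy, noise = mean(noisy) / 50),
    mk(5, 5000 * c(0.98, 1.0, 1.02), noise = 5000 / 8)
  )
  lim3 <- decide_limits(rec3, fit, study_config())
  expect_equal(lim3$lloq, 5)

  # no passing level -> error naming the failing criteria
  expect_error(decide_limits(mk(1, noisy, noise = mean(noisy) / 50), fit,
                             study_config()),
               "CV", class = "otval_no_lloq_error")
})

test_that("raising the S/N threshold never lowers the LLOQ", {
  set.seed(404)
  fit <- exact_fit(1000, 0)
  for (i in 1:20) {
    levels <- c(1, 5, 25)
    rec <- purrr::map_dfr(levels, function(lv) {
      areas <- 1000 * lv * (1 + rnorm(5, 0, 0.05))
      area_records(areas, level = lv, role = "calibrant",
                   noise_sd = stats::runif(1, 150, 1500))
    })
    lloq_at <- function(sn) {
      cfg <- study_config(sn_lloq = sn, sn_lod = min(3, sn))
      tryCatch(decide_limits(rec, fit, cfg)$lloq,
               otval_no_lloq_error = function(e) Inf)
    }
    lims <- vapply(c(2, 5, 10, 20), lloq_at, numeric(1))
    expect_true(all(diff(lims) >= 0))
  }
})

test_that("calibrate_study fits per analyte on the configured response", {
  sim <- simulate_study(simulation_truth(seed = 11), scenario_spec())
  fits <- calibrate_study(sim$measurements, study_config())
  expect_named(fits, c("TBT", "TPhT"))
  expect_equal(fits$TBT$response_kind, "is_ratio")
  expect_equal(fits$TBT$weighting, "one_over_x")
  # IS-ratio slope recovers true slope / nominal IS area within a few percent
  expect_equal(fits$TBT$slope, 1000 / 50000, tolerance = 0.05)
  raw <- calibrate_study(sim$measurements, study_config(), "raw_area")
  expect_equal(raw$TPhT$slope, 400, tolerance = 0.05)
  td <- tidy(fits$TBT)
  expect_equal(td$term, c("slope", "intercept"))
  expect_equal(glance(fits$TBT)$n_points, 42)
})
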