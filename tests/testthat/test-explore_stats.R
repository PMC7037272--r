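test_that("spearman rho matches the brute-force rank formula", {
  out <- spearman_cor(1:6, (1:6)^3)
  expect_equal(out$rho, 1)
  out <- spearman_cor(1:6, -(1:6))
  expect_equal(out$rho, -1)

  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  out <- spearman_cor(x, y)
  d <- rank(x) - rank(y)        # no ties: 1 - 6*sum(d^2)/(n(n^2-1))
  expect_equal(out$rho, 1 - 6 * sum(d^2) / (5 * 24), tolerance = 1e-12)
  expect_equal(out$rho, 0.8)
  # t-approximation p-value, n - 2 df
  tt <- out$rho * sqrt((5 - 2) / (1 - out$rho^2))
  expect_equal(out$p_value, 2 * pt(-abs(tt), 3), tolerance = 1e-12)
  # rho agrees with the reference implementation, ties included
  set.seed(12)
  for (i in 1:10) {
    a <- sample(1:8, 10, replace = TRUE); b <- sample(1:8, 10, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_cor(a, b)$rho,
                 unname(suppressWarnings(
                   stats::cor.test(a, b, method = "spearman")$estimate)),
                 tolerance = 1e-10)
  }

  expect_error(spearman_cor(1:3, 1:3), class = "otval_insufficient_data_error")
  expect_error(spearman_cor(1:5, rep(2, 5)), class = "otval_degenerate_error")
  # pairwise-complete: missing pairs are dropped before the n >= 4 check
  expect_error(spearman_cor(c(1, 2, 3, NA, NA), c(1, 2, 3, 4, 5)),
               class = "otval_insufficient_data_error")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(23)
  for (i in 1:15) {
    x <- stats::runif(9, 1, 100); y <- stats::runif(9, 1, 100)
    base <- spearman_cor(x, y)$rho
    expect_equal(spearman_cor(exp(x / 20), y)$rho, base)
    expect_equal(spearman_cor(x, log(y))$rho, base)
    expect_equal(spearman_cor(-1 / x, y)$rho, base)
  }
})

test_that("correlation screen joins by matrix, drops missing pairwise", {
  prof <- odra_sediment_profiles()
  resp <- tibble::tibble(matrix_id = prof$matrix_id, me_a = prof$toc * 2 + 1)
  out <- correlation_screen(resp, prof, properties = c("toc", "pah"))
  expect_equal(out$rho[out$property == "toc"], 1)
  expect_true(out$significant[out$property == "toc"])
  # pah has 4 missing entries; cell still computed from the 6 complete pairs
  expect_equal(out$n[out$property == "pah"], 6)

  prof2 <- prof; prof2$pah <- NA_real_
  out2 <- correlation_screen(resp, prof2, properties = c("toc", "pah"))
  expect_false("pah" %in% out2$property)
})

test_that("shuffled matrix labels destroy significance at the nominal rate", {
  set.seed(34)
  x <- stats::runif(10)
  hits <- 0; n_shuffle <- 400
  for (i in seq_len(n_shuffle)) {
    if (spearman_cor(x, sample(stats::runif(10)))$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_shuffle, 0.01)
  expect_lt(hits / n_shuffle, 0.10)
})

test_that("PCA standardizes, decomposes and reconstructs", {
  prof <- tibble::tibble(
    matrix_id = paste0("M", 1:6),
    a = c(1, 2, 3, 4, 5, 6), b = 2 * c(1, 2, 3, 4, 5, 6) + 3,
    c = c(2, 1, 4, 3, 6, 5)
  )
  # two perfectly correlated variables: PC1 of (a, b) explains 100 %
  m2 <- pca_profiles(prof, c("a", "b"))
  expect_equal(m2$var_explained[1], 100, tolerance = 1e-10)

  set.seed(45)
  prof5 <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(20), 5, 4)),
                                      c("w", "x", "y", "z")))
  prof5$matrix_id <- paste0("M", 1:5)
  model <- pca_profiles(prof5, c("w", "x", "y", "z"))
  expect_equal(sum(model$var_explained), 100, tolerance = 1e-10)
  # loadings columns are orthonormal
  expect_equal(crossprod(model$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  # full reconstruction: scores %*% t(loadings), unscaled, equals the data
  recon <- model$scores %*% t(model$loadings)
  recon <- sweep(sweep(recon, 2, model$scale, `*`), 2, model$center, `+`)
  expect_equal(unname(recon), unname(as.matrix(prof5[, c("w", "x", "y", "z")])),
               tolerance = 1e-10)

  # signed permutations of variables leave the spectrum unchanged
  prof_perm <- prof5
  prof_perm$w <- -prof5$y; prof_perm$y <- prof5$w
  model_p <- pca_profiles(prof_perm, c("w", "x", "y", "z"))
  expect_equal(sort(model_p$var_explained), sort(model$var_explained),
               tolerance = 1e-10)

  prof_degenerate <- prof; prof_degenerate$a <- 5
  expect_error(pca_profiles(prof_degenerate, c("a", "b")), "a",
               class = "otval_degenerate_variable_error")
})

test_that("biplot coordinates are bounded by the singular-value scale", {
  set.seed(56)
  prof <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(40), 8, 5)),
                                     letters[1:5]))
  prof$matrix_id <- paste0("M", 1:8)
  model <- pca_profiles(prof, letters[1:5])
  bd <- biplot_data(model, c(2, 4))
  expect_equal(nrow(bd$scores), 8)
  expect_true(all(abs(bd$arrows$x) <= model$sdev[2] + 1e-12))
  expect_true(all(abs(bd$arrows$y) <= model$sdev[4] + 1e-12))
  expect_error(biplot_data(model, c(2, 6)), class = "otval_index_error")
})

test_that("Welch test from summary statistics matches the closed form", {
  out <- welch_t_from_summary(10, 1, 5, 10, 1, 5)
  expect_equal(out$p_value, 1)
  expect_equal(out$t, 0)

  # hand closed form on (10, 1, 5) vs (12, 1, 5)
  se2 <- 1 / 5 + 1 / 5
  t_hand <- (10 - 12) / sqrt(se2)
  df_hand <- se2^2 / ((1 / 5)^2 / 4 + (1 / 5)^2 / 4)
  out <- welch_t_from_summary(10, 1, 5, 12, 1, 5)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$df, df_hand, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  # cross-check against t.test on data realising those exact summaries
  a <- vec_with(10, 1, 5); b <- vec_with(12, 1, 5)
  expect_equal(out$p_value, t.test(a, b)$p.value, tolerance = 1e-10)

  # clearly separated extraction-condition groups
  out <- welch_t_from_summary(69.3, 2.7, 5, 89.0, 1.5, 5)
  expect_lt(out$p_value, 0.001)
})
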