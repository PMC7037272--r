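#' Compute the instrument response used for calibration
#'
#' Response is the analyte/IS peak-area ratio when `response_kind =
#' "is_ratio"` (the study's quantification mode, with deuterated TBT as
#' internal standard), or the raw analyte area when `"raw_area"` (the mode
#' matrix-effect slope ratios require).
#'
#' @param data Measurement tibble.
#' @param response_kind `"is_ratio"` or `"raw_area"`.
#' @return Numeric response vector.
#' @keywords internal
measurement_response <- function(data, response_kind = c("is_ratio", "raw_area")) {
  response_kind <- match.arg(response_kind)
  if (response_kind == "raw_area") return(data$peak_area)
  if (any(is.na(data$is_area))) {
    abort("is_ratio response requested but is_area is missing for some rows.",
          class = "otval_contract_error")
  }
  data$peak_area / data$is_area
}

#' Fit a weighted calibration line
#'
#' Weighted least squares for the line y = a x + b with weights 1/x (the
#' default, appropriate for heteroscedastic MS responses whose noise grows
#' with concentration), 1/x^2, or none. Parameter standard errors and
#' two-sided p-values come from the t distribution with n - 2 degrees of
#' freedom; R^2 is computed on the weighted residuals, with the unweighted
#' R^2 also reported for comparison.
#'
#' @param x Nominal concentrations (ng/g). Must be positive under 1/x or
#'   1/x^2 weighting — blanks are never calibration points.
#' @param y Instrument responses.
#' @param weighting `"one_over_x"`, `"none"`, or `"one_over_x2"`.
#' @param analyte Optional analyte label stored in the fit.
#' @param response_kind Label recording what y is: `"is_ratio"` or
#'   `"raw_area"`.
#' @return An object of class `calibration_fit`.
#' @export
#' @examples
#' fit <- fit_weighted_line(c(1, 10, 100), c(3, 21, 201), weighting = "none")
#' fit$slope
fit_weighted_line <- function(x, y,
                              weighting = c("one_over_x", "none", "one_over_x2"),
                              analyte = NA_character_,
                              response_kind = c("is_ratio", "raw_area")) {
  weighting <- match.arg(weighting)
  response_kind <- match.arg(response_kind)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3) {
    abort("Calibration requires >= 3 distinct concentration levels.",
          class = "otval_insufficient_data_error")
  }
  if (weighting != "none" && any(x <= 0)) {
    abort("x must be > 0 under 1/x or 1/x^2 weighting.", class = "otval_domain_error")
  }
  w <- switch(weighting, none = rep(1, length(x)), one_over_x = 1 / x,
              one_over_x2 = 1 / x^2)
  fit <- lm(y ~ x, weights = w)
  # noiseless calibrants are legitimate input; silence only the perfect-fit note
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w_) {
      if (grepl("essentially perfect fit", conditionMessage(w_))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  yhat <- fitted(fit)
  r2_unw <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  structure(
    list(
      analyte = analyte,
      slope = unname(co["x", "Estimate"]),
      intercept = unname(co["(Intercept)", "Estimate"]),
      slope_se = unname(co["x", "Std. Error"]),
      intercept_se = unname(co["(Intercept)", "Std. Error"]),
      p_slope = unname(co["x", "Pr(>|t|)"]),
      p_intercept = unname(co["(Intercept)", "Pr(>|t|)"]),
      r_squared = sm$r.squared,
      r_squared_unweighted = r2_unw,
      weighting = weighting,
      response_kind = response_kind,
      n_points = length(x),
      df_residual = fit$df.residual
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>", if (!is.na(x$analyte)) x$analyte else "", "\n")
  cat(sprintf("  y = %.6g x + %.6g  (%s response, %s weighting)\n",
              x$slope, x$intercept, x$response_kind, x$weighting))
  cat(sprintf("  slope se %.3g (p = %.3g); intercept se %.3g (p = %.3g)\n",
              x$slope_se, x$p_slope, x$intercept_se, x$p_intercept))
  cat(sprintf("  weighted R^2 = %.4f (unweighted %.4f), n = %d\n",
              x$r_squared, x$r_squared_unweighted, x$n_points))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte,
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    std.error = c(x$slope_se, x$intercept_se),
    p.value = c(x$p_slope, x$p_intercept)
  )
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte, slope = x$slope, intercept = x$intercept,
    r.squared = x$r_squared, r.squared.unweighted = x$r_squared_unweighted,
    weighting = x$weighting, response_kind = x$response_kind,
    n_points = x$n_points
  )
}

#' Fit calibration lines for each analyte in a measurement table
#'
#' Filters `role == "calibrant"`, computes the configured response (analyte/IS
#' area ratio when an internal standard is assigned) and fits the weighted
#' line per analyte.
#'
#' @param data Measurement tibble containing calibrant rows.
#' @param config A [study_config()].
#' @param response_kind Response to calibrate on; default `"is_ratio"`.
#' @return A named list of `calibration_fit` objects, one per analyte.
#' @export
calibrate_study <- function(data, config = study_config(),
                            response_kind = c("is_ratio", "raw_area")) {
  response_kind <- match.arg(response_kind)
  data <- validate_measurements(data)
  cal <- dplyr::filter(data, .data$role == "calibrant",
                       .data$analyte %in% config$analytes)
  if (nrow(cal) == 0) {
    abort("No calibrant rows found.", class = "otval_insufficient_data_error")
  }
  fits <- purrr::map(split(cal, cal$analyte), function(d) {
    fit_weighted_line(d$nominal_conc, measurement_response(d, response_kind),
                      weighting = config$weighting,
                      analyte = d$analyte[1], response_kind = response_kind)
  })
  fits[intersect(config$analytes, names(fits))]
}

#' Back-calculate concentration from instrument response
#'
#' Inverts the calibration line: concentration = (response - b) / a. The
#' result may be negative for responses below the intercept; censoring
#' against LOD/LLOQ happens downstream in [quantify()].
#'
#' @param fit A `calibration_fit`.
#' @param response Numeric response vector.
#' @return Numeric concentrations (ng/g).
#' @export
back_calculate <- function(fit, response) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) {
    abort("Degenerate calibration: slope is zero.", class = "otval_degenerate_error")
  }
  (response - fit$intercept) / fit$slope
}

#' Decide quantification and detection limits
#'
#' The lower limit of quantification (LLOQ) is the lowest calibration level
#' whose replicates achieve mean S/N at or above the configured threshold
#' (default 5), replicate CV at or below 20 %, and mean back-calculated
#' accuracy within 100 +/- 20 %. S/N is `peak_area / noise_sd` using the
#' supplied baseline-noise estimate. The limit of detection is obtained by
#' linear scaling of S/N with concentration from the LLOQ point:
#' LOD = LLOQ x S/N_LOD / S/N(LLOQ).
#'
#' @param calibrant_records Measurement tibble (one analyte) with replicate
#'   rows at the candidate levels, including `noise_sd`.
#' @param fit The analyte's `calibration_fit` (for back-calculation).
#' @param config A [study_config()].
#' @return A one-row tibble: `analyte`, `lloq`, `lod`, `sn_at_lloq`,
#'   `lloq_precision` (CV %), `lloq_accuracy` (%).
#' @export
decide_limits <- function(calibrant_records, fit, config = study_config()) {
  rec <- dplyr::filter(validate_measurements(calibrant_records),
                       .data$role == "calibrant", !is.na(.data$nominal_conc))
  if (!is.na(fit$analyte)) rec <- dplyr::filter(rec, .data$analyte == fit$analyte)
  if (nrow(rec) == 0) {
    abort("No calibrant records for limit decision.",
          class = "otval_insufficient_data_error")
  }
  if (any(is.na(rec$noise_sd))) {
    abort("decide_limits requires a noise_sd estimate on every calibrant row.",
          class = "otval_contract_error")
  }
  levels <- sort(unique(rec$nominal_conc))
  tried <- list()
  for (lev in levels) {
    d <- dplyr::filter(rec, .data$nominal_conc == lev)
    conc <- back_calculate(fit, measurement_response(d, fit$response_kind))
    sn <- mean(d$peak_area / d$noise_sd)
    cv <- 100 * sd(conc) / mean(conc)
    acc <- 100 * mean(conc) / lev
    ok_sn <- sn >= config$sn_lloq
    ok_cv <- !is.na(cv) && cv <= config$precision_max_lloq
    ok_acc <- abs(acc - 100) <= config$accuracy_window_lloq
    tried[[as.character(lev)]] <- sprintf(
      "level %g: S/N %.2f [%s], CV %.2f%% [%s], accuracy %.1f%% [%s]",
      lev, sn, if (ok_sn) "ok" else "fail", cv, if (ok_cv) "ok" else "fail",
      acc, if (ok_acc) "ok" else "fail")
    if (ok_sn && ok_cv && ok_acc) {
      return(tibble::tibble(
        analyte = fit$analyte, lloq = lev,
        lod = lev * config$sn_lod / sn,
        sn_at_lloq = sn, lloq_precision = cv, lloq_accuracy = acc
      ))
    }
  }
  abort(paste0("No calibration level satisfies the LLOQ criteria:\n  ",
               paste(unlist(tried), collapse = "\n  ")),
        class = "otval_no_lloq_error")
}

#' Autoplot a calibration fit
#'
#' @param object A `calibration_fit`.
#' @param data Optional measurement tibble of calibrants to overlay as points.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.calibration_fit <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Nominal concentration (ng/g)",
      y = if (object$response_kind == "is_ratio") "Analyte/IS area ratio" else "Peak area",
      title = paste0("Calibration", if (!is.na(object$analyte)) paste0(": ", object$analyte)),
      subtitle = sprintf("y = %.4g x + %.4g, weighted R^2 = %.4f (%s)",
                         object$slope, object$intercept, object$r_squared,
                         object$weighting)
    )
  if (!is.null(data)) {
    d <- dplyr::filter(validate_measurements(data), .data$role == "calibrant")
    if (!is.na(object$analyte)) d <- dplyr::filter(d, .data$analyte == object$analyte)
    d$response <- measurement_response(d, object$response_kind)
    p <- p + ggplot2::geom_point(ggplot2::aes(x = .data$nominal_conc,
                                              y = .data$response), data = d,
                                 alpha = 0.7)
  }
  p
}
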