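#' Accuracy and precision at one concentration level
#'
#' Back-calculates each replicate through the calibration fit, then reports
#' accuracy as 100 x mean(back-calculated)/nominal and precision as the
#' replicate CV (sample standard deviation, n - 1). `scope = "within_run"`
#' restricts to a single run (pass `run_id`, or leave `NULL` when only one
#' run is present); `"between_run"` pools every run. The guideline windows
#' are 100 +/- 15 % accuracy and <= 15 % CV, relaxed to +/- 20 % / <= 20 %
#' at the LLOQ (`lloq_level = TRUE`).
#'
#' @param records Measurement tibble (one analyte) with replicates at `level`.
#' @param fit The analyte's `calibration_fit`.
#' @param level Nominal concentration (ng/g).
#' @param scope `"within_run"` or `"between_run"`.
#' @param run_id Run to restrict to when `scope = "within_run"`.
#' @param config A [study_config()].
#' @param lloq_level Logical: apply the LLOQ windows?
#' @return A one-row tibble: analyte, level, scope, run_id, accuracy,
#'   precision, n, pass.
#' @export
accuracy_precision <- function(records, fit, level,
                               scope = c("within_run", "between_run"),
                               run_id = NULL, config = study_config(),
                               lloq_level = FALSE) {
  scope <- match.arg(scope)
  rec <- dplyr::filter(validate_measurements(records),
                       .data$nominal_conc == level)
  if (!is.na(fit$analyte)) rec <- dplyr::filter(rec, .data$analyte == fit$analyte)
  if (scope == "within_run") {
    if (!is.null(run_id)) {
      rid <- run_id
      rec <- dplyr::filter(rec, .data$run_id == rid)
    } else if (length(unique(rec$run_id)) > 1) {
      abort("within_run scope with multiple runs present: pass `run_id`.",
            class = "otval_contract_error")
    }
  }
  if (nrow(rec) < 2) {
    abort("Accuracy/precision needs >= 2 replicates.",
          class = "otval_insufficient_replicates_error")
  }
  conc <- back_calculate(fit, measurement_response(rec, fit$response_kind))
  accuracy <- 100 * mean(conc) / level
  precision <- 100 * sd(conc) / mean(conc)
  acc_win <- if (lloq_level) config$accuracy_window_lloq else config$accuracy_window
  prec_max <- if (lloq_level) config$precision_max_lloq else config$precision_max
  tibble::tibble(
    analyte = fit$analyte, level = level, scope = scope,
    run_id = if (scope == "within_run") rec$run_id[1] else NA_character_,
    accuracy = accuracy, precision = precision, n = nrow(rec),
    pass = abs(accuracy - 100) <= acc_win && precision <= prec_max
  )
}

#' Full accuracy/precision panel across LLOQ and QC levels
#'
#' Computes, per analyte and level (the LLOQ plus each configured QC level),
#' the within-run cell for every run and the pooled between-run cell —
#' the layout of a standard validation table, with within-run results
#' summarisable as a min-max range across runs.
#'
#' @param records Measurement tibble with `qc` and `calibrant` roles.
#' @param fits Named list of `calibration_fit` objects from [calibrate_study()].
#' @param limits Tibble of limit decisions ([decide_limits()] rows) giving the
#'   LLOQ per analyte; optional — when absent only QC levels are evaluated.
#' @param config A [study_config()].
#' @return A tibble of accuracy/precision cells.
#' @export
accuracy_precision_panel <- function(records, fits, limits = NULL,
                                     config = study_config()) {
  records <- validate_measurements(records)
  purrr::map_dfr(names(fits), function(an) {
    fit <- fits[[an]]
    lloq <- if (!is.null(limits)) limits$lloq[limits$analyte == an][1] else NA_real_
    levels <- tibble::tibble(level = config$qc_levels[[an]], lloq_level = FALSE)
    if (!is.na(lloq)) {
      levels <- dplyr::bind_rows(
        tibble::tibble(level = lloq, lloq_level = TRUE), levels)
    }
    qc <- dplyr::filter(records, .data$analyte == an, .data$role == "qc")
    cal <- dplyr::filter(records, .data$analyte == an, .data$role == "calibrant")
    purrr::map_dfr(seq_len(nrow(levels)), function(i) {
      lev <- levels$level[i]
      is_lloq <- levels$lloq_level[i]
      src <- if (is_lloq && !any(qc$nominal_conc == lev)) cal else qc
      rows <- dplyr::filter(src, .data$nominal_conc == lev)
      if (nrow(rows) < 2) return(tibble::tibble())
      within <- purrr::map_dfr(unique(rows$run_id), function(r) {
        sub <- dplyr::filter(rows, .data$run_id == r)
        if (nrow(sub) < 2) return(tibble::tibble())
        accuracy_precision(sub, fit, lev, "within_run", config = config,
                           lloq_level = is_lloq)
      })
      between <- accuracy_precision(rows, fit, lev, "between_run",
                                    config = config, lloq_level = is_lloq)
      dplyr::bind_rows(within, between)
    })
  })
}

#' Selectivity: blank interference relative to the LLOQ signal
#'
#' The ratio (in %) of the mean blank-sediment peak area at the analyte's
#' retention time to the mean peak area at the LLOQ, with its standard
#' deviation over the blank set. Accepted below 20 % for analytes and 5 %
#' for the internal standard.
#'
#' @param blank_records Blank measurements (`role == "blank"`), one analyte.
#' @param lloq_records Measurements at the LLOQ level, same analyte.
#' @param config A [study_config()].
#' @return A one-row tibble: analyte, selectivity (%), sd, n, threshold, pass.
#' @export
selectivity <- function(blank_records, lloq_records, config = study_config()) {
  blank_records <- validate_measurements(blank_records)
  lloq_records <- validate_measurements(lloq_records)
  an <- unique(c(blank_records$analyte, lloq_records$analyte))
  if (length(an) != 1) {
    abort("selectivity expects records for exactly one analyte.",
          class = "otval_contract_error")
  }
  if (nrow(blank_records) == 0 || nrow(lloq_records) == 0) {
    abort("Both blank and LLOQ records are required.",
          class = "otval_insufficient_data_error")
  }
  a_lloq <- mean(lloq_records$peak_area)
  if (a_lloq == 0) {
    abort("Mean LLOQ peak area is zero.", class = "otval_degenerate_error")
  }
  ratio <- 100 * mean(blank_records$peak_area) / a_lloq
  ratio_sd <- 100 * sd(blank_records$peak_area) / a_lloq
  thr <- if (is_internal_standard(an, config)) config$selectivity_max_is
         else config$selectivity_max_analyte
  tibble::tibble(analyte = an, selectivity = ratio, sd = ratio_sd,
                 n = nrow(blank_records), threshold = thr, pass = ratio < thr)
}

#' Carry-over: residual signal in a blank injected after a high standard
#'
#' Carry-over (%) = 100 x A_blank / A_LLOQ, the residual analyte peak area in
#' a blank injection following a high-concentration standard, relative to the
#' LLOQ peak area. Accepted below 20 % for analytes and 5 % for the internal
#' standard.
#'
#' @param blank_area Peak area(s) of the post-high-standard blank(s), or a
#'   measurement tibble (`peak_area` is used).
#' @param lloq_area Peak area at the LLOQ (scalar or records; the mean is
#'   used).
#' @return Numeric carry-over percentage(s) (vectorised over `blank_area`).
#' @export
#' @examples
#' carry_over(12.1, 1000)  # 1.21 %
carry_over <- function(blank_area, lloq_area) {
  if (is.data.frame(blank_area)) blank_area <- validate_measurements(blank_area)$peak_area
  if (is.data.frame(lloq_area)) lloq_area <- mean(validate_measurements(lloq_area)$peak_area)
  if (length(lloq_area) > 1) lloq_area <- mean(lloq_area)
  if (is.na(lloq_area) || lloq_area == 0) {
    abort("LLOQ peak area is zero.", class = "otval_degenerate_error")
  }
  100 * blank_area / lloq_area
}

#' Carry-over panel over all analytes
#'
#' Applies [carry_over()] to every `carryover_blank` record against the mean
#' LLOQ-level calibrant area of the same analyte and summarises mean, sd and
#' the guideline verdict per analyte.
#'
#' @param records Measurement tibble.
#' @param limits Limit-decision tibble giving the LLOQ per analyte; when an
#'   analyte (e.g. the internal standard) has no row, the lowest calibrant
#'   level present is used.
#' @param config A [study_config()].
#' @return A tibble: analyte, carry_over (mean %), sd, n, threshold, pass.
#' @export
carry_over_panel <- function(records, limits = NULL, config = study_config()) {
  records <- validate_measurements(records)
  blanks <- dplyr::filter(records, .data$role == "carryover_blank")
  purrr::map_dfr(unique(blanks$analyte), function(an) {
    b <- dplyr::filter(blanks, .data$analyte == an)
    if (is_internal_standard(an, config)) {
      # the IS sits at its single working level in every injection
      ref <- dplyr::filter(records, .data$role == "calibrant",
                           .data$analyte %in% config$analytes)
      a_ref <- mean(ref$is_area, na.rm = TRUE)
      co <- 100 * b$peak_area / a_ref
      thr <- config$carryover_max_is
    } else {
      lloq <- if (!is.null(limits) && an %in% limits$analyte) {
        limits$lloq[limits$analyte == an][1]
      } else {
        min(records$nominal_conc[records$role == "calibrant" &
                                   records$analyte == an], na.rm = TRUE)
      }
      ref <- dplyr::filter(records, .data$role == "calibrant",
                           .data$analyte == an, .data$nominal_conc == lloq)
      co <- carry_over(b$peak_area, ref$peak_area)
      thr <- config$carryover_max_analyte
    }
    tibble::tibble(analyte = an, carry_over = mean(co), sd = sd(co),
                   n = length(co), threshold = thr, pass = mean(co) < thr)
  })
}

#' Stability under a storage or handling condition
#'
#' Stability (%) = 100 x mean(test concentration) / mean(reference
#' concentration), comparing fortified samples stored under the condition
#' (freeze/thaw cycles, bench-top, long-term frozen, autosampler) against
#' freshly prepared reference samples at the same level. Accepted within
#' 85-115 %.
#'
#' @param test_records Stability measurements under the condition.
#' @param reference_records Fresh reference measurements, same analyte/level.
#' @param condition Condition label for the output cell.
#' @param fit Optional `calibration_fit`; when supplied, concentrations are
#'   back-calculated from the fit's response, otherwise the raw responses are
#'   compared directly.
#' @param config A [study_config()].
#' @return A one-row tibble: analyte, level, condition, stability, pass.
#' @export
stability <- function(test_records, reference_records, condition,
                      fit = NULL, config = study_config()) {
  test_records <- validate_measurements(test_records)
  reference_records <- validate_measurements(reference_records)
  if (nrow(test_records) == 0 || nrow(reference_records) == 0) {
    abort("Both test and reference records are required.",
          class = "otval_insufficient_data_error")
  }
  an <- unique(c(test_records$analyte, reference_records$analyte))
  lev <- unique(c(test_records$nominal_conc, reference_records$nominal_conc))
  if (length(an) != 1 || length(lev) != 1) {
    abort("stability expects one analyte at one level in both sets.",
          class = "otval_contract_error")
  }
  value <- function(d) {
    if (is.null(fit)) measurement_response(d, "raw_area")
    else back_calculate(fit, measurement_response(d, fit$response_kind))
  }
  ref_mean <- mean(value(reference_records))
  if (ref_mean == 0) {
    abort("Reference mean is zero.", class = "otval_degenerate_error")
  }
  st <- 100 * mean(value(test_records)) / ref_mean
  win <- config$stability_window
  tibble::tibble(analyte = an, level = lev, condition = condition,
                 stability = st, pass = st >= win[1] & st <= win[2])
}

#' Stability panel over every condition and level present
#'
#' Pairs each (`analyte`, `level`, `condition`) stability block with the
#' reference records (`condition == "reference"` or `role == "reference"` at
#' the same level in matrix medium) and applies [stability()].
#'
#' @inheritParams stability
#' @param records Measurement tibble with `role == "stability"` rows whose
#'   `condition` tags the storage condition, plus reference rows tagged
#'   `condition == "reference"`.
#' @param fits Named list of calibration fits (optional, see [stability()]).
#' @return A tibble of stability cells.
#' @export
stability_panel <- function(records, fits = NULL, config = study_config()) {
  records <- validate_measurements(records)
  stab <- dplyr::filter(records, .data$role == "stability",
                        .data$condition != "reference")
  refs <- dplyr::filter(records, .data$role == "stability",
                        .data$condition == "reference")
  cells <- dplyr::distinct(stab, .data$analyte, .data$nominal_conc, .data$condition)
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    an <- cells$analyte[i]; lev <- cells$nominal_conc[i]; cond <- cells$condition[i]
    test <- dplyr::filter(stab, .data$analyte == an,
                          .data$nominal_conc == lev, .data$condition == cond)
    ref <- dplyr::filter(refs, .data$analyte == an, .data$nominal_conc == lev)
    if (nrow(ref) == 0) return(tibble::tibble())
    stability(test, ref, cond, fit = fits[[an]], config = config)
  })
}

#' Apply the guideline acceptance logic across all validation blocks
#'
#' Pure function of the computed cells: each block passes iff all its cells
#' pass (calibration requires significant regression parameters, p < 0.05);
#' the overall verdict is the conjunction of block verdicts. Blocks absent
#' from `cells` are reported as not run and excluded from the conjunction.
#'
#' @param cells Named list with any of: `calibration` (a [glance()]/[tidy()]
#'   style tibble with `p.value` or a list of `calibration_fit`),
#'   `accuracy_precision`, `selectivity`, `carry_over`, `stability`
#'   (tibbles with a `pass` column), `me_r` (from
#'   [relative_matrix_effect()]), `trueness` (from [trueness_vs_crm()],
#'   `compatible` column).
#' @param config A [study_config()].
#' @return A tibble: block, n_cells, pass (NA = not run), with an `overall`
#'   row last.
#' @export
evaluate_acceptance <- function(cells, config = study_config()) {
  block_pass <- function(name) {
    x <- cells[[name]]
    if (is.null(x)) return(c(n = 0L, pass = NA))
    if (name == "calibration") {
      if (is.list(x) && !is.data.frame(x)) x <- purrr::map_dfr(x, tidy)
      # the response must depend on concentration; an intercept compatible
      # with zero is desirable, so only slope significance gates the block
      if ("term" %in% names(x)) x <- x[x$term == "slope", ]
      ok <- all(x$p.value < 0.05)
      return(c(n = nrow(x), pass = ok))
    }
    col <- if (name == "trueness") "compatible" else "pass"
    c(n = nrow(x), pass = all(x[[col]]))
  }
  blocks <- c("calibration", "accuracy_precision", "selectivity",
              "carry_over", "stability", "me_r", "trueness")
  out <- purrr::map_dfr(blocks, function(b) {
    r <- block_pass(b)
    tibble::tibble(block = b, n_cells = as.integer(r[["n"]]),
                   pass = as.logical(r[["pass"]]))
  })
  ran <- !is.na(out$pass)
  dplyr::bind_rows(out, tibble::tibble(
    block = "overall", n_cells = sum(out$n_cells),
    pass = if (any(ran)) all(out$pass[ran]) else NA
  ))
}
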