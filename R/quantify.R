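#' Quantify real samples with LOD/LLOQ censoring
#'
#' Back-calculates each replicate of each real sample through the analyte's
#' calibration fit (IS-ratio response in the validated method), averages the
#' replicates, then censors: mean below the LOD reports `below_lod`; at or
#' above the LOD but below the LLOQ reports `below_lloq`; otherwise the
#' numeric concentration is reported.
#'
#' @param records Measurement tibble with `role == "real"` rows.
#' @param fits Named list of `calibration_fit` objects (or a single fit).
#' @param limits Limit-decision tibble ([decide_limits()] rows per analyte).
#' @param localizations Optional tibble (`sample_id`, `localization`) to
#'   carry through.
#' @return A tibble: sample_id, analyte, concentration (NA when censored),
#'   censor (`NA`, `"below_lod"` or `"below_lloq"`), n, localization.
#' @export
quantify <- function(records, fits, limits, localizations = NULL) {
  records <- dplyr::filter(validate_measurements(records), .data$role == "real")
  if (inherits(fits, "calibration_fit")) fits <- setNames(list(fits), fits$analyte)
  if (nrow(records) == 0) {
    abort("No real-sample records.", class = "otval_insufficient_data_error")
  }
  records <- dplyr::filter(records, .data$analyte %in% names(fits))
  if (nrow(records) == 0) {
    abort("No calibration fit matches the real-sample analytes.",
          class = "otval_contract_error")
  }
  out <- records |>
    dplyr::group_by(.data$sample_id, .data$analyte) |>
    dplyr::group_modify(function(d, key) {
      fit <- fits[[key$analyte]]
      conc <- mean(back_calculate(fit, measurement_response(d, fit$response_kind)))
      lim <- limits[limits$analyte == key$analyte, ]
      if (nrow(lim) == 0) {
        abort(paste0("No limits for analyte ", key$analyte),
              class = "otval_contract_error")
      }
      censor <- if (conc < lim$lod) "below_lod"
                else if (conc < lim$lloq) "below_lloq"
                else NA_character_
      tibble::tibble(
        concentration = if (is.na(censor)) conc else NA_real_,
        censor = censor, n = nrow(d)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$analyte, .data$sample_id)
  if (!is.null(localizations)) {
    out <- dplyr::left_join(out, localizations, by = "sample_id")
  }
  out
}

#' Summarise a censored quantification table
#'
#' Per analyte: maximum and minimum of the uncensored (quantified)
#' concentrations, the number of uncensored samples, the censored counts by
#' flag, and counts above any user-supplied concentration thresholds.
#' Censored entries never enter max/min.
#'
#' @param results Quantification tibble ([quantify()] or
#'   [odra_organotin_results()] layout: `sample_id`, `analyte`,
#'   `concentration`, `censor`).
#' @param thresholds Optional numeric vector of concentration cutoffs (ng/g);
#'   for each, the count of samples at or above it is reported.
#' @return A tibble, one row per analyte (plus `n_above_<t>` columns).
#' @export
summarize_quant <- function(results, thresholds = NULL) {
  if (nrow(results) == 0) {
    abort("Empty results table.", class = "otval_insufficient_data_error")
  }
  out <- results |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_quantified = sum(is.na(.data$censor)),
      n_below_lloq = sum(.data$censor == "below_lloq", na.rm = TRUE),
      n_below_lod = sum(.data$censor == "below_lod", na.rm = TRUE),
      max_conc = if (any(is.na(.data$censor)))
        max(.data$concentration[is.na(.data$censor)]) else NA_real_,
      min_conc = if (any(is.na(.data$censor)))
        min(.data$concentration[is.na(.data$censor)]) else NA_real_,
      .groups = "drop"
    )
  for (t in thresholds) {
    col <- paste0("n_above_", t)
    counts <- results |>
      dplyr::group_by(.data$analyte) |>
      dplyr::summarise(v = sum(!is.na(.data$concentration) &
                                 .data$concentration >= t), .groups = "drop")
    out[[col]] <- counts$v[match(out$analyte, counts$analyte)]
  }
  out
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "-", formatC(signif(x, digits), format = "fg", big.mark = ""))
}

#' Render a deterministic study report
#'
#' Combines the validation verdict, quantification limits, matrix-effect
#' results and the censored sample table into a markdown document with
#' stable ordering — the same inputs always produce byte-identical output.
#' Sections whose inputs are absent are marked "not run".
#'
#' @param summary Summary tibble from [summarize_quant()], or `NULL`.
#' @param results Quantification tibble from [quantify()], or `NULL`.
#' @param verdict Acceptance tibble from [evaluate_acceptance()], or `NULL`.
#' @param limits Limit-decision tibble, or `NULL`.
#' @param matrix_results `per_matrix` tibble from [matrix_effect_table()],
#'   or `NULL`.
#' @param path Optional file path; when given the report is written there.
#' @return The report as a character vector of lines (invisibly when `path`
#'   is given).
#' @export
render_report <- function(summary = NULL, results = NULL, verdict = NULL,
                          limits = NULL, matrix_results = NULL, path = NULL) {
  lines <- c("# Organotin quantification study report", "")

  lines <- c(lines, "## Method validation", "")
  if (is.null(verdict)) {
    lines <- c(lines, "not run", "")
  } else {
    lines <- c(lines, "| block | cells | pass |", "|---|---|---|",
               sprintf("| %s | %d | %s |", verdict$block, verdict$n_cells,
                       ifelse(is.na(verdict$pass), "not run",
                              ifelse(verdict$pass, "pass", "FAIL"))), "")
  }

  lines <- c(lines, "## Quantification limits", "")
  if (is.null(limits)) {
    lines <- c(lines, "not run", "")
  } else {
    lim <- dplyr::arrange(limits, .data$analyte)
    lines <- c(lines, "| analyte | LLOQ (ng/g) | LOD (ng/g) | S/N at LLOQ |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %s | %s |", lim$analyte, fmt_num(lim$lloq),
                       fmt_num(lim$lod), fmt_num(lim$sn_at_lloq)), "")
  }

  lines <- c(lines, "## Matrix effects", "")
  if (is.null(matrix_results)) {
    lines <- c(lines, "not run", "")
  } else {
    mr <- dplyr::arrange(matrix_results, .data$analyte, .data$matrix_id)
    lines <- c(lines, "| matrix | analyte | ME_A (%) | RE (%) |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %s | %s |", mr$matrix_id, mr$analyte,
                       fmt_num(mr$me_a), fmt_num(mr$re)), "")
  }

  lines <- c(lines, "## Real samples", "")
  if (is.null(results)) {
    lines <- c(lines, "not run", "")
  } else {
    res <- dplyr::arrange(results, .data$analyte, .data$sample_id)
    shown <- ifelse(is.na(res$censor), fmt_num(res$concentration),
                    ifelse(res$censor == "below_lod", "< LOD", "< LLOQ"))
    lines <- c(lines, "| sample | analyte | concentration (ng/g) |",
               "|---|---|---|",
               sprintf("| %s | %s | %s |", res$sample_id, res$analyte, shown), "")
  }

  lines <- c(lines, "## Summary", "")
  if (is.null(summary)) {
    lines <- c(lines, "not run", "")
  } else {
    sm <- dplyr::arrange(summary, .data$analyte)
    lines <- c(lines,
               "| analyte | quantified | max (ng/g) | min (ng/g) | censored |",
               "|---|---|---|---|---|",
               sprintf("| %s | %d | %s | %s | %d |", sm$analyte,
                       sm$n_quantified, fmt_num(sm$max_conc),
                       fmt_num(sm$min_conc),
                       sm$n_below_lloq + sm$n_below_lod), "")
  }

  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
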