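#' Selectivity panel over analytes and the internal standard
#'
#' For each quantified analyte, compares blank-sediment interference against
#' the LLOQ-level calibrant signal; for the internal standard, compares the
#' IS-channel blank signal against the IS working-level area observed across
#' calibrant injections.
#'
#' @param records Measurement tibble with `blank` rows.
#' @param limits Limit-decision tibble (LLOQ per analyte); when absent the
#'   lowest calibrant level is used.
#' @param config A [study_config()].
#' @return A tibble of selectivity cells (see [selectivity()]).
#' @export
selectivity_panel <- function(records, limits = NULL, config = study_config()) {
  records <- validate_measurements(records)
  blanks <- dplyr::filter(records, .data$role == "blank")
  purrr::map_dfr(unique(blanks$analyte), function(an) {
    b <- dplyr::filter(blanks, .data$analyte == an)
    if (is_internal_standard(an, config)) {
      ref <- dplyr::filter(records, .data$role == "calibrant",
                           .data$analyte %in% config$analytes)
      a_ref <- mean(ref$is_area, na.rm = TRUE)
      ratio <- 100 * mean(b$peak_area) / a_ref
      ratio_sd <- 100 * sd(b$peak_area) / a_ref
      thr <- config$selectivity_max_is
      return(tibble::tibble(analyte = an, selectivity = ratio, sd = ratio_sd,
                            n = nrow(b), threshold = thr, pass = ratio < thr))
    }
    lloq <- if (!is.null(limits) && an %in% limits$analyte) {
      limits$lloq[limits$analyte == an][1]
    } else {
      min(records$nominal_conc[records$role == "calibrant" &
                                 records$analyte == an], na.rm = TRUE)
    }
    ref <- dplyr::filter(records, .data$role == "calibrant",
                         .data$analyte == an, .data$nominal_conc == lloq)
    selectivity(b, ref, config = config)
  })
}

#' Trueness panel against the CRM block
#'
#' Back-calculates the CRM replicate concentrations through each analyte's
#' calibration fit and applies [trueness_vs_crm()] with the certified values
#' and reference uncertainties.
#'
#' @param records Measurement tibble with `crm` rows.
#' @param fits Named list of `calibration_fit` objects.
#' @param certified,u_ref Named numeric vectors per analyte (ng/g).
#' @param config A [study_config()] (supplies the coverage factor).
#' @return A tibble of trueness results, one row per analyte.
#' @export
trueness_panel <- function(records, fits, certified, u_ref,
                           config = study_config()) {
  records <- dplyr::filter(validate_measurements(records), .data$role == "crm")
  purrr::map_dfr(intersect(names(fits), names(certified)), function(an) {
    d <- dplyr::filter(records, .data$analyte == an)
    if (nrow(d) < 2) return(tibble::tibble())
    fit <- fits[[an]]
    conc <- back_calculate(fit, measurement_response(d, fit$response_kind))
    trueness_vs_crm(conc, certified[[an]], u_ref[[an]], k = config$coverage_k,
                    analyte = an)
  })
}

#' Run the full validation and application pipeline
#'
#' Convenience driver chaining every stage on a complete measurement set
#' (e.g. one produced by [simulate_study()]): calibration, limit decisions,
#' accuracy/precision panel, selectivity, carry-over, stability, matrix
#' effects and relative matrix effect, CRM trueness, guideline acceptance,
#' and censored quantification of the real samples.
#'
#' @param measurements Measurement tibble covering the full study design.
#' @param config A [study_config()].
#' @param crm Optional list with named `certified` and `u_ref` vectors; when
#'   absent the trueness block is skipped.
#' @param recovery_level Level (ng/g) of the pre/post-extraction spike pairs.
#' @return A list: `fits`, `limits`, `accuracy_precision`, `selectivity`,
#'   `carry_over`, `stability`, `matrix_effects` (list from
#'   [matrix_effect_table()]), `trueness`, `verdict`, `quantified`,
#'   `summary`.
#' @export
run_study <- function(measurements, config = study_config(), crm = NULL,
                      recovery_level = 1000) {
  measurements <- validate_measurements(measurements)
  fits <- calibrate_study(measurements, config)
  limits <- purrr::map_dfr(fits, function(f) {
    decide_limits(measurements, f, config)
  })
  ap <- accuracy_precision_panel(measurements, fits, limits, config)
  sel <- selectivity_panel(measurements, limits, config)
  co <- carry_over_panel(measurements, limits, config)
  st <- stability_panel(measurements, fits, config)
  me <- matrix_effect_table(measurements, config, recovery_level)
  tr <- if (!is.null(crm)) {
    trueness_panel(measurements, fits, crm$certified, crm$u_ref, config)
  } else NULL
  verdict <- evaluate_acceptance(
    list(calibration = fits, accuracy_precision = ap, selectivity = sel,
         carry_over = co, stability = st, me_r = me$me_r, trueness = tr),
    config
  )
  quantified <- if (any(measurements$role == "real")) {
    quantify(measurements, fits, limits)
  } else NULL
  summary <- if (!is.null(quantified)) summarize_quant(quantified) else NULL
  list(fits = fits, limits = limits, accuracy_precision = ap,
       selectivity = sel, carry_over = co, stability = st,
       matrix_effects = me, trueness = tr, verdict = verdict,
       quantified = quantified, summary = summary)
}
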