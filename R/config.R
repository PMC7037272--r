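#' Study configuration
#'
#' Holds the design constants and guideline acceptance thresholds that drive
#' every pipeline stage: which analytes are quantified and which compound is
#' the isotope-labelled internal standard, the QC concentration levels, the
#' EMA-style acceptance windows, the signal-to-noise thresholds that define
#' the quantification and detection limits, the calibration weighting scheme,
#' and the coverage factor used in the trueness test.
#'
#' Defaults reproduce the organotin sediment study design: TBT and TPhT
#' quantified against deuterated TBT (TBT-d27); QC levels 3/2500/4000 ng/g
#' for TBT and 15/2500/4000 ng/g for TPhT; precision accepted at <= 15 % CV
#' (20 % at the LLOQ); accuracy within 85-115 % of nominal (80-120 % at the
#' LLOQ); carry-over and blank interference below 20 % of the LLOQ signal for
#' analytes and 5 % for the internal standard; stability within 85-115 % of
#' the reference; relative matrix effect below 15 % CV; S/N >= 5 at the LLOQ
#' and S/N = 3 defining the LOD; weighted 1/x calibration; coverage factor
#' k = 2 (~95 % confidence).
#'
#' @param analytes Character vector of quantified analytes.
#' @param internal_standard Name of the internal-standard compound.
#' @param qc_levels Named list of QC nominal concentrations (ng/g) per analyte.
#' @param precision_max,precision_max_lloq Maximum accepted CV (%) at QC
#'   levels and at the LLOQ.
#' @param accuracy_window,accuracy_window_lloq Half-width (%) of the accepted
#'   accuracy window about 100 %.
#' @param carryover_max_analyte,carryover_max_is Maximum accepted carry-over
#'   (% of the LLOQ signal).
#' @param selectivity_max_analyte,selectivity_max_is Maximum accepted blank
#'   interference (% of the LLOQ signal).
#' @param stability_window Length-2 numeric, accepted stability range
#'   (% of reference).
#' @param me_r_max Maximum accepted relative matrix effect (CV %).
#' @param sn_lloq,sn_lod Signal-to-noise thresholds defining LLOQ and LOD.
#' @param weighting Calibration weighting scheme: `"one_over_x"`, `"none"`,
#'   or `"one_over_x2"`.
#' @param coverage_k Coverage factor for expanded uncertainty.
#' @param seed Optional integer seed recorded with the study.
#'
#' @return An object of class `study_config` (a named list).
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$qc_levels$TBT
study_config <- function(analytes = c("TBT", "TPhT"),
                         internal_standard = "TBT_d27",
                         qc_levels = list(TBT = c(3, 2500, 4000),
                                          TPhT = c(15, 2500, 4000)),
                         precision_max = 15,
                         precision_max_lloq = 20,
                         accuracy_window = 15,
                         accuracy_window_lloq = 20,
                         carryover_max_analyte = 20,
                         carryover_max_is = 5,
                         selectivity_max_analyte = 20,
                         selectivity_max_is = 5,
                         stability_window = c(85, 115),
                         me_r_max = 15,
                         sn_lloq = 5,
                         sn_lod = 3,
                         weighting = c("one_over_x", "none", "one_over_x2"),
                         coverage_k = 2,
                         seed = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(length(stability_window) == 2L, stability_window[1] < stability_window[2])
  if (coverage_k <= 0) abort("`coverage_k` must be > 0.", class = "otval_config_error")
  if (sn_lod > sn_lloq) abort("`sn_lod` must not exceed `sn_lloq`.", class = "otval_config_error")
  missing_qc <- setdiff(analytes, names(qc_levels))
  if (length(missing_qc) > 0) {
    abort(paste0("No QC levels configured for: ", paste(missing_qc, collapse = ", ")),
          class = "otval_config_error")
  }
  structure(
    list(
      analytes = analytes,
      internal_standard = internal_standard,
      qc_levels = qc_levels,
      precision_max = precision_max,
      precision_max_lloq = precision_max_lloq,
      accuracy_window = accuracy_window,
      accuracy_window_lloq = accuracy_window_lloq,
      carryover_max_analyte = carryover_max_analyte,
      carryover_max_is = carryover_max_is,
      selectivity_max_analyte = selectivity_max_analyte,
      selectivity_max_is = selectivity_max_is,
      stability_window = stability_window,
      me_r_max = me_r_max,
      sn_lloq = sn_lloq,
      sn_lod = sn_lod,
      weighting = weighting,
      coverage_k = coverage_k,
      seed = seed
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  analytes:          ", paste(x$analytes, collapse = ", "), "\n")
  cat("  internal standard: ", x$internal_standard, "\n")
  cat("  weighting:         ", x$weighting, "\n")
  cat("  precision <=", x$precision_max, "% (LLOQ", x$precision_max_lloq, "%)\n")
  cat("  accuracy 100 +/-", x$accuracy_window, "% (LLOQ +/-", x$accuracy_window_lloq, "%)\n")
  cat("  S/N thresholds: LLOQ >=", x$sn_lloq, ", LOD =", x$sn_lod, "\n")
  cat("  coverage factor k =", x$coverage_k, "\n")
  invisible(x)
}

#' Read or write a study configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return `read_study_config()` returns a [study_config()] object;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path), class = "otval_io_error")
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config fields: ", paste(unknown, collapse = ", ")),
          class = "otval_config_error")
  }
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @param config A [study_config()] object.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

is_internal_standard <- function(analyte, config) {
  analyte == config$internal_standard
}
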