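#' @keywords internal
measurement_roles <- c("blank", "calibrant", "qc", "crm", "real", "spike_pre",
                       "spike_post", "stability", "carryover_blank", "reference")

measurement_cols <- c(
  sample_id = "character", analyte = "character", role = "character",
  run_id = "character", replicate = "integer", nominal_conc = "numeric",
  peak_area = "numeric", is_area = "numeric", noise_sd = "numeric",
  matrix_id = "character", condition = "character", medium = "character"
)

#' Construct a measurement table
#'
#' The pipeline's single long-format container: one row per MRM peak-area
#' observation, with its role in the study design carried in the `role`
#' column (calibrant, QC, blank, CRM, pre/post-extraction spike, stability,
#' carry-over blank, aqueous reference, or real sample). Concentrations are
#' ng analyte per g dry sediment throughout; peak areas are arbitrary
#' detector units.
#'
#' @param sample_id,analyte,role,run_id Character vectors.
#' @param replicate Positive integer replicate index.
#' @param nominal_conc Nominal (spiked) concentration, ng/g; `NA` for blanks
#'   and real samples.
#' @param peak_area Analyte peak area, detector units, >= 0.
#' @param is_area Internal-standard peak area (optional, `NA` allowed).
#' @param noise_sd Baseline noise estimate in detector units, used for S/N.
#' @param matrix_id Sediment matrix identifier (optional).
#' @param condition Free-text condition tag, e.g. `"freeze_thaw"`.
#' @param medium `"water"` or `"matrix"`.
#' @return A tibble with the measurement columns, validated.
#' @export
measurement_table <- function(sample_id, analyte, role, run_id = "run1",
                              replicate = 1L, nominal_conc = NA_real_,
                              peak_area, is_area = NA_real_,
                              noise_sd = NA_real_, matrix_id = NA_character_,
                              condition = NA_character_, medium = "water") {
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    analyte = as.character(analyte),
    role = as.character(role),
    run_id = as.character(run_id),
    replicate = as.integer(replicate),
    nominal_conc = as.numeric(nominal_conc),
    peak_area = as.numeric(peak_area),
    is_area = as.numeric(is_area),
    noise_sd = as.numeric(noise_sd),
    matrix_id = as.character(matrix_id),
    condition = as.character(condition),
    medium = as.character(medium)
  )
  validate_measurements(out)
}

#' Validate a measurement table against the data-model invariants
#'
#' Checks column presence and types, non-negative peak areas, known roles,
#' and the structural requirements (calibrants carry a nominal concentration;
#' pre/post-extraction spikes carry a matrix id). Violations are reported
#' with the offending row numbers.
#'
#' @param data A data frame of measurements.
#' @return The data as a validated tibble (invisibly the same content).
#' @export
validate_measurements <- function(data) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(names(measurement_cols), names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
          class = "otval_schema_error")
  }
  if (nrow(data) == 0) return(data[names(measurement_cols)])

  fail <- function(rows, what) {
    abort(paste0("Invalid measurement rows (", what, "): row ",
                 paste(head(rows, 10), collapse = ", "),
                 if (length(rows) > 10) " ..."),
          class = "otval_validation_error")
  }
  bad <- which(!is.na(data$peak_area) & data$peak_area < 0)
  if (length(bad)) fail(bad, "peak_area < 0")
  bad <- which(is.na(data$peak_area))
  if (length(bad)) fail(bad, "peak_area missing")
  bad <- which(!is.na(data$is_area) & data$is_area < 0)
  if (length(bad)) fail(bad, "is_area < 0")
  bad <- which(!is.na(data$nominal_conc) & data$nominal_conc < 0)
  if (length(bad)) fail(bad, "nominal_conc < 0")
  bad <- which(!data$role %in% measurement_roles)
  if (length(bad)) fail(bad, "unknown role")
  bad <- which(data$role == "calibrant" & is.na(data$nominal_conc))
  if (length(bad)) fail(bad, "calibrant without nominal_conc")
  bad <- which(data$role %in% c("spike_pre", "spike_post") & is.na(data$matrix_id))
  if (length(bad)) fail(bad, "spike without matrix_id")
  bad <- which(!is.na(data$replicate) & data$replicate < 1)
  if (length(bad)) fail(bad, "replicate < 1")
  data[names(measurement_cols)]
}

#' Read and write measurement tables
#'
#' CSV dialect: comma separator, decimal point, UTF-8, header row. Empty
#' cells and the literal `"no data"` become missing values; no other sentinel
#' is accepted. Every row is parsed into the measurement data model and
#' validated; rows violating an invariant abort the read with their row
#' numbers.
#'
#' @param path Path to a CSV file.
#' @param config Optional [study_config()]; when given, analyte names are
#'   checked against the configured analytes and internal standard.
#' @return A validated measurement tibble.
#' @export
read_measurements <- function(path, config = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path), class = "otval_io_error")
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(), analyte = readr::col_character(),
      role = readr::col_character(), run_id = readr::col_character(),
      replicate = readr::col_integer(), nominal_conc = readr::col_double(),
      peak_area = readr::col_double(), is_area = readr::col_double(),
      noise_sd = readr::col_double(), matrix_id = readr::col_character(),
      condition = readr::col_character(), medium = readr::col_character()
    ),
    na = c("", "NA", "no data"),
    progress = FALSE
  )
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed cells at row(s): ",
                 paste(unique(head(probs$row, 10)), collapse = ", ")),
          class = "otval_validation_error")
  }
  data <- validate_measurements(data)
  if (!is.null(config)) {
    known <- c(config$analytes, config$internal_standard)
    bad <- setdiff(unique(data$analyte), known)
    if (length(bad) > 0) {
      abort(paste0("Unconfigured analyte(s): ", paste(bad, collapse = ", ")),
            class = "otval_validation_error")
    }
  }
  data
}

#' @rdname read_measurements
#' @param data A validated measurement tibble.
#' @export
write_measurements <- function(data, path) {
  data <- validate_measurements(data)
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Report whether each pipeline stage can run on a measurement set
#'
#' Inspects the study structure per analyte — calibration levels and
#' replicates, QC levels present, blanks, carry-over blanks, stability
#' conditions, pre/post-extraction spike pairs, aqueous reference curves,
#' CRM replicates, real samples — and flags any downstream block that could
#' not run on this design. Report-only: never throws on an incomplete study.
#'
#' @param records A measurement tibble.
#' @param config A [study_config()].
#' @return A tibble with columns `analyte`, `block`, `runnable`, `detail`.
#' @export
validate_study_design <- function(records, config = study_config()) {
  records <- validate_measurements(records)
  if (nrow(records) == 0) abort("No measurement records.", class = "otval_validation_error")

  purrr::map_dfr(config$analytes, function(an) {
    rec <- dplyr::filter(records, .data$analyte == an)
    cal <- dplyr::filter(rec, .data$role == "calibrant")
    cal_levels <- sort(unique(cal$nominal_conc))
    reps_per_level <- if (nrow(cal)) min(table(cal$nominal_conc)) else 0L
    qc <- dplyr::filter(rec, .data$role == "qc")
    qc_levels <- sort(unique(qc$nominal_conc))
    n_blank <- sum(rec$role == "blank")
    n_co <- sum(rec$role == "carryover_blank")
    n_crm <- sum(rec$role == "crm")
    n_real <- length(unique(rec$sample_id[rec$role == "real"]))
    pre_m <- unique(rec$matrix_id[rec$role == "spike_pre"])
    post_m <- unique(rec$matrix_id[rec$role == "spike_post"])
    n_ref <- sum(rec$role == "reference")
    stab_cond <- unique(rec$condition[rec$role == "stability"])
    stab_cond <- stab_cond[!is.na(stab_cond)]

    block <- function(name, runnable, detail) {
      tibble::tibble(analyte = an, block = name, runnable = runnable, detail = detail)
    }
    dplyr::bind_rows(
      block("calibration", length(cal_levels) >= 3,
            sprintf("%d levels x %d replicates", length(cal_levels), reps_per_level)),
      block("accuracy_precision", nrow(qc) >= 2 && length(qc_levels) >= 1,
            sprintf("QC levels: %s", paste(qc_levels, collapse = ", "))),
      block("selectivity", n_blank >= 1 && length(cal_levels) >= 1,
            sprintf("%d blanks", n_blank)),
      block("carry_over", n_co >= 1 && length(cal_levels) >= 1,
            sprintf("%d carry-over blanks", n_co)),
      block("stability", length(stab_cond) >= 1,
            sprintf("conditions: %s", paste(stab_cond, collapse = ", "))),
      block("matrix_effect", length(post_m) >= 1 && n_ref >= 3,
            sprintf("%d matrices, %d aqueous reference points", length(post_m), n_ref)),
      block("recovery", length(intersect(pre_m, post_m)) >= 1,
            sprintf("%d pre/post spike matrix pairs", length(intersect(pre_m, post_m)))),
      block("trueness", n_crm >= 2, sprintf("%d CRM replicates", n_crm)),
      block("quantification", n_real >= 1 && length(cal_levels) >= 3,
            sprintf("%d real samples", n_real))
    )
  })
}
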