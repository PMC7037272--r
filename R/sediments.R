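sediment_numeric_cols <- c("pH", "conductivity", "toc", "n", "h", "avs", "p",
                           "heavy_metals", "pah", "sand", "silt", "clay")

#' Read sediment physicochemical profiles
#'
#' One row per sediment matrix: pH and conductivity of the water extract,
#' total organic carbon, nitrogen, hydrogen, acid volatile sulfur and
#' phosphorus contents (%), summed heavy metals (mg/kg), summed priority
#' PAHs (ug/kg), and the sand/silt/clay granulometric fractions (%).
#'
#' Empty cells and the literal `"no data"` are read as missing values —
#' never as zeros, so that downstream correlations drop the pair rather than
#' silently imputing. Percentage fields must lie in [0, 100] and the three
#' grain-size fractions must sum to roughly 100 when all are present.
#'
#' @param path Path to a CSV file with a `matrix_id` column plus the numeric
#'   profile columns.
#' @return A tibble of sediment profiles.
#' @export
read_sediment_profiles <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path), class = "otval_io_error")
  data <- readr::read_csv(path, na = c("", "NA", "no data"), progress = FALSE,
                          col_types = readr::cols(matrix_id = readr::col_character(),
                                                  .default = readr::col_double()))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed cells at row(s): ",
                 paste(unique(head(probs$row, 10)), collapse = ", ")),
          class = "otval_validation_error")
  }
  validate_sediment_profiles(data)
}

#' @rdname read_sediment_profiles
#' @param profiles A sediment-profile tibble.
#' @export
validate_sediment_profiles <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  if (!"matrix_id" %in% names(profiles)) {
    abort("Missing required column: matrix_id", class = "otval_schema_error")
  }
  dup <- unique(profiles$matrix_id[duplicated(profiles$matrix_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated matrix_id: ", paste(dup, collapse = ", ")),
          class = "otval_validation_error")
  }
  pct_cols <- intersect(c("toc", "n", "h", "avs", "p", "sand", "silt", "clay"),
                        names(profiles))
  for (col in pct_cols) {
    v <- profiles[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      abort(paste0("Column ", col, " outside [0, 100]."), class = "otval_validation_error")
    }
  }
  if (all(c("sand", "silt", "clay") %in% names(profiles))) {
    tot <- profiles$sand + profiles$silt + profiles$clay
    bad <- which(!is.na(tot) & (tot < 95 | tot > 105))
    if (length(bad) > 0) {
      abort(paste0("Grain-size fractions do not sum to ~100 for matrix: ",
                   paste(profiles$matrix_id[bad], collapse = ", ")),
            class = "otval_validation_error")
    }
  }
  profiles
}

#' Bundled study tables
#'
#' `odra_sediment_profiles()` returns the physicochemical characterisation of
#' the ten Odra River Estuary sediments used for matrix-effect and recovery
#' work (the `"no data"` PAH entries are missing values).
#' `odra_organotin_results()` returns the published TBT/TPhT concentrations
#' in the same ten sediments as a censored result table: entries printed as
#' "<5" become `below_lloq` censor flags at the 5 ng/g TPhT quantification
#' limit.
#'
#' @return A tibble; see Details.
#' @export
odra_sediment_profiles <- function() {
  read_sediment_profiles(system.file("extdata", "odra_sediments.csv",
                                     package = "otval", mustWork = TRUE))
}

#' @rdname odra_sediment_profiles
#' @export
odra_organotin_results <- function() {
  path <- system.file("extdata", "odra_organotin_results.csv",
                      package = "otval", mustWork = TRUE)
  raw <- readr::read_csv(path, col_types = "cccc", progress = FALSE)
  censored <- grepl("^<", raw$reported)
  tibble::tibble(
    sample_id = raw$sample_id,
    analyte = raw$analyte,
    concentration = ifelse(censored, NA_real_, suppressWarnings(as.numeric(raw$reported))),
    censor = ifelse(censored, "below_lloq", NA_character_),
    censor_limit = ifelse(censored, as.numeric(sub("^<", "", raw$reported)), NA_real_),
    localization = raw$localization
  )
}
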