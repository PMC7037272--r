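#' Extraction recovery from pre- vs post-extraction spikes
#'
#' Recovery (%) = 100 x mean(A_pre) / mean(A_ref): the peak area of samples
#' spiked before extraction relative to a reference spiked after extraction
#' (isolating extraction losses from ionization effects) or to an aqueous
#' solution (the optimisation-style recovery, where complete transfer from
#' water is assumed). The caller selects the reference by which records it
#' passes.
#'
#' @param pre_spike Records (or numeric areas) of samples spiked before
#'   extraction.
#' @param reference Records (or numeric areas) of the reference:
#'   post-extraction spikes or aqueous solutions at the same nominal level.
#' @return Recovery percentage (scalar).
#' @export
#' @examples
#' extraction_recovery(c(50, 60), c(100, 100))  # 55
extraction_recovery <- function(pre_spike, reference) {
  area <- function(x) if (is.data.frame(x)) validate_measurements(x)$peak_area else x
  pre <- area(pre_spike); ref <- area(reference)
  if (length(pre) == 0 || length(ref) == 0) {
    abort("Both spike sets must be non-empty.", class = "otval_insufficient_data_error")
  }
  if (mean(ref) == 0) {
    abort("Reference mean area is zero.", class = "otval_degenerate_error")
  }
  100 * mean(pre) / mean(ref)
}

#' Absolute matrix effect from the slope ratio
#'
#' ME_A (%) = 100 x a_matrix / a_water: the slope of a calibration line
#' prepared in post-extraction sediment extract relative to the slope of the
#' same design prepared in pure water. Values below 100 % indicate
#' ionization suppression, above 100 % enhancement. Both fits must be on raw
#' peak areas — an IS-ratio response would already absorb the effect being
#' measured.
#'
#' @param matrix_fit,water_fit `calibration_fit` objects with
#'   `response_kind == "raw_area"`.
#' @return ME_A percentage (scalar).
#' @export
absolute_matrix_effect <- function(matrix_fit, water_fit) {
  stopifnot(inherits(matrix_fit, "calibration_fit"),
            inherits(water_fit, "calibration_fit"))
  if (matrix_fit$response_kind != "raw_area" || water_fit$response_kind != "raw_area") {
    abort("Matrix-effect slopes must be fit on raw areas, not IS ratios.",
          class = "otval_contract_error")
  }
  if (water_fit$slope == 0) {
    abort("Aqueous calibration slope is zero.", class = "otval_degenerate_error")
  }
  100 * matrix_fit$slope / water_fit$slope
}

#' Relative matrix effect across matrices
#'
#' ME_R is the coefficient of variation, over matrices, of the
#' analyte-to-internal-standard matrix-effect ratio r_i = ME_A(analyte, i) /
#' ME_A(IS, i). It is exactly zero when the IS tracks the analyte's
#' suppression in every matrix, and is accepted below 15 % CV.
#'
#' @param analyte_me Numeric vector of per-matrix analyte ME_A values.
#' @param is_me Numeric vector of per-matrix internal-standard ME_A values,
#'   same matrices in the same order.
#' @param analyte Optional label.
#' @param config A [study_config()].
#' @return A one-row tibble: analyte, me_r (CV %), n_matrices, pass.
#' @export
#' @examples
#' relative_matrix_effect(c(90, 100, 110), c(100, 100, 100))
relative_matrix_effect <- function(analyte_me, is_me, analyte = NA_character_,
                                   config = study_config()) {
  if (length(analyte_me) != length(is_me) || length(analyte_me) < 2) {
    abort("Need the same >= 2 matrices in both collections.",
          class = "otval_insufficient_data_error")
  }
  if (any(is_me == 0)) {
    abort("Internal-standard matrix effect of zero is degenerate.",
          class = "otval_degenerate_error")
  }
  r <- analyte_me / is_me
  me_r <- 100 * sd(r) / mean(r)
  tibble::tibble(analyte = analyte, me_r = me_r,
                 n_matrices = length(r), pass = me_r < config$me_r_max)
}

#' Per-matrix matrix effects and recovery for a whole study
#'
#' For each analyte and sediment matrix, fits the post-extraction spike curve
#' (raw areas, the configured weighting) and the matching aqueous reference
#' curve and forms the Eq-style slope-ratio ME_A; measures the internal
#' standard's matrix effect as the ratio of its mean peak area in
#' matrix-matched vs aqueous spikes (the IS sits at one fixed level, so no
#' slope exists for it); and computes extraction recovery from the
#' pre-extraction spikes against the post-extraction spikes at the shared
#' recovery level. Also returns the study-level ME_R.
#'
#' @param records Measurement tibble containing `spike_post`, `spike_pre` and
#'   aqueous `reference` rows.
#' @param config A [study_config()].
#' @param recovery_level Nominal level (ng/g) at which pre/post spikes are
#'   compared; default 1000.
#' @return A list with `per_matrix` (tibble: matrix_id, analyte, me_a,
#'   is_me_a, re) and `me_r` (tibble from [relative_matrix_effect()] per
#'   analyte).
#' @export
matrix_effect_table <- function(records, config = study_config(),
                                recovery_level = 1000) {
  records <- validate_measurements(records)
  post <- dplyr::filter(records, .data$role == "spike_post")
  pre <- dplyr::filter(records, .data$role == "spike_pre")
  ref <- dplyr::filter(records, .data$role == "reference")
  if (nrow(post) == 0 || nrow(ref) == 0) {
    abort("Matrix-effect estimation needs spike_post and aqueous reference rows.",
          class = "otval_insufficient_data_error")
  }
  per_matrix <- purrr::map_dfr(intersect(config$analytes, unique(post$analyte)),
                               function(an) {
    ref_a <- dplyr::filter(ref, .data$analyte == an)
    water_fit <- fit_weighted_line(ref_a$nominal_conc, ref_a$peak_area,
                                   weighting = config$weighting, analyte = an,
                                   response_kind = "raw_area")
    is_water <- mean(ref_a$is_area, na.rm = TRUE)
    purrr::map_dfr(sort(unique(post$matrix_id[post$analyte == an])), function(m) {
      d <- dplyr::filter(post, .data$analyte == an, .data$matrix_id == m)
      mfit <- fit_weighted_line(d$nominal_conc, d$peak_area,
                                weighting = config$weighting, analyte = an,
                                response_kind = "raw_area")
      is_me <- if (is.finite(is_water) && is_water > 0) {
        100 * mean(d$is_area, na.rm = TRUE) / is_water
      } else NA_real_
      p <- dplyr::filter(pre, .data$analyte == an, .data$matrix_id == m,
                         .data$nominal_conc == recovery_level)
      q <- dplyr::filter(d, .data$nominal_conc == recovery_level)
      re <- if (nrow(p) > 0 && nrow(q) > 0) extraction_recovery(p, q) else NA_real_
      tibble::tibble(matrix_id = m, analyte = an,
                     me_a = absolute_matrix_effect(mfit, water_fit),
                     is_me_a = is_me, re = re)
    })
  })
  me_r <- per_matrix |>
    dplyr::filter(!is.na(.data$is_me_a)) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(~ relative_matrix_effect(.x$me_a, .x$is_me_a,
                                                 analyte = .y$analyte,
                                                 config = config)[-1]) |>
    dplyr::ungroup()
  list(per_matrix = per_matrix, me_r = me_r)
}

#' Trueness against a certified reference material
#'
#' Tests whether the method's bias against a CRM is within the expanded
#' uncertainty of the difference: delta = |certified - mean(measured)| is
#' compared with U_delta = k * sqrt(u_ref^2 + s_m^2 / n), where u_ref is the
#' certificate's standard uncertainty, s_m the sample standard deviation of
#' the n replicate measurements, and k the coverage factor (k = 2 for ~95 %
#' confidence). The method is compatible with the certificate when
#' delta <= U_delta (boundary counts as compatible).
#'
#' @param measured Numeric vector of replicate measured concentrations (ng/g).
#' @param certified Certified concentration (ng/g).
#' @param u_ref Standard uncertainty of the certified value (ng/g), >= 0.
#' @param k Coverage factor, > 0.
#' @param analyte Optional label.
#' @return A one-row tibble of class data: analyte, certified, u_ref,
#'   measured_mean, s_m, n, k, delta, u_delta, compatible.
#' @export
#' @examples
#' trueness_vs_crm(rnorm(6, 450, 30), certified = 480, u_ref = 40, k = 2)
trueness_vs_crm <- function(measured, certified, u_ref, k = 2,
                            analyte = NA_character_) {
  measured <- measured[!is.na(measured)]
  if (length(measured) < 2) {
    abort("Trueness needs >= 2 replicate measurements.",
          class = "otval_insufficient_replicates_error")
  }
  if (u_ref < 0) abort("u_ref must be >= 0.", class = "otval_domain_error")
  if (k <= 0) abort("k must be > 0.", class = "otval_domain_error")
  n <- length(measured)
  s_m <- sd(measured)
  delta <- abs(certified - mean(measured))
  u_delta <- k * sqrt(u_ref^2 + s_m^2 / n)
  tibble::tibble(
    analyte = analyte, certified = certified, u_ref = u_ref,
    measured_mean = mean(measured), s_m = s_m, n = n, k = k,
    delta = delta, u_delta = u_delta, compatible = delta <= u_delta
  )
}

#' Compare matrix effects before and after sieving
#'
#' Paired two-sided t-test on per-matrix ME_A values measured on the same
#' sediments before and after sieving (grain-size fractionation), with group
#' means and standard deviations. When every pair is identical (t = 0) the
#' p-value is reported as 1.
#'
#' @param me_before,me_after Numeric vectors of per-matrix ME_A values.
#' @param matrix_id Optional matrix identifiers; when given for both groups
#'   the pairs are matched by id and unmatched ids are an error.
#' @return A one-row tibble: n, mean_before, sd_before, mean_after, sd_after,
#'   t, p_value.
#' @export
compare_sieving <- function(me_before, me_after, matrix_id = NULL) {
  if (!is.null(matrix_id)) {
    if (length(matrix_id) != length(me_before) ||
        length(matrix_id) != length(me_after)) {
      abort("matrix_id must match both ME vectors.", class = "otval_pairing_error")
    }
  }
  if (length(me_before) != length(me_after) || length(me_before) < 2) {
    abort("Paired comparison needs >= 2 matched pairs.",
          class = "otval_pairing_error")
  }
  d <- me_before - me_after
  n <- length(d)
  sd_d <- sd(d)
  if (sd_d == 0) {
    t_stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p <- if (mean(d) == 0) 1 else 0
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  tibble::tibble(
    n = n, mean_before = mean(me_before), sd_before = sd(me_before),
    mean_after = mean(me_after), sd_after = sd(me_after),
    t = t_stat, p_value = p
  )
}
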