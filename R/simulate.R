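#' Latent truth for a simulated validation study
#'
#' Encodes the measurement model the generator samples from: per-analyte true
#' aqueous response lines (raw-area scale), per-matrix ionization-suppression
#' factors for each analyte and for the internal standard, per-matrix
#' extraction-recovery factors, a two-part noise model, carry-over and
#' blank-interference fractions, and the random seed. Every latent value is
#' recorded so downstream tests can check parameter recovery.
#'
#' The noise model has a concentration-proportional component
#' (`cv_prop`, justifying 1/x calibration weights) and a small additive
#' area-integration floor (`sd_floor`, 0.3 % of the LLOQ-level area by
#' default). The baseline-noise figure reported in the `noise_sd` column —
#' the quantity S/N is computed from — is a separate, larger `noise_level`,
#' set so the expected S/N at the LLOQ matches the study's observed values
#' (5.3 for TBT, 7.2 for TPhT): peak-detection noise and area-integration
#' repeatability are different quantities on a real instrument.
#'
#' Default suppression factors span 0.58-0.92 (the observed ME_A range, the
#' most suppressed matrix at 0.58), recoveries span 0.86-1.04, and the IS
#' tracks each analyte's suppression to within a few percent (giving a
#' relative matrix effect of ~4-5 % CV). The carry-over fraction of the
#' preceding high-standard area is set so the measured carry-over relative
#' to the LLOQ signal echoes ~1.2 %.
#'
#' @param seed Integer seed (< 2^31); per-block substreams are derived as
#'   seed + a fixed small offset per block.
#' @param n_matrices Number of sediment matrices (default 10).
#' @param cv_prop Proportional noise CV (default 0.05).
#' @param sd_floor_frac Additive floor as a fraction of the LLOQ-level area.
#' @param suppression Optional named list per analyte of length-`n_matrices`
#'   suppression factors in (0, 1.3]; defaults as described.
#' @param recovery Optional length-`n_matrices` recovery factors in (0, 1.1].
#' @param is_tracking Optional length-`n_matrices` IS/analyte suppression
#'   ratios (1 = perfect co-suppression).
#' @param carryover_frac Optional named per-analyte fraction of the preceding
#'   high-standard area appearing in the next blank, in [0, 0.05].
#' @param blank_frac Named per-analyte blank interference as a fraction of
#'   the LLOQ-level area.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(seed = 1L,
                             n_matrices = 10L,
                             cv_prop = 0.05,
                             sd_floor_frac = 0.003,
                             suppression = NULL,
                             recovery = NULL,
                             is_tracking = NULL,
                             carryover_frac = NULL,
                             blank_frac = c(TBT = 0.061, TPhT = 0.038)) {
  if (cv_prop < 0) abort("cv_prop must be >= 0.", class = "otval_validation_error")
  if (sd_floor_frac <= 0) abort("sd_floor_frac must be > 0.", class = "otval_validation_error")

  analytes <- tibble::tibble(
    analyte = c("TBT", "TPhT"),
    slope = c(1000, 400),          # area units per ng/g, aqueous
    intercept = c(20, 10),
    lloq = c(1, 5),
    top = c(4000, 4000),
    sn_at_lloq = c(5.3, 7.2)       # expected S/N at the LLOQ
  )
  analytes$a_lloq <- analytes$slope * analytes$lloq + analytes$intercept
  analytes$sd_floor <- sd_floor_frac * analytes$a_lloq
  analytes$noise_level <- analytes$a_lloq / analytes$sn_at_lloq
  analytes$blank_frac <- unname(blank_frac[analytes$analyte])
  if (is.null(carryover_frac)) {
    a_top <- analytes$slope * analytes$top + analytes$intercept
    carryover_frac <- c(0.0121, 0.0114) * analytes$a_lloq / a_top
  }
  analytes$carryover_frac <- unname(carryover_frac)
  if (any(analytes$carryover_frac < 0 | analytes$carryover_frac > 0.05)) {
    abort("carryover_frac must lie in [0, 0.05].", class = "otval_validation_error")
  }

  base_m <- seq(0.58, 0.92, length.out = n_matrices)
  if (is.null(suppression)) {
    suppression <- list(
      TBT = base_m,
      TPhT = pmin(pmax(base_m + rep_len(c(0.02, -0.02, 0.01, -0.01, 0.03),
                                        n_matrices), 0.05), 1.3)
    )
  }
  if (is.null(recovery)) recovery <- seq(0.86, 1.04, length.out = n_matrices)
  if (is.null(is_tracking)) {
    is_tracking <- rep_len(c(1.00, 0.95, 1.05, 0.98, 1.02, 0.96, 1.04, 1.00,
                             0.97, 1.03), n_matrices)
  }
  for (an in names(suppression)) {
    if (any(suppression[[an]] <= 0 | suppression[[an]] > 1.3)) {
      abort("Suppression factors must lie in (0, 1.3].", class = "otval_validation_error")
    }
  }
  if (any(recovery <= 0 | recovery > 1.1)) {
    abort("Recovery factors must lie in (0, 1.1].", class = "otval_validation_error")
  }

  matrices <- tibble::tibble(
    matrix_id = paste0("S", seq_len(n_matrices)),
    suppression_TBT = suppression$TBT,
    suppression_TPhT = suppression$TPhT,
    is_tracking = is_tracking,
    suppression_IS = suppression$TBT * is_tracking,
    recovery = recovery
  )

  structure(
    list(
      analytes = analytes,
      matrices = matrices,
      internal_standard = "TBT_d27",
      is_nominal_area = 50000,
      is_sd_floor = sd_floor_frac * 50000,
      is_blank_frac = 0.012,       # blank IS interference (fraction of IS area)
      is_carryover_frac = 0.003,
      control = list(suppression = 0.80, recovery = 0.95),  # blank QC sediment
      crm = list(suppression = 0.75, recovery = 0.92),
      cv_prop = cv_prop,
      seed = as.integer(seed)
    ),
    class = "simulation_truth"
  )
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth> seed", x$seed, "\n")
  cat("  analytes:", paste(x$analytes$analyte, collapse = ", "),
      "| IS:", x$internal_standard, "\n")
  cat("  matrices:", nrow(x$matrices),
      sprintf("| suppression %.2f-%.2f | recovery %.2f-%.2f\n",
              min(x$matrices$suppression_TBT), max(x$matrices$suppression_TBT),
              min(x$matrices$recovery), max(x$matrices$recovery)))
  cat("  noise: cv_prop", x$cv_prop, "\n")
  invisible(x)
}

#' Scenario specification for a simulated study
#'
#' The study design the generator realises: seven-point aqueous calibration
#' spanning 1-4000 ng/g (TBT) and 5-4000 ng/g (TPhT) with six replicate
#' curves, QC levels 3/2500/4000 (TBT) and 15/2500/4000 (TPhT) ng/g measured
#' five times within each of three runs, matrix-matched spike curves at
#' 2500/1000/500/100/50 ng/g in quadruplicate, pre/post-extraction spike
#' pairs at 1000 ng/g, six blank and six carry-over injections, five
#' stability conditions at a low and a high level, six CRM replicates, and
#' ten real samples (defaults at the concentrations reported for the ten
#' estuary sediments).
#'
#' @param cal_levels Named list of calibration levels per analyte (ng/g),
#'   positive and strictly increasing.
#' @param cal_replicates Replicate calibration curves (default 6).
#' @param qc_levels Named list of QC levels per analyte.
#' @param n_runs,qc_replicates Runs and within-run QC replicates.
#' @param me_levels Matrix-spike curve levels (ng/g).
#' @param me_replicates Replicates per matrix-spike level (default 4).
#' @param recovery_level,recovery_replicates Pre/post spike comparison level
#'   and replicates.
#' @param n_blanks,n_carryover Blank and carry-over injection counts.
#' @param stability_conditions Condition tags for stability blocks.
#' @param stability_levels Named list, low/high stability level per analyte.
#' @param stability_replicates Replicates per stability cell.
#' @param degradation Named numeric, fractional signal change per condition
#'   in [-0.3, 0.3]; conditions not named default to 0.
#' @param crm List: `certified`, `u_ref` (named per analyte), `n`.
#' @param real_samples Tibble with `sample_id` and one true-concentration
#'   column per analyte; defaults to the ten-sediment monitoring scenario.
#' @param real_replicates Replicates per real sample.
#' @param property_noise Log-scale sd of the noise on the linked sediment
#'   property (PAH).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(cal_levels = list(TBT = c(1, 5, 25, 100, 500, 2000, 4000),
                                            TPhT = c(5, 10, 50, 250, 1000, 2000, 4000)),
                          cal_replicates = 6L,
                          qc_levels = list(TBT = c(3, 2500, 4000),
                                           TPhT = c(15, 2500, 4000)),
                          n_runs = 3L,
                          qc_replicates = 5L,
                          me_levels = c(50, 100, 500, 1000, 2500),
                          me_replicates = 4L,
                          recovery_level = 1000,
                          recovery_replicates = 4L,
                          n_blanks = 6L,
                          n_carryover = 6L,
                          stability_conditions = c("freeze_thaw", "short_term_4h",
                                                   "long_term_30d",
                                                   "autosampler_24h",
                                                   "autosampler_48h"),
                          stability_levels = list(TBT = c(3, 4000),
                                                  TPhT = c(15, 4000)),
                          stability_replicates = 5L,
                          degradation = NULL,
                          crm = list(certified = c(TBT = 480, TPhT = 29),
                                     u_ref = c(TBT = 40, TPhT = 5.5), n = 6L),
                          real_samples = NULL,
                          real_replicates = 3L,
                          property_noise = 0.3) {
  for (an in names(cal_levels)) {
    lv <- cal_levels[[an]]
    if (any(lv <= 0) || is.unsorted(lv, strictly = TRUE)) {
      abort("Calibration levels must be positive and strictly increasing.",
            class = "otval_validation_error")
    }
  }
  reps <- c(cal_replicates, qc_replicates, me_replicates, recovery_replicates,
            stability_replicates, real_replicates, crm$n)
  if (any(reps < 2)) {
    abort("All replicate counts must be >= 2.", class = "otval_validation_error")
  }
  deg <- setNames(rep(0, length(stability_conditions)), stability_conditions)
  if (!is.null(degradation)) {
    if (any(abs(degradation) > 0.3)) {
      abort("Degradation fractions must lie in [-0.3, 0.3].",
            class = "otval_validation_error")
    }
    deg[names(degradation)] <- degradation
  }
  if (is.null(real_samples)) {
    real_samples <- tibble::tibble(
      sample_id = paste0("S", 1:10),
      TBT = c(3296, 3884, 142, 1016, 345, 213, 220, 750, 193, 5263),
      TPhT = c(2, 2, 90, 2, 2, 2, 2, 2, 2, 9)
    )
  }
  structure(
    list(cal_levels = cal_levels, cal_replicates = as.integer(cal_replicates),
         qc_levels = qc_levels, n_runs = as.integer(n_runs),
         qc_replicates = as.integer(qc_replicates),
         me_levels = me_levels, me_replicates = as.integer(me_replicates),
         recovery_level = recovery_level,
         recovery_replicates = as.integer(recovery_replicates),
         n_blanks = as.integer(n_blanks), n_carryover = as.integer(n_carryover),
         stability_conditions = stability_conditions,
         stability_levels = stability_levels,
         stability_replicates = as.integer(stability_replicates),
         degradation = deg, crm = crm,
         real_samples = real_samples,
         real_replicates = as.integer(real_replicates),
         property_noise = property_noise),
    class = "scenario_spec"
  )
}

# Noise model: area = expected * (1 + N(0, cv)) + N(0, floor), truncated at 0.
noisy_area <- function(expected, cv, floor_sd) {
  n <- length(expected)
  pmax(expected * (1 + rnorm(n, 0, cv)) + rnorm(n, 0, floor_sd), 0)
}

block_seed <- function(truth, offset) {
  set.seed((truth$seed %% 1000000000L) + offset)
}

row_tpl <- function(...) {
  defaults <- list(sample_id = NA_character_, analyte = NA_character_,
                   role = NA_character_, run_id = "run1", replicate = 1L,
                   nominal_conc = NA_real_, peak_area = NA_real_,
                   is_area = NA_real_, noise_sd = NA_real_,
                   matrix_id = NA_character_, condition = NA_character_,
                   medium = "water")
  args <- list(...)
  defaults[names(args)] <- args
  do.call(tibble::tibble, defaults)
}

#' Simulate a complete validation study
#'
#' Realises every block the pipeline consumes from the latent truth and the
#' scenario: aqueous calibration curves, QC replicates across runs in a
#' control sediment, blanks with interference near the LLOQ, carry-over
#' blanks following the top standard, stability sets with the configured
#' degradation, matrix-matched post-extraction spike curves (areas scaled by
#' the suppression factor), pre-extraction spikes (scaled by suppression x
#' recovery), aqueous reference curves for the matrix-effect design, CRM
#' replicates and real samples. Fully reproducible: the same truth (seed)
#' and scenario yield identical records, with a fixed substream offset per
#' block so blocks are individually reproducible.
#'
#' @param truth A [simulation_truth()].
#' @param spec A [scenario_spec()].
#' @return A list of class `otval_simulation`: `measurements` (validated
#'   measurement tibble), `profiles` (sediment profiles linked to the
#'   suppression factors), and `truth`.
#' @export
simulate_study <- function(truth = simulation_truth(), spec = scenario_spec()) {
  stopifnot(inherits(truth, "simulation_truth"), inherits(spec, "scenario_spec"))
  an_tab <- truth$analytes
  mats <- truth$matrices
  is_nom <- truth$is_nominal_area
  is_floor <- truth$is_sd_floor %||% (0.003 * is_nom)
  cv <- truth$cv_prop
  blocks <- list()

  aqueous_expected <- function(a, x) a$slope * x + a$intercept
  sample_expected <- function(a, x, supp, rec) supp * rec * a$slope * x + a$intercept

  # -- calibration (offset 1): aqueous curves, IS at nominal -----------------
  block_seed(truth, 1L)
  blocks$cal <- purrr::map_dfr(seq_len(nrow(an_tab)), function(i) {
    a <- an_tab[i, ]
    lv <- spec$cal_levels[[a$analyte]]
    d <- tidyr::expand_grid(nominal_conc = lv,
                            replicate = seq_len(spec$cal_replicates))
    row_tpl(
      sample_id = sprintf("CAL_%s_L%02d_r%d", a$analyte,
                          match(d$nominal_conc, lv), d$replicate),
      analyte = a$analyte, role = "calibrant",
      run_id = paste0("run", ((d$replicate - 1L) %% spec$n_runs) + 1L),
      replicate = d$replicate, nominal_conc = d$nominal_conc,
      peak_area = noisy_area(aqueous_expected(a, d$nominal_conc), cv, a$sd_floor),
      is_area = noisy_area(rep(is_nom, nrow(d)), cv, is_floor),
      noise_sd = a$noise_level, medium = "water"
    )
  })

  # -- QC (offset 2): control sediment, IS co-suppressed exactly ------------
  block_seed(truth, 2L)
  ctl <- truth$control
  blocks$qc <- purrr::map_dfr(seq_len(nrow(an_tab)), function(i) {
    a <- an_tab[i, ]
    # the LLOQ is part of the accuracy/precision design (n = 5 within-run,
    # n = 15 between runs), alongside the QC levels
    d <- tidyr::expand_grid(nominal_conc = c(a$lloq, spec$qc_levels[[a$analyte]]),
                            run = seq_len(spec$n_runs),
                            replicate = seq_len(spec$qc_replicates))
    row_tpl(
      sample_id = sprintf("QC_%s_%g_run%d_r%d", a$analyte, d$nominal_conc,
                          d$run, d$replicate),
      analyte = a$analyte, role = "qc", run_id = paste0("run", d$run),
      replicate = d$replicate, nominal_conc = d$nominal_conc,
      peak_area = noisy_area(sample_expected(a, d$nominal_conc,
                                             ctl$suppression, ctl$recovery),
                             cv, a$sd_floor),
      is_area = noisy_area(rep(is_nom * ctl$suppression * ctl$recovery, nrow(d)),
                           cv, is_floor),
      noise_sd = a$noise_level, matrix_id = "CTRL", medium = "matrix"
    )
  })

  # -- blanks (offset 3): interference near the LLOQ; plus IS-channel blanks -
  block_seed(truth, 3L)
  blocks$blank <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(nrow(an_tab)), function(i) {
      a <- an_tab[i, ]
      row_tpl(
        sample_id = sprintf("BLK_%s_%d", a$analyte, seq_len(spec$n_blanks)),
        analyte = a$analyte, role = "blank",
        replicate = seq_len(spec$n_blanks),
        peak_area = noisy_area(rep(a$blank_frac * a$a_lloq, spec$n_blanks),
                               cv, a$sd_floor),
        noise_sd = a$noise_level, matrix_id = "CTRL", medium = "matrix"
      )
    }),
    row_tpl(
      sample_id = sprintf("BLK_IS_%d", seq_len(spec$n_blanks)),
      analyte = truth$internal_standard, role = "blank",
      replicate = seq_len(spec$n_blanks),
      peak_area = noisy_area(rep(truth$is_blank_frac * is_nom, spec$n_blanks),
                             cv, is_floor),
      matrix_id = "CTRL", medium = "matrix"
    )
  )

  # -- carry-over blanks (offset 4): fraction of preceding top standard ------
  block_seed(truth, 4L)
  blocks$carry <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(nrow(an_tab)), function(i) {
      a <- an_tab[i, ]
      a_top <- aqueous_expected(a, a$top)
      row_tpl(
        sample_id = sprintf("CO_%s_%d", a$analyte, seq_len(spec$n_carryover)),
        analyte = a$analyte, role = "carryover_blank",
        replicate = seq_len(spec$n_carryover),
        peak_area = noisy_area(rep(a$carryover_frac * a_top, spec$n_carryover),
                               cv, a$sd_floor),
        noise_sd = a$noise_level, medium = "water"
      )
    }),
    row_tpl(
      sample_id = sprintf("CO_IS_%d", seq_len(spec$n_carryover)),
      analyte = truth$internal_standard, role = "carryover_blank",
      replicate = seq_len(spec$n_carryover),
      peak_area = noisy_area(rep(truth$is_carryover_frac * is_nom,
                                 spec$n_carryover), cv, is_floor),
      medium = "water"
    )
  )

  # -- stability (offset 5): condition sets plus fresh references ------------
  block_seed(truth, 5L)
  conds <- c("reference", spec$stability_conditions)
  blocks$stab <- purrr::map_dfr(seq_len(nrow(an_tab)), function(i) {
    a <- an_tab[i, ]
    d <- tidyr::expand_grid(nominal_conc = spec$stability_levels[[a$analyte]],
                            condition = conds,
                            replicate = seq_len(spec$stability_replicates))
    frac <- ifelse(d$condition == "reference", 0,
                   spec$degradation[d$condition])
    expected <- sample_expected(a, d$nominal_conc, ctl$suppression,
                                ctl$recovery) * (1 + frac)
    row_tpl(
      sample_id = sprintf("ST_%s_%g_%s_r%d", a$analyte, d$nominal_conc,
                          d$condition, d$replicate),
      analyte = a$analyte, role = "stability", replicate = d$replicate,
      nominal_conc = d$nominal_conc,
      peak_area = noisy_area(expected, cv, a$sd_floor),
      is_area = noisy_area(rep(is_nom * ctl$suppression * ctl$recovery, nrow(d)),
                           cv, is_floor),
      noise_sd = a$noise_level, matrix_id = "CTRL",
      condition = d$condition, medium = "matrix"
    )
  })

  # -- CRM (offset 6) --------------------------------------------------------
  block_seed(truth, 6L)
  blocks$crm <- purrr::map_dfr(seq_len(nrow(an_tab)), function(i) {
    a <- an_tab[i, ]
    conc <- spec$crm$certified[[a$analyte]]
    n <- spec$crm$n
    row_tpl(
      sample_id = sprintf("CRM_%s_r%d", a$analyte, seq_len(n)),
      analyte = a$analyte, role = "crm", replicate = seq_len(n),
      nominal_conc = conc,
      peak_area = noisy_area(rep(sample_expected(a, conc, truth$crm$suppression,
                                                 truth$crm$recovery), n),
                             cv, a$sd_floor),
      is_area = noisy_area(rep(is_nom * truth$crm$suppression *
                                 truth$crm$recovery, n), cv, is_floor),
      noise_sd = a$noise_level, matrix_id = "CRM", medium = "matrix"
    )
  })

  # -- real samples (offset 7): the study matrices themselves ----------------
  block_seed(truth, 7L)
  blocks$real <- purrr::map_dfr(seq_len(nrow(an_tab)), function(i) {
    a <- an_tab[i, ]
    rs <- spec$real_samples
    idx <- match(rs$sample_id, mats$matrix_id)
    supp <- mats[[paste0("suppression_", a$analyte)]][idx]
    supp[is.na(supp)] <- 1
    rec <- mats$recovery[idx]; rec[is.na(rec)] <- 1
    is_supp <- mats$suppression_IS[idx] /
      mats$suppression_TBT[idx] * supp  # IS tracking applied to this analyte
    is_supp[is.na(is_supp)] <- 1
    d <- tidyr::expand_grid(k = seq_len(nrow(rs)),
                            replicate = seq_len(spec$real_replicates))
    conc <- rs[[a$analyte]][d$k]
    row_tpl(
      sample_id = rs$sample_id[d$k], analyte = a$analyte, role = "real",
      replicate = d$replicate,
      peak_area = noisy_area(sample_expected(a, conc, supp[d$k], rec[d$k]),
                             cv, a$sd_floor),
      is_area = noisy_area(is_nom * is_supp[d$k] * rec[d$k], cv, is_floor),
      noise_sd = a$noise_level, matrix_id = rs$sample_id[d$k],
      medium = "matrix"
    )
  })

  # -- matrix-effect design (offset 8): reference, post- and pre-spikes ------
  block_seed(truth, 8L)
  blocks$me <- purrr::map_dfr(seq_len(nrow(an_tab)), function(i) {
    a <- an_tab[i, ]
    supp <- mats[[paste0("suppression_", a$analyte)]]
    is_supp <- mats$suppression_IS / mats$suppression_TBT * supp
    ref <- tidyr::expand_grid(nominal_conc = spec$me_levels,
                              replicate = seq_len(spec$me_replicates))
    post <- tidyr::expand_grid(m = seq_len(nrow(mats)),
                               nominal_conc = spec$me_levels,
                               replicate = seq_len(spec$me_replicates))
    pre <- tidyr::expand_grid(m = seq_len(nrow(mats)),
                              nominal_conc = spec$recovery_level,
                              replicate = seq_len(spec$recovery_replicates))
    dplyr::bind_rows(
      row_tpl(
        sample_id = sprintf("REF_%s_%g_r%d", a$analyte, ref$nominal_conc,
                            ref$replicate),
        analyte = a$analyte, role = "reference", replicate = ref$replicate,
        nominal_conc = ref$nominal_conc,
        peak_area = noisy_area(aqueous_expected(a, ref$nominal_conc), cv,
                               a$sd_floor),
        is_area = noisy_area(rep(is_nom, nrow(ref)), cv, is_floor),
        noise_sd = a$noise_level, medium = "water"
      ),
      # post-extraction spike: suppression only, IS added after extraction
      row_tpl(
        sample_id = sprintf("POST_%s_%s_%g_r%d", a$analyte,
                            mats$matrix_id[post$m], post$nominal_conc,
                            post$replicate),
        analyte = a$analyte, role = "spike_post", replicate = post$replicate,
        nominal_conc = post$nominal_conc,
        peak_area = noisy_area(supp[post$m] * a$slope * post$nominal_conc +
                                 a$intercept, cv, a$sd_floor),
        is_area = noisy_area(is_nom * is_supp[post$m], cv, is_floor),
        noise_sd = a$noise_level, matrix_id = mats$matrix_id[post$m],
        medium = "matrix"
      ),
      # pre-extraction spike: suppression x recovery
      row_tpl(
        sample_id = sprintf("PRE_%s_%s_r%d", a$analyte,
                            mats$matrix_id[pre$m], pre$replicate),
        analyte = a$analyte, role = "spike_pre", replicate = pre$replicate,
        nominal_conc = pre$nominal_conc,
        peak_area = noisy_area(supp[pre$m] * mats$recovery[pre$m] * a$slope *
                                 pre$nominal_conc + a$intercept, cv, a$sd_floor),
        is_area = noisy_area(is_nom * is_supp[pre$m] * mats$recovery[pre$m],
                             cv, is_floor),
        noise_sd = a$noise_level, matrix_id = mats$matrix_id[pre$m],
        medium = "matrix"
      )
    )
  })

  measurements <- validate_measurements(dplyr::bind_rows(blocks))
  profiles <- simulate_sediment_profiles(truth, spec)
  structure(list(measurements = measurements, profiles = profiles,
                 truth = truth),
            class = "otval_simulation")
}

#' Simulate sediment profiles linked to the suppression factors
#'
#' Generates property vectors whose anthropogenic-contamination markers are
#' monotone transforms of the ionization suppression (1 - m): PAH (the
#' linked property, log-scale spanning ~500-74,000 ug/kg), with TOC, AVS and
#' heavy metals partially co-varying, sand decreasing and silt increasing
#' with suppression — emulating the observed structure in which polluted,
#' fine-grained, organic-rich sediments suppress ESI ionization most. Grain
#' fractions sum to 100.
#'
#' @param truth A [simulation_truth()] (uses the TBT suppression factors and
#'   seed substream 9).
#' @param spec A [scenario_spec()] (uses `property_noise`).
#' @return A sediment-profile tibble.
#' @export
simulate_sediment_profiles <- function(truth = simulation_truth(),
                                       spec = scenario_spec()) {
  block_seed(truth, 9L)
  m <- truth$matrices$suppression_TBT
  n <- length(m)
  # u in [0, 1]: 1 = most suppressed (dirtiest) matrix
  u <- if (diff(range(m)) > 0) (max(m) - m) / diff(range(m)) else rep(0.5, n)
  noise <- function(sdlog) exp(rnorm(n, 0, sdlog))
  pah <- 500 * (74000 / 500)^u * noise(spec$property_noise)
  toc <- pmin(0.5 + 11 * u * noise(0.25), 100)
  avs <- pmin(0.05 + 0.8 * u * noise(0.3), 100)
  metals <- 1200 + 2400 * u * noise(0.2)
  sand <- pmin(pmax(round(50 - 35 * u + rnorm(n, 0, 3)), 5), 95)
  clay <- pmin(pmax(round(3 + rnorm(n, 0, 0.7)), 1), 6)
  tibble::tibble(
    matrix_id = truth$matrices$matrix_id,
    pH = round(rnorm(n, 6.8, 0.15), 1),
    conductivity = round(exp(rnorm(n, 0, 0.25)), 2),
    toc = round(toc, 2),
    n = round(0.2 + 1.1 * u * noise(0.2), 2),
    h = round(0.5 + 1.7 * u * noise(0.2), 2),
    avs = round(avs, 2),
    p = round(stats::runif(n, 0.13, 0.8), 3),
    heavy_metals = round(metals),
    pah = round(pah),
    sand = sand,
    silt = 100 - sand - clay,
    clay = clay
  )
}

#' Apply a stability degradation to measured records
#'
#' Scales the peak areas of a record set by (1 + fraction) and re-applies the
#' proportional noise, preserving all tags except the condition, which is set
#' to `condition`. Used to manufacture stability test sets from reference
#' records.
#'
#' @param records Measurement tibble.
#' @param condition Condition tag for the degraded records.
#' @param fraction Fractional signal change in [-0.3, 0.3].
#' @param cv_prop Proportional noise CV applied on top (default 0.05).
#' @param seed Optional seed.
#' @return The degraded measurement tibble.
#' @export
degrade_for_stability <- function(records, condition, fraction,
                                  cv_prop = 0.05, seed = NULL) {
  if (abs(fraction) > 0.3) {
    abort("Degradation fraction must lie in [-0.3, 0.3].",
          class = "otval_validation_error")
  }
  records <- validate_measurements(records)
  if (!is.null(seed)) set.seed(seed)
  records$peak_area <- pmax(records$peak_area * (1 + fraction) *
                              (1 + rnorm(nrow(records), 0, cv_prop)), 0)
  records$condition <- condition
  records$role <- "stability"
  records
}
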