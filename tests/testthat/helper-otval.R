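# Closed-form weighted least squares via the normal equations: the
# independent oracle for fit_weighted_line().
wls_oracle <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  den <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / sw
  r <- y - intercept - slope * x
  s2 <- sum(w * r^2) / (length(x) - 2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(s2 * sw / den),
       intercept_se = sqrt(s2 * sxx / den))
}

# Exact calibration_fit for a known line (noiseless points).
exact_fit <- function(slope, intercept, response_kind = "raw_area",
                      analyte = "TBT") {
  x <- c(1, 10, 100)
  fit_weighted_line(x, slope * x + intercept, weighting = "none",
                    response_kind = response_kind, analyte = analyte)
}

# Numeric vector with exactly the requested mean, sd and length.
vec_with <- function(mean, sd, n) {
  if (sd == 0) return(rep(mean, n))
  base <- rep(c(-1, 1), length.out = n)
  base <- base - mean(base)
  mean + sd * base / stats::sd(base)
}

# Measurement rows at one level with given areas (raw-area response).
area_records <- function(areas, analyte = "TBT", level = 100,
                         role = "qc", run_id = "run1", noise_sd = NA_real_,
                         matrix_id = NA_character_, condition = NA_character_) {
  measurement_table(
    sample_id = paste0(role, "_", seq_along(areas)), analyte = analyte,
    role = role, run_id = run_id, replicate = seq_along(areas),
    nominal_conc = level, peak_area = areas, noise_sd = noise_sd,
    matrix_id = matrix_id, condition = condition,
    medium = if (role %in% c("calibrant", "reference")) "water" else "matrix"
  )
}
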