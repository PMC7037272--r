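#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the product-moment correlation of average ranks (ties get average
#' ranks); the two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) with n - 2 degrees of freedom,
#' adequate at the study's sample sizes (n ~ 10). Missing pairs are dropped
#' pairwise before ranking.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble: rho, p_value, n.
#' @export
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length.", class = "otval_contract_error")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) {
    abort("Spearman correlation needs >= 4 complete pairs.",
          class = "otval_insufficient_data_error")
  }
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("Correlation undefined: zero variance in ranks.",
          class = "otval_degenerate_error")
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * pt(-abs(t_stat), df = n - 2), .Machine$double.xmin)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Screen matrix-effect/recovery responses against sediment properties
#'
#' Joins a per-matrix response table (e.g. ME_A and RE per analyte) with the
#' sediment profiles by `matrix_id` and computes one Spearman cell per
#' (response, property) pair, dropping missing values pairwise. Pairs with
#' fewer than 4 complete observations are omitted. Cells are flagged
#' significant at p < 0.05; no multiple-testing correction is applied — the
#' raw p-values are returned so the user can apply one.
#'
#' @param responses Tibble with `matrix_id` plus numeric response columns.
#' @param profiles Sediment-profile tibble ([read_sediment_profiles()]).
#' @param properties Character vector of profile columns to screen; defaults
#'   to all numeric profile columns present.
#' @return A tibble: response, property, rho, p_value, n, significant.
#' @export
correlation_screen <- function(responses, profiles,
                               properties = intersect(sediment_numeric_cols,
                                                      names(profiles))) {
  profiles <- validate_sediment_profiles(profiles)
  joined <- dplyr::inner_join(responses, profiles, by = "matrix_id",
                              suffix = c("", ".profile"))
  resp_cols <- setdiff(names(responses)[vapply(responses, is.numeric, logical(1))],
                       "matrix_id")
  grid <- tidyr::expand_grid(response = resp_cols, property = properties)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    rs <- grid$response[i]; pr <- grid$property[i]
    x <- joined[[rs]]; y <- joined[[pr]]
    if (sum(!is.na(x) & !is.na(y)) < 4) return(tibble::tibble())
    cell <- tryCatch(spearman_cor(x, y), otval_degenerate_error = function(e) NULL)
    if (is.null(cell)) return(tibble::tibble())
    dplyr::bind_cols(tibble::tibble(response = rs, property = pr), cell) |>
      dplyr::mutate(significant = .data$p_value < 0.05)
  })
}

#' Principal component analysis of sediment profiles
#'
#' Standardizes the selected variables to zero mean and unit variance
#' (mandatory here: the profile mixes %, mS, mg/kg and ug/kg scales) and
#' decomposes by singular values. Rows with any missing value among the
#' selected variables are excluded listwise.
#'
#' @param profiles Sediment-profile tibble.
#' @param variables Columns to include; defaults to all numeric profile
#'   columns present.
#' @return An object of class `pca_model`: variable names, loadings
#'   (orthonormal columns), per-sample scores, standard deviations, and
#'   variance explained per component (%, summing to 100).
#' @export
pca_profiles <- function(profiles,
                         variables = intersect(sediment_numeric_cols,
                                               names(profiles))) {
  profiles <- validate_sediment_profiles(profiles)
  if (length(variables) < 2) {
    abort("PCA needs >= 2 variables.", class = "otval_insufficient_data_error")
  }
  mat <- as.matrix(profiles[variables])
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  ids <- profiles$matrix_id[keep]
  if (nrow(mat) < 3) {
    abort("PCA needs >= 3 complete samples after listwise deletion.",
          class = "otval_insufficient_data_error")
  }
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance variable(s): ",
                 paste(variables[sds == 0], collapse = ", ")),
          class = "otval_degenerate_variable_error")
  }
  pc <- prcomp(mat, center = TRUE, scale. = TRUE)
  var_expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(variables = variables, matrix_id = ids,
         loadings = pc$rotation, scores = pc$x,
         sdev = pc$sdev, var_explained = var_expl,
         center = pc$center, scale = pc$scale),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", length(x$variables), "variables,",
      nrow(x$scores), "samples\n")
  cat("  variance explained (%):",
      paste(sprintf("%.1f", x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.pca_model <- function(x, matrix = c("loadings", "scores"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "loadings") {
    tibble::as_tibble(x$loadings, rownames = "variable") |>
      tidyr::pivot_longer(-"variable", names_to = "component",
                          values_to = "loading")
  } else {
    tibble::as_tibble(x$scores) |>
      dplyr::mutate(matrix_id = x$matrix_id, .before = 1) |>
      tidyr::pivot_longer(-"matrix_id", names_to = "component",
                          values_to = "score")
  }
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(component = seq_along(x$sdev), sdev = x$sdev,
                 var_explained = x$var_explained,
                 cum_var_explained = cumsum(x$var_explained))
}

#' Biplot coordinates for a chosen pair of principal components
#'
#' Returns plottable tables only — no plotting side effects. Scores are the
#' per-sample coordinates on the two components; loading arrows are the
#' variable loadings scaled by the component standard deviations, so each
#' arrow's length approximates the variable's correlation structure and is
#' bounded by its singular-value scale.
#'
#' @param model A `pca_model`.
#' @param components Integer pair (i, j) of component indices.
#' @return A list of tibbles: `scores` (matrix_id, x, y) and `arrows`
#'   (variable, x, y).
#' @export
biplot_data <- function(model, components = c(1, 2)) {
  stopifnot(inherits(model, "pca_model"))
  k <- length(model$sdev)
  if (any(components < 1 | components > k)) {
    abort(sprintf("Component index out of range 1..%d.", k),
          class = "otval_index_error")
  }
  i <- components[1]; j <- components[2]
  list(
    scores = tibble::tibble(matrix_id = model$matrix_id,
                            x = model$scores[, i], y = model$scores[, j]),
    arrows = tibble::tibble(variable = rownames(model$loadings),
                            x = model$loadings[, i] * model$sdev[i],
                            y = model$loadings[, j] * model$sdev[j])
  )
}

#' Autoplot a PCA biplot
#'
#' @param object A `pca_model`.
#' @param components Component pair to display.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pca_model <- function(object, components = c(1, 2), ...) {
  bd <- biplot_data(object, components)
  scale_f <- max(abs(unlist(bd$scores[c("x", "y")]))) /
    max(abs(unlist(bd$arrows[c("x", "y")])), na.rm = TRUE)
  arrows <- dplyr::mutate(bd$arrows, x = .data$x * scale_f, y = .data$y * scale_f)
  ggplot2::ggplot(bd$scores, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$matrix_id),
                       vjust = -0.6, size = 3) +
    ggplot2::geom_segment(data = arrows,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "firebrick") +
    ggplot2::geom_text(data = arrows,
                       ggplot2::aes(label = .data$variable),
                       colour = "firebrick", vjust = 1.4, size = 3) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1],
                  object$var_explained[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2],
                  object$var_explained[components[2]])
    )
}

#' Welch's t-test from summary statistics
#'
#' Two-sided Welch test for groups reported only as mean +/- sd with n —
#' the form in which condition comparisons (extraction times, agitation
#' techniques) are tabulated. When both sds are zero the p-value is 1 for
#' equal means and 0 otherwise.
#'
#' @param mean1,sd1,n1 First group's mean, sd (>= 0) and size (>= 2).
#' @param mean2,sd2,n2 Second group's summary statistics.
#' @return A one-row tibble: t, df, p_value.
#' @export
#' @examples
#' welch_t_from_summary(69.3, 2.7, 5, 89.0, 1.5, 5)
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) {
    abort("Both groups need n >= 2.", class = "otval_insufficient_data_error")
  }
  if (sd1 < 0 || sd2 < 0) abort("sds must be >= 0.", class = "otval_domain_error")
  se2 <- sd1^2 / n1 + sd2^2 / n2
  if (se2 == 0) {
    return(tibble::tibble(t = 0, df = n1 + n2 - 2,
                          p_value = if (mean1 == mean2) 1 else 0))
  }
  t_stat <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  tibble::tibble(t = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df = df))
}
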