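#' Evaluation metrics for deconvolution predictions
#'
#' Four statistics used to compare a prediction `y` against a ground truth
#' `x`: the mean absolute (L1) error, Pearson's correlation, Lin's
#' concordance correlation coefficient (CCC), and a linear-fitting R² score.
#' All moment-based quantities use population (1/N) variances so that
#' `ccc(x, x)` is exactly 1.
#'
#' Lin's CCC is
#' \deqn{\rho_c = \frac{2\rho\sigma_x\sigma_y}{\sigma_x^2+\sigma_y^2+(\mu_x-\mu_y)^2}}
#' which penalises both decorrelation and location/scale shifts, so
#' \eqn{|\rho_c| \le |\rho|} with equality only when the two moments match.
#'
#' The R² score is \eqn{1 - \sum_i (y_i-x_i)^2 / \sum_i (x_i-\bar x)^2}: it is
#' 1 for a perfect prediction and 0 for the constant prediction at the
#' ground-truth mean (unlike regression R², it can be arbitrarily negative).
#'
#' @param x numeric vector of ground-truth values.
#' @param y numeric vector of predictions, same length as `x`.
#' @return a single numeric value.
#' @examples
#' x <- c(0, 1, 2)
#' ccc(x, x + 1)      # 2*var/(2*var + 1) with population var 2/3 -> 4/7
#' r2_fit(x, rep(mean(x), 3)) # constant prediction at the mean -> 0
#' @name deconv-metrics
NULL

check_xy <- function(x, y, n_min = 1L) {
  if (!is.numeric(x) || !is.numeric(y)) {
    abort("`x` and `y` must be numeric vectors.")
  }
  if (length(x) != length(y)) {
    abort(sprintf(
      "`x` and `y` must have equal length (got %d and %d).",
      length(x), length(y)
    ))
  }
  if (length(x) < n_min) {
    abort(sprintf("need at least %d observations.", n_min))
  }
  if (anyNA(x) || anyNA(y)) abort("`x` and `y` must not contain NA.")
  invisible(TRUE)
}

pop_var <- function(x) mean((x - mean(x))^2)

#' @rdname deconv-metrics
#' @export
l1_error <- function(x, y) {
  check_xy(x, y, 1L)
  mean(abs(y - x))
}

#' @rdname deconv-metrics
#' @export
pearson <- function(x, y) {
  check_xy(x, y, 2L)
  if (pop_var(x) == 0 || pop_var(y) == 0) {
    abort("Pearson correlation undefined for constant input.")
  }
  stats::cor(x, y)
}

#' @rdname deconv-metrics
#' @export
ccc <- function(x, y) {
  check_xy(x, y, 2L)
  vx <- pop_var(x)
  vy <- pop_var(y)
  if (vx == 0 || vy == 0) {
    abort("CCC undefined for constant input (zero variance).")
  }
  rho <- stats::cor(x, y)
  2 * rho * sqrt(vx) * sqrt(vy) / (vx + vy + (mean(x) - mean(y))^2)
}

#' @rdname deconv-metrics
#' @export
r2_fit <- function(x, y) {
  check_xy(x, y, 2L)
  ss_den <- sum((x - mean(x))^2)
  if (ss_den == 0) abort("R² undefined for constant ground truth.")
  1 - sum((y - x)^2) / ss_den
}

#' Summarise all metrics for one prediction/truth pair
#'
#' @param x,y ground truth and prediction vectors.
#' @return a one-row tibble with `l1`, `pearson`, `ccc`, `r2`, `n` and the
#'   audit moments `mu_x`, `mu_y`, `var_x`, `var_y` (population variances).
#' @export
metrics_report <- function(x, y) {
  check_xy(x, y, 2L)
  tibble(
    l1 = l1_error(x, y),
    pearson = pearson(x, y),
    ccc = ccc(x, y),
    r2 = r2_fit(x, y),
    n = length(x),
    mu_x = mean(x), mu_y = mean(y),
    var_x = pop_var(x), var_y = pop_var(y)
  )
}

#' Per-cell-type evaluation of a deconvolution run against ground truth
#'
#' Compares predicted proportions (and optionally predicted GEPs) from
#' [deconvolve()] with the ground truth carried by a simulated pseudobulk
#' set, one row per cell type.
#'
#' @param result a `deconv_result` from [deconvolve()].
#' @param truth a `pseudobulk_set` holding `p_target` and `G_target`.
#' @return a tibble with one row per cell type: proportion `l1`, `ccc`,
#'   `pearson`, `r2` across samples, and mean per-sample GEP Pearson
#'   correlation `gep_pearson` over samples where the type is present.
#' @export
evaluate_deconvolution <- function(result, truth) {
  stopifnot(inherits(result, "deconv_result"), inherits(truth, "pseudobulk_set"))
  types <- result$cell_types
  if (!identical(types, truth$cell_types)) {
    abort("cell-type order differs between result and truth.")
  }
  p_hat <- result$proportions_matrix   # n x c
  p_true <- t(truth$p_target)          # n x c
  genes <- intersect(result$gene_ids, truth$gene_ids)
  gi_r <- match(genes, result$gene_ids)
  gi_t <- match(genes, truth$gene_ids)
  purrr::map_dfr(seq_along(types), function(k) {
    gp <- vapply(seq_len(dim(result$G_hat)[3]), function(s) {
      if (!truth$type_mask[k, s]) return(NA_real_)
      gt <- truth$G_target[gi_t, k, s]
      if (pop_var(gt) == 0) return(NA_real_)
      stats::cor(result$G_hat[gi_r, k, s], gt)
    }, numeric(1))
    tibble(
      cell_type = types[k],
      l1 = l1_error(p_true[, k], p_hat[, k]),
      ccc = ccc(p_true[, k], p_hat[, k]),
      pearson = pearson(p_true[, k], p_hat[, k]),
      r2 = r2_fit(p_true[, k], p_hat[, k]),
      gep_pearson = mean(gp, na.rm = TRUE)
    )
  })
}
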