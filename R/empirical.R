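#' Empirical cumulative distribution function at a point
#'
#' Right-continuous step-function estimate of a distribution function:
#' the fraction of sample values less than or equal to `x`. Ties in the
#' sample are handled by the weak inequality, so duplicated values
#' contribute jointly to the step height.
#'
#' @param values Numeric sample (need not be sorted). Must be non-empty
#'   and finite.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector in `[0, 1]`, one probability per element of `x`.
#' @examples
#' empirical_cdf(c(1, 2, 2, 5), 2)   # 0.75
#' empirical_cdf(c(1, 2, 3), c(0.5, 3))
#' @seealso [empirical_quantile()] for the generalized inverse.
#' @export
empirical_cdf <- function(values, x) {
  if (length(values) == 0L) {
    stop("empirical_cdf: degenerate input, sample is empty")
  }
  if (!all(is.finite(values))) {
    stop("empirical_cdf: sample contains non-finite values")
  }
  vapply(x, function(xi) mean(values <= xi), numeric(1))
}

#' Empirical quantile function (left-continuous generalized inverse)
#'
#' Returns the smallest sample value `v` such that
#' `empirical_cdf(values, v) >= y`. This is the left-continuous
#' generalized inverse of the empirical CDF; for a sample of size `m`
#' and probability `y` it equals the `ceiling(m * y)`-th order statistic.
#'
#' @param values Numeric sample, non-empty and finite.
#' @param y Probabilities, each strictly inside `(0, 1)`.
#' @return Numeric vector of sample values, one per element of `y`.
#' @examples
#' empirical_quantile(c(1, 2, 3, 4), 0.5)   # 2
#' empirical_quantile(c(1, 2, 3, 4), 0.51)  # 3
#' @export
empirical_quantile <- function(values, y) {
  if (length(values) == 0L) {
    stop("empirical_quantile: degenerate input, sample is empty")
  }
  if (!all(is.finite(values))) {
    stop("empirical_quantile: sample contains non-finite values")
  }
  if (any(y <= 0 | y >= 1)) {
    stop("empirical_quantile: probabilities must lie strictly in (0, 1)")
  }
  sorted <- sort(values)
  m <- length(sorted)
  sorted[ceiling(y * m)]
}

#' Reference distribution of the normal group on a fixed probability grid
#'
#' Builds the reference used by the change-point scan: the sorted
#' normal-group sample together with a fixed-step probability grid
#' `y_j = j / (G + 1)`, `j = 1..G`, and the corresponding quantiles of
#' the empirical CDF. The grid avoids the endpoints 0 and 1, where the
#' inverse empirical CDF is degenerate; with the default `grid_size`
#' of 100 the grid levels never coincide with a jump `i / n1` of the
#' reference ECDF for any group size `n1 < 101`, which keeps the scan
#' statistic exactly antisymmetric under negation of the data.
#'
#' @param normal_values Expression values of the normal-group samples
#'   (at least 2, all finite).
#' @param grid_size Number of grid levels `G` (>= 10, default 100).
#' @return A list of class `"npcps_reference"` with elements
#'   `sorted` (sorted normal values), `grid` (probability levels) and
#'   `quantiles` (left-continuous empirical quantiles at the grid).
#' @examples
#' ref <- reference_distribution(rnorm(25))
#' all(empirical_cdf(ref$sorted, ref$quantiles) >= ref$grid)  # TRUE
#' @export
reference_distribution <- function(normal_values, grid_size = 100L) {
  if (length(normal_values) < 2L) {
    stop("reference_distribution: need at least 2 normal-group values")
  }
  if (!all(is.finite(normal_values))) {
    stop("reference_distribution: normal values must be finite")
  }
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 10L) {
    stop("reference_distribution: grid_size must be an integer >= 10")
  }
  if (length(unique(normal_values)) == 1L) {
    warning("reference_distribution: constant normal values, reference is a point mass")
  }
  sorted <- sort(normal_values)
  grid <- seq_len(grid_size) / (grid_size + 1)
  structure(
    list(
      sorted = sorted,
      grid = grid,
      quantiles = sorted[ceiling(grid * length(sorted))]
    ),
    class = "npcps_reference"
  )
}
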