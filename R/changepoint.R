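#' Asymptotic Kolmogorov critical value
#'
#' Two-sided critical value `C(alpha)` of the Kolmogorov distribution,
#' `sqrt(-log(alpha / 2) / 2)`. Reproduces the classical constants
#' `C(0.05) = 1.358` and `C(0.01) = 1.628`.
#'
#' @param alpha Significance level in `(0, 1)`.
#' @return Positive critical value.
#' @examples
#' kolmogorov_critical(0.05)  # 1.358...
#' @export
kolmogorov_critical <- function(alpha) {
  if (any(alpha <= 0 | alpha >= 1)) {
    stop("kolmogorov_critical: alpha must lie strictly in (0, 1)")
  }
  sqrt(-log(alpha / 2) / 2)
}

# Core scan over candidate change points.
#
# z: combined sequence (normals first), n1: number of normal samples.
# Returns per-candidate signed statistics D(r) for r = 1..n-2 (tails of
# length m = n - r >= min_tail), using a two-sided sup deviation between
# the tail ECDF and the reference grid: the positive side compares the
# right-continuous ECDF value F(q_j) with y_j, the negative side the left
# limit F(q_j-) (strict inequality). Taking both sides is what makes the
# statistic an honest sup distance between step functions and exactly
# antisymmetric under negation of the data.
npcps_profile <- function(z, n1, grid_size = 100L, min_tail = 2L) {
  n <- length(z)
  ref <- reference_distribution(z[seq_len(n1)], grid_size)
  q <- ref$quantiles
  ygrid <- ref$grid
  g <- length(ygrid)

  r_all <- seq_len(n - min_tail)
  m <- n - r_all

  # Tail counts: for each grid quantile, the number of tail values <= q
  # (and < q), computed as column cumulative sums from the bottom row.
  ind <- cbind(outer(z, q, "<="), outer(z, q, "<"))
  csum <- .lower_tri_cumsum(ind)
  totals <- csum[n, ]
  tail_counts <- matrix(totals, nrow = length(r_all), ncol = 2L * g, byrow = TRUE) -
    csum[r_all, , drop = FALSE]

  f_le <- tail_counts[, seq_len(g), drop = FALSE] / m
  f_lt <- tail_counts[, g + seq_len(g), drop = FALSE] / m
  ymat <- matrix(ygrid, nrow = length(r_all), ncol = g, byrow = TRUE)

  dev_pos <- f_le - ymat  # F(q_j) - y_j
  dev_neg <- ymat - f_lt  # y_j - F(q_j-)
  j_pos <- max.col(dev_pos, ties.method = "first")
  j_neg <- max.col(dev_neg, ties.method = "first")
  d_pos <- dev_pos[cbind(seq_along(r_all), j_pos)]
  d_neg <- dev_neg[cbind(seq_along(r_all), j_neg)]
  # Signed sup deviation; an exact tie between the two sides resolves to
  # the positive (under-expression) side.
  delta <- ifelse(d_pos >= d_neg, d_pos, -d_neg)

  list(r = r_all, m = m, D = sqrt(m) * delta, reference = ref)
}

# Row-wise cumulative sums of a logical/numeric matrix via a cached
# lower-triangular multiply; one BLAS call beats G column cumsums.
.lower_tri_cumsum <- local({
  cache <- new.env(parent = emptyenv())
  function(x) {
    n <- nrow(x)
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      l <- matrix(0, n, n)
      l[lower.tri(l, diag = TRUE)] <- 1
      cache[[key]] <- l
    }
    cache[[key]] %*% x
  }
})

#' Change-point test for a single gene
#'
#' Scans every candidate change-point position `r` in the combined
#' sequence (normal samples first, cancer samples appended) and computes
#' the signed modified Kolmogorov statistic
#' `D(r) = sqrt(m) * Delta(r)`, where `m = n - r` is the tail length and
#' `Delta(r)` is the signed sup deviation between the empirical CDF of
#' the tail segment and the normal-group reference distribution
#' evaluated on the fixed probability grid. The reported statistic is
#' `D_n = D(r*)` at `r* = argmax |D(r)|` (ties resolved to the smallest
#' `r`); the change-point fraction is `tau_hat = r* / n`.
#'
#' A positive `D_n` (tail distribution above the reference, i.e. mass
#' shifted to smaller values) indicates under-expression; a negative
#' `D_n` indicates over-expression. The null hypothesis of no change
#' point is rejected when `|D_n|` exceeds the critical value.
#'
#' The statistic depends on the data only through relative order, so it
#' is invariant under strictly increasing transformations and needs no
#' prior normalisation.
#'
#' @param normal Expression values of the normal-group samples (n1 >= 2).
#' @param cancer Expression values of the cancer-group samples (n2 >= 2).
#' @param alpha Significance level (default 0.05).
#' @param critical Critical value `C(alpha)`; defaults to
#'   [kolmogorov_critical()] of `alpha`, i.e. 1.358 at 0.05 and 1.628
#'   at 0.01.
#' @param grid_size Number of probability grid levels (default 100).
#' @param min_tail Smallest admissible tail length (default 2);
#'   candidate positions with fewer than `min_tail` trailing samples are
#'   excluded.
#' @return Object of class `"npcps_test"`: a list with `statistic`
#'   (signed `D_n`), `change_point` (`r*`), `tau_hat`, `reject`,
#'   `direction` (`"over"`, `"under"` or `"none"`), `alpha`, `critical`,
#'   `n1`, `n2`, and `profile` (data frame of `r`, `m`, `D` over the
#'   scan range).
#' @examples
#' set.seed(1)
#' x <- rnorm(25)
#' y <- rnorm(25)
#' y[17:25] <- y[17:25] + 2  # last 9 cancer samples over-expressed
#' fit <- npcps_test(x, y, alpha = 0.01)
#' fit$statistic < 0  # over-expression
#' fit$tau_hat        # close to (50 - 9) / 50
#' @export
npcps_test <- function(normal, cancer, alpha = 0.05, critical = NULL,
                       grid_size = 100L, min_tail = 2L) {
  if (length(normal) < 2L || length(cancer) < 2L) {
    stop("npcps_test: both groups need at least 2 samples")
  }
  if (!all(is.finite(normal)) || !all(is.finite(cancer))) {
    stop("npcps_test: expression values must be finite")
  }
  if (alpha <= 0 || alpha >= 1) stop("npcps_test: alpha must lie in (0, 1)")
  if (is.null(critical)) critical <- kolmogorov_critical(alpha)
  if (critical <= 0) stop("npcps_test: critical value must be positive")

  n1 <- length(normal)
  n2 <- length(cancer)
  n <- n1 + n2
  prof <- npcps_profile(c(normal, cancer), n1, grid_size, min_tail)

  idx <- which.max(abs(prof$D))  # first index: smallest r on ties
  d_n <- prof$D[idx]
  r_star <- prof$r[idx]
  reject <- abs(d_n) > critical
  direction <- if (!reject) "none" else if (d_n > 0) "under" else "over"

  structure(
    list(
      statistic = d_n,
      change_point = r_star,
      tau_hat = r_star / n,
      reject = reject,
      direction = direction,
      alpha = alpha,
      critical = critical,
      grid_size = as.integer(grid_size),
      n1 = n1,
      n2 = n2,
      profile = data.frame(r = prof$r, m = prof$m, D = prof$D)
    ),
    class = "npcps_test"
  )
}

#' @export
print.npcps_test <- function(x, ...) {
  cat("Non-parametric change-point test\n")
  cat(sprintf("  n1 = %d normal, n2 = %d cancer samples\n", x$n1, x$n2))
  cat(sprintf("  D_n = %.4f  (critical %.3f at alpha = %g)\n",
              x$statistic, x$critical, x$alpha))
  cat(sprintf("  change point r* = %d  (tau_hat = %.3f)\n",
              x$change_point, x$tau_hat))
  cat(sprintf("  %s\n", if (x$reject) {
    paste0("reject: ", x$direction, "-expression")
  } else {
    "no change point detected"
  }))
  invisible(x)
}

#' True change-point fraction of a simulated design
#'
#' For `n1` normal samples, `n2` cancer samples of which the last `k`
#' carry the expression shift, the change point sits at position
#' `n1 + n2 - k` of the combined sequence, i.e. at fraction
#' `(n1 + n2 - k) / (n1 + n2)`.
#'
#' @param n1,n2 Group sizes.
#' @param k Number of shifted cancer samples, `0 < k <= n2`.
#' @return The change-point fraction in `(0, 1)`.
#' @examples
#' true_change_fraction(25, 25, 9)   # 0.82
#' true_change_fraction(25, 25, 25)  # 0.50
#' @export
true_change_fraction <- function(n1, n2, k) {
  if (k <= 0 || k > n2) {
    stop("true_change_fraction: k must satisfy 0 < k <= n2")
  }
  (n1 + n2 - k) / (n1 + n2)
}

#' Change-point scan over an expression matrix
#'
#' Applies [npcps_test()] to every gene (row) of an expression matrix
#' and returns a ranked result table. Genes are ranked by descending
#' signed `D_n` (most-positive first, i.e. the strongest
#' under-expression candidates lead); rank ties are broken by gene id
#' so output files are byte-stable.
#'
#' @param x Numeric matrix, genes in rows, samples in columns. Row
#'   names are used as gene ids (generated as `gene_1..gene_g` when
#'   absent).
#' @param normal,cancer Column indices (or names) of the normal and
#'   cancer samples.
#' @param alpha,critical,grid_size,min_tail Passed to [npcps_test()].
#' @param sort_cancer If `TRUE`, cancer columns of each gene are sorted
#'   by intensity before the scan (the arrangement used by the
#'   likelihood-ratio scan); default `FALSE`, columns are used in the
#'   given order.
#' @return A data frame with columns `gene_id`, `rank`, `D_n`,
#'   `cp_index`, `cp_fraction`, `direction`, `reject`, ordered by rank.
#'   Genes containing missing values are skipped with a warning and
#'   reported in the `skipped` attribute; the `summary` attribute holds
#'   the counts of positive/negative statistics and rejections together
#'   with the run configuration.
#' @examples
#' sim <- simulate_matrix(genes = 20, n1 = 10, n2 = 10, k = 5, mu = 3, seed = 1)
#' res <- npcps_matrix(sim$x, sim$normal, sim$cancer, alpha = 0.01)
#' head(res)
#' @export
npcps_matrix <- function(x, normal, cancer, alpha = 0.05, critical = NULL,
                         grid_size = 100L, min_tail = 2L, sort_cancer = FALSE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("gene_", seq_len(nrow(x)))
  }
  if (is.character(normal)) normal <- match(normal, colnames(x))
  if (is.character(cancer)) cancer <- match(cancer, colnames(x))
  if (anyNA(normal) || anyNA(cancer)) {
    stop("npcps_matrix: unknown sample columns in group assignment")
  }
  if (length(intersect(normal, cancer)) > 0L) {
    stop("npcps_matrix: a sample cannot be in both groups")
  }
  if (is.null(critical)) critical <- kolmogorov_critical(alpha)

  ids <- rownames(x)
  skipped <- character(0)
  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    xn <- x[i, normal]
    xc <- x[i, cancer]
    if (anyNA(xn) || anyNA(xc)) {
      skipped <- c(skipped, ids[i])
      next
    }
    if (sort_cancer) xc <- sort(xc)
    fit <- npcps_test(xn, xc, alpha = alpha, critical = critical,
                      grid_size = grid_size, min_tail = min_tail)
    rows[[i]] <- data.frame(
      gene_id = ids[i],
      D_n = fit$statistic,
      cp_index = fit$change_point,
      cp_fraction = fit$tau_hat,
      direction = fit$direction,
      reject = fit$reject,
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped) > 0L) {
    warning(sprintf("npcps_matrix: skipped %d gene(s) with missing values: %s",
                    length(skipped), paste(utils::head(skipped, 5), collapse = ", ")))
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L) {
    stop("npcps_matrix: no gene with complete data")
  }
  ord <- order(-res$D_n, res$gene_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res <- res[, c("gene_id", "rank", "D_n", "cp_index", "cp_fraction",
                 "direction", "reject")]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "summary") <- list(
    n1 = length(normal), n2 = length(cancer),
    alpha = alpha, critical = critical, grid_size = as.integer(grid_size),
    genes = nrow(res), skipped = length(skipped),
    positive = sum(res$D_n > 0), negative = sum(res$D_n < 0),
    rejected = sum(res$reject)
  )
  res
}
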