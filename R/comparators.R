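# Seven comparison statistics for cancer-outlier differential expression.
# All percentile computations in this file use linear interpolation
# between order statistics (stats::quantile type 7), the single
# convention fixed package-wide.

.pctl <- function(v, p) {
  unname(stats::quantile(v, p / 100, type = 7, names = FALSE))
}

.mad_about <- function(v, center) {
  1.4826 * stats::median(abs(v - center))
}

#' Pooled two-sample t statistic
#'
#' Classical two-sample t with pooled standard deviation, oriented so
#' that over-expression of the cancer group is positive:
#' `(mean(cancer) - mean(normal)) / (s_p * sqrt(1/n1 + 1/n2))`.
#'
#' @param normal,cancer Expression values of the two groups (each of
#'   length >= 2).
#' @return The t statistic, or `NA` (with a warning) when the pooled
#'   variance is zero.
#' @examples
#' stat_t(c(1, 2, 3), c(4, 5, 6))  # 3.674
#' @export
stat_t <- function(normal, cancer) {
  n1 <- length(normal)
  n2 <- length(cancer)
  if (n1 < 2L || n2 < 2L) stop("stat_t: both groups need at least 2 samples")
  sp2 <- ((n1 - 1) * stats::var(normal) + (n2 - 1) * stats::var(cancer)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) {
    warning("stat_t: zero pooled variance, statistic undefined")
    return(NA_real_)
  }
  (mean(cancer) - mean(normal)) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
}

#' COPA cancer-outlier statistic
#'
#' Centres all values of the gene at the overall median, scales by the
#' median absolute deviation about it (scaled by 1.4826), and returns a
#' high percentile of the standardized cancer-group values. The
#' percentile is user-selectable; 90 is the package default.
#'
#' @param normal,cancer Expression values of the two groups.
#' @param pct Percentile in `(50, 100)`, default 90.
#' @param mode `"over"` scores over-expression; `"under"` mirrors the
#'   computation on negated values.
#' @return The COPA statistic, or `NA` (with a warning) when the MAD is
#'   zero.
#' @export
stat_copa <- function(normal, cancer, pct = 90, mode = c("over", "under")) {
  mode <- match.arg(mode)
  if (pct <= 50 || pct >= 100) stop("stat_copa: pct must lie in (50, 100)")
  if (mode == "under") return(stat_copa(-normal, -cancer, pct, "over"))
  v <- c(normal, cancer)
  med <- stats::median(v)
  s <- .mad_about(v, med)
  if (s <= 0) {
    warning("stat_copa: zero MAD, statistic undefined")
    return(NA_real_)
  }
  .pctl((cancer - med) / s, pct)
}

#' Outlier-sum (OS) statistic
#'
#' Standardizes all values of the gene by the overall median and MAD,
#' then sums the standardized cancer values lying beyond the quartile
#' fence: above `Q3 + IQR` in over mode, below `Q1 - IQR` in under mode
#' (quartiles and IQR of the standardized values of all samples). An
#' empty outlier set gives 0.
#'
#' @inheritParams stat_copa
#' @return The outlier sum (negative in under mode), `NA` when the MAD
#'   is zero.
#' @export
stat_os <- function(normal, cancer, mode = c("over", "under")) {
  mode <- match.arg(mode)
  if (mode == "under") return(-stat_os(-normal, -cancer, "over"))
  v <- c(normal, cancer)
  if (length(v) < 4L) stop("stat_os: need at least 4 samples for quartiles")
  med <- stats::median(v)
  s <- .mad_about(v, med)
  if (s <= 0) {
    warning("stat_os: zero MAD, statistic undefined")
    return(NA_real_)
  }
  z <- (v - med) / s
  zc <- (cancer - med) / s
  q3 <- .pctl(z, 75)
  q1 <- .pctl(z, 25)
  fence <- q3 + (q3 - q1)
  out <- zc[zc > fence]
  if (length(out) == 0L) 0 else sum(out)
}

#' Outlier-robust t (ORT) statistic
#'
#' Variant of the outlier sum centred on the normal-group median, with
#' a robust scale pooled over both groups: the MAD (scaled by 1.4826)
#' of the absolute deviations of each group about its own median. The
#' outlier set is defined relative to the quartile fence of the
#' normal-group values: cancer values above `Q3(normal) + IQR(normal)`
#' in over mode.
#'
#' @inheritParams stat_copa
#' @return Sum of `(value - median(normal)) / mad` over outlying cancer
#'   values (sign mirrored in under mode); 0 when the outlier set is
#'   empty, `NA` when the scale estimate is zero.
#' @export
stat_ort <- function(normal, cancer, mode = c("over", "under")) {
  mode <- match.arg(mode)
  if (mode == "under") return(-stat_ort(-normal, -cancer, "over"))
  if (length(normal) < 4L) stop("stat_ort: need at least 4 normal samples for quartiles")
  med_x <- stats::median(normal)
  med_y <- stats::median(cancer)
  s <- 1.4826 * stats::median(c(abs(normal - med_x), abs(cancer - med_y)))
  if (s <= 0) {
    warning("stat_ort: zero robust scale, statistic undefined")
    return(NA_real_)
  }
  q3 <- .pctl(normal, 75)
  q1 <- .pctl(normal, 25)
  fence <- q3 + (q3 - q1)
  out <- cancer[cancer > fence]
  if (length(out) == 0L) 0 else sum((out - med_x) / s)
}

# Cache of null order-statistic moments, keyed by "n2.reps.seed".
.most_cache <- new.env(parent = emptyenv())

#' Null order-statistic moments for the MOST statistic
#'
#' Monte Carlo estimates, under the standard normal null, of the mean
#' and standard deviation of the cumulative sums of the decreasingly
#' sorted values of a sample of size `n2`: `mu_k = E[sum of top k]`,
#' `sigma_k = sd[sum of top k]`, `k = 1..n2`. Computed once per group
#' size with a fixed internal seed (independent of the caller's RNG
#' state, which is preserved) and cached for the session.
#'
#' @param n2 Cancer-group size.
#' @param reps Monte Carlo replicates (default 1e5).
#' @param seed Internal seed for the replicates.
#' @return List with numeric vectors `mu` and `sigma` of length `n2`.
#' @export
most_null_moments <- function(n2, reps = 1e5, seed = 20110531) {
  key <- paste(n2, reps, seed, sep = ".")
  if (!is.null(.most_cache[[key]])) return(.most_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  z <- matrix(stats::rnorm(reps * n2), nrow = n2, ncol = reps)
  # sort each column decreasingly with one radix pass
  o <- order(rep(seq_len(reps), each = n2), -as.vector(z), method = "radix")
  zs <- matrix(as.vector(z)[o], nrow = n2, ncol = reps)
  for (i in seq_len(n2)[-1]) zs[i, ] <- zs[i - 1L, ] + zs[i, ]
  mu <- rowMeans(zs)
  sigma <- sqrt(rowSums((zs - mu)^2) / (reps - 1))
  .most_cache[[key]] <- list(mu = mu, sigma = sigma)
  .most_cache[[key]]
}

#' Maximum ordered-subset t (MOST) statistic
#'
#' Centres the cancer values at the normal-group median, scales by the
#' pooled robust MAD (as in [stat_ort()]), sorts them decreasingly and
#' forms the cumulative sum over the top `k` values for every
#' `k = 1..n2`. Each cumulative sum is standardized by the null moments
#' `mu_k`, `sigma_k` of [most_null_moments()]; the statistic is the
#' maximum standardized value over `k`.
#'
#' @inheritParams stat_copa
#' @param moments Optional precomputed [most_null_moments()] list.
#' @return The MOST statistic, `NA` when the robust scale is zero.
#' @export
stat_most <- function(normal, cancer, mode = c("over", "under"), moments = NULL) {
  mode <- match.arg(mode)
  if (mode == "under") return(stat_most(-normal, -cancer, "over", moments))
  med_x <- stats::median(normal)
  med_y <- stats::median(cancer)
  s <- 1.4826 * stats::median(c(abs(normal - med_x), abs(cancer - med_y)))
  if (s <= 0) {
    warning("stat_most: zero robust scale, statistic undefined")
    return(NA_real_)
  }
  z <- sort((cancer - med_x) / s, decreasing = TRUE)
  cs <- cumsum(z)
  if (is.null(moments)) moments <- most_null_moments(length(cancer))
  max((cs - moments$mu) / moments$sigma)
}

#' Percentile separability (PPST) statistic
#'
#' Count-based score of how separable the two groups are at a high
#' percentile boundary: in over mode, the number of cancer samples
#' above the `pct`-th percentile of the normal group plus the number of
#' normal samples below the `(100 - pct)`-th percentile of the cancer
#' group. Under mode mirrors the computation.
#'
#' @inheritParams stat_copa
#' @param pct Boundary percentile, default 95.
#' @return Integer-valued score.
#' @export
stat_ppst <- function(normal, cancer, pct = 95, mode = c("over", "under")) {
  mode <- match.arg(mode)
  if (mode == "under") return(stat_ppst(-normal, -cancer, pct, "over"))
  if (length(normal) == 0L || length(cancer) == 0L) {
    stop("stat_ppst: both groups must be non-empty")
  }
  sum(cancer > .pctl(normal, pct)) + sum(normal < .pctl(cancer, 100 - pct))
}

#' Likelihood-ratio scan (LRS) statistic
#'
#' Arranges the samples with the normal group first and the cancer
#' group sorted ascending, then scans candidate outlier segments formed
#' by the top `j` cancer samples (`j = 1..n2-1`). For each segment the
#' statistic compares a one-mean Gaussian model with a two-mean model
#' (background vs segment, common variance):
#' `LR(j) = n * log(SS_total / (SS_background + SS_segment))`, with a
#' variance floor of `1e-8` on the pooled sums of squares. The
#' statistic is the maximum over segments. Under mode applies the same
#' scan to the negated data.
#'
#' @inheritParams stat_copa
#' @return The maximal log likelihood ratio (non-negative).
#' @export
stat_lrs <- function(normal, cancer, mode = c("over", "under")) {
  mode <- match.arg(mode)
  if (mode == "under") return(stat_lrs(-normal, -cancer, "over"))
  n2 <- length(cancer)
  if (n2 < 2L) stop("stat_lrs: need at least 2 cancer samples")
  s <- c(normal, sort(cancer))
  n <- length(s)
  p1 <- cumsum(s)
  p2 <- cumsum(s^2)
  ss_total <- p2[n] - p1[n]^2 / n
  cuts <- (n - n2 + 1L):(n - 1L)  # background keeps all normals + >=1 cancer
  ss_bg <- p2[cuts] - p1[cuts]^2 / cuts
  top_n <- n - cuts
  ss_top <- (p2[n] - p2[cuts]) - (p1[n] - p1[cuts])^2 / top_n
  max(n * log(pmax(ss_total, 1e-8) / pmax(ss_bg + ss_top, 1e-8)))
}

#' Natural-log initialization of an expression matrix
#'
#' Transforms strictly positive raw intensities to the natural-log
#' scale, the initialization applied before the comparison statistics
#' (the change-point statistic is rank-invariant and is applied to the
#' raw values).
#'
#' @param x Numeric vector or matrix of strictly positive values.
#' @return Object of the same shape with `log(x)` values.
#' @examples
#' log_initialize(34)     # 3.526
#' log_initialize(43053)  # 10.670
#' @export
log_initialize <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("log_initialize: values must be finite and strictly positive")
  }
  log(x)
}

#' Comparison statistics over an expression matrix
#'
#' Computes a chosen set of the seven comparison statistics for every
#' gene (row) of an expression matrix, together with per-method ranks
#' (descending statistic, rank ties broken by gene id). `NA` statistics
#' (zero-variance genes) rank last.
#'
#' @inheritParams npcps_matrix
#' @param methods Character vector out of
#'   `c("T", "COPA", "OS", "ORT", "MOST", "PPST", "LRS")`.
#' @param mode Scoring direction passed to the directional statistics.
#' @param copa_pct,ppst_pct Percentile parameters.
#' @return Data frame with `gene_id`, one statistic column per method
#'   and one `<method>_rank` column per method.
#' @export
comparator_matrix <- function(x, normal, cancer,
                              methods = c("T", "COPA", "OS", "ORT", "MOST",
                                          "PPST", "LRS"),
                              mode = c("over", "under"),
                              copa_pct = 90, ppst_pct = 95) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, several.ok = TRUE)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("gene_", seq_len(nrow(x)))
  if (is.character(normal)) normal <- match(normal, colnames(x))
  if (is.character(cancer)) cancer <- match(cancer, colnames(x))

  moments <- if ("MOST" %in% methods) most_null_moments(length(cancer)) else NULL
  fns <- list(
    T = function(xn, xc) stat_t(xn, xc),
    COPA = function(xn, xc) stat_copa(xn, xc, pct = copa_pct, mode = mode),
    OS = function(xn, xc) stat_os(xn, xc, mode = mode),
    ORT = function(xn, xc) stat_ort(xn, xc, mode = mode),
    MOST = function(xn, xc) stat_most(xn, xc, mode = mode, moments = moments),
    PPST = function(xn, xc) stat_ppst(xn, xc, pct = ppst_pct, mode = mode),
    LRS = function(xn, xc) stat_lrs(xn, xc, mode = mode)
  )

  out <- data.frame(gene_id = rownames(x), stringsAsFactors = FALSE)
  for (mth in methods) {
    stats_m <- vapply(seq_len(nrow(x)), function(i) {
      fns[[mth]](x[i, normal], x[i, cancer])
    }, numeric(1))
    ord <- order(-stats_m, out$gene_id, na.last = TRUE)
    rk <- integer(length(stats_m))
    rk[ord] <- seq_along(ord)
    out[[mth]] <- stats_m
    out[[paste0(mth, "_rank")]] <- rk
  }
  out
}

#' Pairwise correlation of gene rankings
#'
#' Pearson correlation between per-method rank vectors (equivalent to
#' the Spearman correlation of the statistics in the absence of rank
#' ties).
#'
#' @param ranks Data frame or matrix whose columns are rank vectors
#'   (permutations of `1..g`), one per method.
#' @return Symmetric correlation matrix.
#' @export
rank_correlations <- function(ranks) {
  stats::cor(as.matrix(ranks))
}
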