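# Synthetic expression data with the Monte Carlo structure used to
# validate the change-point statistic: i.i.d. per-gene draws from a
# standard normal (or standardized skew-normal) base, with a constant
# effect mu added to the last k cancer samples of each DGE gene.

#' Skew-normal random draws
#'
#' Samples from the skew-normal law with location 0, scale 1 and the
#' given shape, via the mixing representation
#' `delta * |Z1| + sqrt(1 - delta^2) * Z2` with
#' `delta = shape / sqrt(1 + shape^2)` and independent standard normal
#' `Z1`, `Z2`. Shape 0 recovers the standard normal; the sign of the
#' shape flips the skewness.
#'
#' @param n Number of draws.
#' @param shape Skewness (slant) parameter, finite.
#' @return Numeric vector of draws.
#' @export
rskewnorm <- function(n, shape = 0) {
  if (!is.finite(shape)) stop("rskewnorm: shape must be finite")
  delta <- shape / sqrt(1 + shape^2)
  delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
}

.base_draw <- function(n, base, shape) {
  switch(base,
    normal = stats::rnorm(n),
    skew_normal = rskewnorm(n, shape),
    stop("unknown base distribution: ", base)
  )
}

#' Simulate one gene
#'
#' Draws `n1` normal-group and `n2` cancer-group values from the base
#' distribution and adds the constant `mu` to the last `k` cancer
#' samples, so the true change point of the combined sequence sits at
#' position `n1 + n2 - k` (fraction [true_change_fraction()]).
#'
#' @param n1,n2 Group sizes.
#' @param k Number of shifted cancer samples, `0 <= k <= n2` (0 gives a
#'   null gene).
#' @param mu Effect size added to the shifted samples.
#' @param base `"normal"` or `"skew_normal"`.
#' @param shape Skew-normal shape (ignored for the normal base).
#' @return List with numeric vectors `normal` and `cancer`.
#' @export
simulate_gene <- function(n1, n2, k, mu, base = c("normal", "skew_normal"),
                          shape = 5) {
  base <- match.arg(base)
  if (k < 0 || k > n2) stop("simulate_gene: k must satisfy 0 <= k <= n2")
  xn <- .base_draw(n1, base, shape)
  xc <- .base_draw(n2, base, shape)
  if (k > 0) {
    idx <- (n2 - k + 1L):n2
    xc[idx] <- xc[idx] + mu
  }
  list(normal = xn, cancer = xc)
}

#' Simulate a labelled expression matrix
#'
#' Generates `genes` independent genes with the two-group design of
#' [simulate_gene()]. The first `round(genes * dge_fraction)` genes
#' carry the effect (`dge_fraction = 1`, the default, reproduces the
#' all-DGE design of the miss-rate and change-point-recovery
#' experiments; smaller fractions give the labelled null/DGE mixtures
#' of the ROC experiments).
#'
#' Each gene is drawn from its own deterministic substream derived from
#' `seed`, so the same seed yields bit-identical matrices and changing
#' the gene count does not reshuffle earlier genes.
#'
#' @inheritParams simulate_gene
#' @param genes Number of genes (rows).
#' @param dge_fraction Fraction of genes carrying the effect.
#' @param seed Integer seed; `NULL` leaves the caller's RNG state in
#'   charge (and makes per-gene substreams sequential).
#' @return List with `x` (genes x (n1+n2) matrix with gene/sample
#'   dimnames), `normal` and `cancer` (column index vectors), and
#'   `truth` (data frame: `gene_id`, `dge`, `k`, `mu`,
#'   `change_fraction`).
#' @examples
#' sim <- simulate_matrix(genes = 100, n1 = 25, n2 = 25, k = 9, mu = 2,
#'                        dge_fraction = 0.5, seed = 1)
#' table(sim$truth$dge)
#' @export
simulate_matrix <- function(genes, n1, n2, k, mu,
                            base = c("normal", "skew_normal"), shape = 5,
                            dge_fraction = 1, seed = NULL) {
  base <- match.arg(base)
  if (genes < 1) stop("simulate_matrix: need at least one gene")
  if (dge_fraction < 0 || dge_fraction > 1) {
    stop("simulate_matrix: dge_fraction must lie in [0, 1]")
  }
  n_dge <- round(genes * dge_fraction)
  x <- matrix(NA_real_, nrow = genes, ncol = n1 + n2)
  for (g in seq_len(genes)) {
    if (!is.null(seed)) set.seed(.gene_seed(seed, g))
    gene <- simulate_gene(n1, n2, if (g <= n_dge) k else 0L, mu, base, shape)
    x[g, ] <- c(gene$normal, gene$cancer)
  }
  rownames(x) <- sprintf("gene_%04d", seq_len(genes))
  colnames(x) <- c(paste0("normal_", seq_len(n1)), paste0("cancer_", seq_len(n2)))
  is_dge <- seq_len(genes) <= n_dge
  truth <- data.frame(
    gene_id = rownames(x),
    dge = is_dge,
    k = ifelse(is_dge, k, 0L),
    mu = ifelse(is_dge, mu, 0),
    change_fraction = ifelse(is_dge & k > 0,
                             (n1 + n2 - k) / (n1 + n2), NA_real_),
    stringsAsFactors = FALSE
  )
  list(x = x, normal = seq_len(n1), cancer = n1 + seq_len(n2), truth = truth)
}

# Deterministic per-gene substream seed below 2^31.
.gene_seed <- function(seed, g) {
  as.integer(((as.numeric(seed) %% 1e6) * 2039 + as.numeric(g) * 48271) %% 2147483647)
}
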