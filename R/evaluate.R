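# Evaluation harness: AUC/ROC of gene rankings, the miss-rate and
# change-point recovery tables of the all-DGE Monte Carlo design, and
# the direction-symmetry experiment.

#' Area under the ROC curve of a gene ranking
#'
#' Probability that a randomly chosen DGE-gene score exceeds a randomly
#' chosen null-gene score, ties counted one half (the Mann-Whitney pair
#' statistic). Identical to the trapezoidal area under the empirical
#' ROC curve of the ranking.
#'
#' @param null_scores Scores of the null genes (larger = more DGE-like).
#' @param dge_scores Scores of the DGE genes.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_scores(c(1, 2, 3), c(4, 5, 6))  # 1
#' auc_scores(c(1, 3), c(2, 4))        # 0.75
#' @export
auc_scores <- function(null_scores, dge_scores) {
  n0 <- length(null_scores)
  n1 <- length(dge_scores)
  if (n0 == 0L || n1 == 0L) stop("auc_scores: both score vectors must be non-empty")
  r <- rank(c(null_scores, dge_scores))  # average ranks handle ties as 1/2
  (sum(r[n0 + seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Empirical ROC curve of a gene ranking
#'
#' @inheritParams auc_scores
#' @return Data frame of `fpr` and `tpr`, monotone non-decreasing from
#'   (0, 0) to (1, 1), one point per distinct score threshold.
#' @export
roc_curve <- function(null_scores, dge_scores) {
  if (length(null_scores) == 0L || length(dge_scores) == 0L) {
    stop("roc_curve: both score vectors must be non-empty")
  }
  thr <- sort(unique(c(null_scores, dge_scores)), decreasing = TRUE)
  fpr <- vapply(thr, function(t) mean(null_scores >= t), numeric(1))
  tpr <- vapply(thr, function(t) mean(dge_scores >= t), numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

# Over-expression-oriented scores of every gene of a matrix under one
# method. The change-point statistic is scored by its magnitude |D_n|
# (its sign only encodes direction, and the same ranking serves both
# over- and under-expression); "npcps_signed" gives the signed
# orientation -D_n for comparison.
.method_scores <- function(x, normal, cancer, method,
                           mode = "over", alpha = 0.01,
                           grid_size = 100L, copa_pct = 90, ppst_pct = 95,
                           moments = NULL) {
  g <- nrow(x)
  if (method %in% c("NPCPS", "npcps", "npcps_signed")) {
    sc <- vapply(seq_len(g), function(i) {
      npcps_test(x[i, normal], x[i, cancer], alpha = alpha,
                 grid_size = grid_size)$statistic
    }, numeric(1))
    if (method == "npcps_signed") {
      return(if (mode == "over") -sc else sc)
    }
    return(abs(sc))
  }
  fn <- switch(method,
    T = function(xn, xc) {
      s <- stat_t(xn, xc)
      if (mode == "over") s else -s
    },
    COPA = function(xn, xc) stat_copa(xn, xc, pct = copa_pct, mode = mode),
    OS = function(xn, xc) {
      s <- stat_os(xn, xc, mode = mode)
      if (mode == "over") s else -s
    },
    ORT = function(xn, xc) {
      s <- stat_ort(xn, xc, mode = mode)
      if (mode == "over") s else -s
    },
    MOST = function(xn, xc) stat_most(xn, xc, mode = mode, moments = moments),
    PPST = function(xn, xc) stat_ppst(xn, xc, pct = ppst_pct, mode = mode),
    LRS = function(xn, xc) stat_lrs(xn, xc, mode = mode),
    stop("unknown method: ", method)
  )
  vapply(seq_len(g), function(i) fn(x[i, normal], x[i, cancer]), numeric(1))
}

#' ROC/AUC grid over simulation scenarios
#'
#' For each scenario (a row of `scenarios`), simulates a labelled
#' mixture of null genes and DGE genes, scores every gene with every
#' requested method in over-expression orientation, and records the
#' Mann-Whitney AUC of DGE-vs-null scores.
#'
#' @param scenarios Data frame with columns `n1`, `n2`, `mu`, `k` and
#'   optionally `base` (default `"normal"`) and `shape`.
#' @param methods Methods to score; `"NPCPS"` plus any of the seven
#'   comparison statistics.
#' @param genes_per_class Null genes and DGE genes per scenario
#'   (default 1000 each).
#' @param alpha Significance level for the change-point test (does not
#'   affect its ranking).
#' @param seed Root seed; scenario `i` uses substream `seed + i`.
#' @return Data frame: scenario columns plus `method` and `auc`.
#' @export
roc_grid <- function(scenarios,
                     methods = c("NPCPS", "LRS", "COPA", "OS", "ORT",
                                 "PPST", "T", "MOST"),
                     genes_per_class = 1000, alpha = 0.01, seed = 1) {
  out <- list()
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    base <- if ("base" %in% names(sc)) as.character(sc$base) else "normal"
    shape <- if ("shape" %in% names(sc)) sc$shape else 5
    sim <- simulate_matrix(
      genes = 2 * genes_per_class, n1 = sc$n1, n2 = sc$n2, k = sc$k,
      mu = sc$mu, base = base, shape = shape, dge_fraction = 0.5,
      seed = seed + i
    )
    is_dge <- sim$truth$dge
    moments <- if ("MOST" %in% methods) most_null_moments(sc$n2) else NULL
    for (mth in methods) {
      scores <- .method_scores(sim$x, sim$normal, sim$cancer, mth,
                               alpha = alpha, moments = moments)
      out[[length(out) + 1L]] <- data.frame(
        n1 = sc$n1, n2 = sc$n2, mu = sc$mu, k = sc$k, base = base,
        method = mth,
        auc = auc_scores(scores[!is_dge], scores[is_dge])
      )
    }
  }
  do.call(rbind, out)
}

#' Miss-rate and change-point recovery table
#'
#' Reproduces the all-DGE Monte Carlo design: for each `k`, simulates
#' `genes` genes that all carry the effect `mu` on their last `k`
#' cancer samples, runs the change-point test on each, and reports the
#' true change fraction, the mean estimated fraction `tau_hat`
#' (averaged over all genes), the non-rejection (miss) rate and the
#' rejection rate. The miss rate on all-DGE genes is the quantity the
#' original study tabulates against `k`; the rejection rate on matched
#' null genes is a different quantity (see the package vignette).
#'
#' @param k_values Vector of DGE subset sizes.
#' @param n1,n2 Group sizes.
#' @param mu Effect size.
#' @param genes Genes per `k` (default 7000).
#' @param alpha Significance level of the test (default 0.01).
#' @param seed Root seed; `k_values[i]` uses substream `seed + i`.
#' @return Data frame: `k`, `actual`, `mean_tau_hat`, `miss_rate`,
#'   `reject_rate`.
#' @export
recovery_table <- function(k_values, n1 = 25, n2 = 25, mu = 2,
                           genes = 7000, alpha = 0.01, seed = 1) {
  critical <- kolmogorov_critical(alpha)
  rows <- lapply(seq_along(k_values), function(i) {
    k <- k_values[i]
    sim <- simulate_matrix(genes = genes, n1 = n1, n2 = n2, k = k, mu = mu,
                           seed = seed + i)
    fits <- vapply(seq_len(genes), function(g) {
      fit <- npcps_test(sim$x[g, sim$normal], sim$x[g, sim$cancer],
                        alpha = alpha, critical = critical)
      c(fit$tau_hat, fit$reject)
    }, numeric(2))
    data.frame(
      k = k,
      actual = true_change_fraction(n1, n2, k),
      mean_tau_hat = mean(fits[1, ]),
      miss_rate = mean(fits[2, ] == 0),
      reject_rate = mean(fits[2, ] == 1)
    )
  })
  do.call(rbind, rows)
}

#' Direction-symmetry experiment
#'
#' Applies each method's over-expression scoring to an over-expressed
#' simulation (`mu > 0`) and to the mirrored under-expressed simulation
#' (`-mu`), and records both AUCs. The change-point ranking uses
#' `|D_n|` and is symmetric by construction; the directional
#' comparators degrade to chance (or below) on the mirrored data.
#'
#' @param n1,n2 Group sizes.
#' @param k Number of shifted cancer samples.
#' @param mu Positive effect size; the mirrored run uses `-mu`.
#' @param methods Methods to score.
#' @param genes_per_class Null and DGE genes per run.
#' @param seed Root seed.
#' @return Data frame: `method`, `auc_over_data` (effect `+mu`),
#'   `auc_under_data` (effect `-mu`), both under over-expression
#'   scoring.
#' @export
direction_symmetry <- function(n1 = 25, n2 = 25, k = 8, mu = 2,
                               methods = c("NPCPS", "LRS", "COPA", "OS",
                                           "ORT", "PPST", "T", "MOST"),
                               genes_per_class = 1000, seed = 1) {
  run <- function(effect, offset) {
    sim <- simulate_matrix(genes = 2 * genes_per_class, n1 = n1, n2 = n2,
                           k = k, mu = effect, dge_fraction = 0.5,
                           seed = seed + offset)
    is_dge <- sim$truth$dge
    moments <- if ("MOST" %in% methods) most_null_moments(n2) else NULL
    vapply(methods, function(mth) {
      scores <- .method_scores(sim$x, sim$normal, sim$cancer, mth,
                               mode = "over", moments = moments)
      auc_scores(scores[!is_dge], scores[is_dge])
    }, numeric(1))
  }
  data.frame(
    method = methods,
    auc_over_data = run(mu, 1L),
    auc_under_data = run(-mu, 2L),
    row.names = NULL
  )
}
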