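# Correlation/error metric panel for estimated vs. reference abundances,
# inferential relative variance, and precision-recall over expressed
# transcripts.

# Lin's concordance correlation coefficient on moment (1/n) estimators.
.ccc <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(NA_real_)
  2 * sxy / den
}

.safe_cor <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

#' Metric panel comparing estimated and reference abundances
#'
#' Computes rank correlations (Spearman with average ranks, Kendall tau-b) on
#' the raw values, Pearson and concordance (CCC) correlations on
#' `log(1 + x)`-transformed values, and three error metrics:
#' `rmse = sqrt(mean((x - y)^2))`, `nrmse = rmse / mean(truth)`, and
#' `mard = mean(|x - y| / (x + y))` with the absolute relative difference
#' taken as 0 when both values are 0 (so MARD is bounded in \[0, 1\]).
#' Zero-variance inputs make a correlation undefined; it is reported as `NA`.
#'
#' @param estimated,truth Equal-length numeric vectors of per-transcript
#'   abundances (length >= 2).
#' @param log_transform_linear Compute Pearson/CCC on the `log(1 + x)` scale
#'   (default TRUE); set FALSE for raw-scale variants.
#' @return A one-row tibble: `spearman`, `pearson_log1p`, `ccc`, `kendall`,
#'   `rmse`, `nrmse`, `mard`, `n`.
#' @export
compute_metrics <- function(estimated, truth, log_transform_linear = TRUE) {
  if (length(estimated) != length(truth)) {
    rlang::abort("estimated and truth must have equal length")
  }
  if (length(truth) < 2) {
    rlang::abort("at least two transcripts are required")
  }
  lx <- if (log_transform_linear) log1p(estimated) else estimated
  ly <- if (log_transform_linear) log1p(truth) else truth
  d <- estimated - truth
  s <- estimated + truth
  ard <- ifelse(s == 0, 0, abs(d) / s)
  rmse <- sqrt(mean(d^2))
  tibble::tibble(
    spearman = .safe_cor(estimated, truth, "spearman"),
    pearson_log1p = .safe_cor(lx, ly, "pearson"),
    ccc = .ccc(lx, ly),
    kendall = .safe_cor(estimated, truth, "kendall"),
    rmse = rmse,
    nrmse = if (mean(truth) == 0) NA_real_ else rmse / mean(truth),
    mard = mean(ard),
    n = length(truth)
  )
}

#' Inferential relative variance
#'
#' Uncertainty of an abundance estimate across inferential replicates (e.g.
#' Gibbs samples): `max(sigma2 - mu, 0) / (mu + 5) + 0.01`. The pseudocount
#' of 5 stabilises low-abundance transcripts and the additive 0.01 guarantees
#' positivity for log transformation, so the result is always >= 0.01.
#'
#' @param mu Mean abundance across replicates (>= 0, vectorised).
#' @param sigma2 Variance across replicates (>= 0, vectorised).
#' @return Numeric vector of InfRV values.
#' @examples
#' infrv(10, 10)   # variance equals mean: floor value 0.01
#' infrv(5, 25)
#' @export
infrv <- function(mu, sigma2) {
  if (any(mu < 0) || any(sigma2 < 0)) {
    rlang::abort("mu and sigma2 must be non-negative")
  }
  pmax(sigma2 - mu, 0) / (mu + 5) + 0.01
}

#' Precision-recall curve for expressed-transcript detection
#'
#' Treats expressed transcripts as positives and uses the estimated abundance
#' as the score: sweeping the threshold down over the distinct scores yields
#' the precision-recall curve. The area under the curve is computed by
#' trapezoidal integration over recall, and average precision as
#' `sum((R_k - R_(k-1)) * P_k)` over the sweep.
#'
#' @param estimated Numeric score vector (estimated abundances).
#' @param expressed Logical vector: is the transcript truly expressed? Must
#'   contain at least one positive and one negative.
#' @return A list with `curve` (tibble `threshold`, `tp`, `fp`, `precision`,
#'   `recall`), `auc_pr`, and `average_precision`.
#' @export
precision_recall <- function(estimated, expressed) {
  stopifnot(length(estimated) == length(expressed))
  expressed <- as.logical(expressed)
  n_pos <- sum(expressed)
  if (n_pos == 0 || n_pos == length(expressed)) {
    rlang::abort("both expressed and unexpressed transcripts are required")
  }
  ord <- order(estimated, decreasing = TRUE)
  sc <- estimated[ord]
  lab <- expressed[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  # collapse ties: one operating point per distinct threshold
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[last]
  fp <- fp[last]
  curve <- tibble::tibble(
    threshold = sc[last],
    tp = tp,
    fp = fp,
    precision = tp / (tp + fp),
    recall = tp / n_pos
  )
  r <- c(0, curve$recall)
  p <- curve$precision
  ap <- sum(diff(r) * p)
  auc <- sum(diff(r) * (p + c(p[1], p[-length(p)])) / 2)
  list(curve = curve, auc_pr = auc, average_precision = ap)
}

#' Evaluate a quantification against a reference, by transcript name
#'
#' Inner-joins the estimate and reference tables on `tname` (a message reports
#' unmatched names) and computes the full metric panel plus, when both
#' expressed and unexpressed transcripts are present, the precision-recall
#' summaries with `truth > 0` as the positive label.
#'
#' @param estimated A data frame with columns `tname` and `num_reads` (as
#'   written by [write_quantification()]), or an `em_fit` object.
#' @param truth A data frame with columns `tname` and `true_count` (as written
#'   by [simulate_reads()]).
#' @return A one-row tibble: the [compute_metrics()] columns plus `auc_pr` and
#'   `average_precision` (`NA` when only one class is present).
#' @export
evaluate_quantification <- function(estimated, truth) {
  if (inherits(estimated, "em_fit")) {
    estimated <- tidy(estimated)
  }
  est_col <- if ("num_reads" %in% names(estimated)) "num_reads" else "frac"
  truth_col <- if ("true_count" %in% names(truth)) "true_count" else "true_frac"
  joined <- dplyr::inner_join(
    dplyr::select(estimated, "tname", est = dplyr::all_of(est_col)),
    dplyr::select(truth, "tname", truth = dplyr::all_of(truth_col)),
    by = "tname"
  )
  n_unmatched <- nrow(estimated) + nrow(truth) - 2L * nrow(joined)
  if (n_unmatched > 0) {
    rlang::inform(paste0("evaluate_quantification: ", n_unmatched,
                         " unmatched transcript name(s) dropped"))
  }
  metrics <- compute_metrics(joined$est, joined$truth)
  pos <- joined$truth > 0
  if (any(pos) && !all(pos)) {
    pr <- precision_recall(joined$est, pos)
    metrics$auc_pr <- pr$auc_pr
    metrics$average_precision <- pr$average_precision
  } else {
    metrics$auc_pr <- NA_real_
    metrics$average_precision <- NA_real_
  }
  metrics
}
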