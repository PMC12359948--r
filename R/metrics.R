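# Evaluation metrics and the statistical tests used by the training
# protocol. These are implemented here (rather than wrapped) because the
# protocol prescribes their exact algorithms: AUC in the Mann-Whitney
# formulation with half-credit ties, Wilcoxon rank sum with exact
# enumeration at small sample sizes, and the Sidak family-wise correction.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half. Computed from mid-ranks,
#' which is equivalent to all-pairs concordance counting.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc() requires both classes to be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion counts from scores and labels
#'
#' @param scores Numeric scores (probabilities or logits).
#' @param labels Binary labels (0/1).
#' @param threshold Predict positive when `scores >= threshold`.
#' @return List with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  list(tp = sum(pred == 1L & labels == 1L),
       tn = sum(pred == 0L & labels == 0L),
       fp = sum(pred == 1L & labels == 0L),
       fn = sum(pred == 0L & labels == 1L))
}

#' Threshold classification metrics
#'
#' Accuracy, F1 score (harmonic mean of precision and recall) and the
#' Matthews correlation coefficient. Zero-denominator cases return 0 by
#' convention so fold aggregates stay totals.
#'
#' @param counts List with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]).
#' @return List with `acc`, `f1`, `mcc`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  stopifnot(total >= 1L)
  acc <- (tp + tn) / total
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  list(acc = acc, f1 = f1, mcc = mcc)
}

#' Full metric report
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Binary labels.
#' @param threshold Classification threshold for ACC/F1/MCC.
#' @return List with `auc`, `acc`, `f1`, `mcc`.
#' @export
metric_report <- function(scores, labels, threshold = 0.5) {
  m <- classification_metrics(confusion_counts(scores, labels, threshold))
  c(list(auc = roc_auc(scores, labels)), m)
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic with mid-ranks for ties. For pooled sample sizes
#' `n + m <= exact_limit` the p-value is computed exactly by enumerating
#' all assignments of the pooled values to the two groups; otherwise a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param sidedness `"one_sided"` tests whether `x` tends to be greater
#'   than `y` (the improvement direction of the training protocol);
#'   `"two_sided"` is the symmetric alternative.
#' @param exact_limit Largest pooled size for exact enumeration.
#' @return List with `statistic` (rank sum of `x`), `p_value`, `sidedness`,
#'   `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y, sidedness = c("one_sided", "two_sided"),
                              exact_limit = 12L) {
  sidedness <- match.arg(sidedness)
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L) stop("wilcoxon_rank_sum() requires non-empty samples")
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  w_obs <- sum(r[seq_len(n)])
  N <- n + m

  if (N <= exact_limit) {
    combos <- utils::combn(N, n)
    w_all <- colSums(matrix(r[combos], nrow = n))
    eps <- 1e-9
    p_ge <- mean(w_all >= w_obs - eps)
    p_le <- mean(w_all <= w_obs + eps)
    p <- if (sidedness == "one_sided") p_ge else min(1, 2 * min(p_ge, p_le))
    return(list(statistic = w_obs, p_value = p, sidedness = sidedness,
                exact = TRUE))
  }

  mu <- n * (N + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / ((N) * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    # all values identical: no evidence in either direction
    return(list(statistic = w_obs, p_value = 1, sidedness = sidedness,
                exact = FALSE))
  }
  # continuity-corrected normal approximation
  z_up <- (w_obs - mu - 0.5) / sqrt(sigma2)
  z_dn <- (w_obs - mu + 0.5) / sqrt(sigma2)
  p_ge <- stats::pnorm(z_up, lower.tail = FALSE)
  p_le <- stats::pnorm(z_dn)
  p <- if (sidedness == "one_sided") p_ge else min(1, 2 * min(p_ge, p_le))
  list(statistic = w_obs, p_value = p, sidedness = sidedness, exact = FALSE)
}

#' Sidak-corrected significance level
#'
#' Family-wise error control for `m` comparisons:
#' `alpha' = 1 - (1 - alpha)^(1/m)`.
#'
#' @param alpha Significance level in (0, 1).
#' @param m Number of comparisons, `>= 1`.
#' @return Corrected per-comparison alpha.
#' @export
sidak_alpha <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  1 - (1 - alpha)^(1 / m)
}
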