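#' Classification metrics at a threshold
#'
#' AUC is computed by the rank (Mann-Whitney) statistic with tie-halving;
#' sensitivity, specificity, precision, recall and F1 come from the confusion
#' matrix at `threshold` (predicted positive when `score >= threshold`).
#' Sensitivity and specificity are reported in percent, matching clinical
#' convention.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1, logical, or a factor whose second level
#'   is the positive class).
#' @param threshold Decision threshold on the score scale; `"youden"`
#'   (default) picks the threshold maximizing sensitivity + specificity - 1
#'   over the observed scores.
#' @return A one-row tibble: `auc`, `sensitivity`, `specificity`, `f1`,
#'   `precision`, `recall`, `threshold`, `n`.
#' @examples
#' evaluate_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))$auc  # 0.75
#' @export
evaluate_metrics <- function(scores, labels, threshold = "youden") {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y))
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)

  r <- rank(scores)  # midranks halve ties
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  if (identical(threshold, "youden")) {
    cand <- sort(unique(scores))
    j <- vapply(cand, function(th) {
      sens <- sum(scores >= th & y == 1) / n1
      spec <- sum(scores < th & y == 0) / n0
      sens + spec - 1
    }, numeric(1))
    threshold <- cand[which.max(j)]
  }
  tp <- sum(scores >= threshold & y == 1)
  fn <- n1 - tp
  fp <- sum(scores >= threshold & y == 0)
  tn <- n0 - fp
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- sens
  f1 <- if (is.na(prec) || prec + rec == 0) NA_real_ else 2 * prec * rec / (prec + rec)
  tibble::tibble(auc = auc, sensitivity = 100 * sens, specificity = 100 * spec,
                 f1 = f1, precision = prec, recall = rec,
                 threshold = threshold, n = length(y))
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    as.integer(labels == levels(labels)[2L])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1)))
      stop("labels must be binary (0/1, logical, or two-level factor)",
           call. = FALSE)
    as.integer(labels)
  }
}

# Stratified k-fold assignment: within each class, fold sizes differ by at
# most one record.
stratified_folds <- function(y, k = 3L) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}
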