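# Benchmarking prioritizations against proof-of-concept targets:
# ROC/AUC (Mann-Whitney), precision-recall with F-max, and the naive
# drug-count baseline.

.split_scores <- function(scores, labels) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  pos <- intersect(labels$positives, names(scores))
  neg <- intersect(labels$controls, names(scores))
  if (!length(pos) || !length(neg))
    stop("both classes must be present among the scored genes")
  list(pos = scores[pos], neg = scores[neg])
}

#' ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney statistic
#' `P(score_pos > score_neg) + 0.5 P(tie)`, so it is threshold-free and
#' invariant under strictly monotone transforms of the scores. The curve
#' is swept over the distinct score thresholds.
#'
#' @param scores Named numeric vector of per-gene scores.
#' @param labels A `label_set` (fields `positives`, `controls`); only
#'   genes present in `scores` are used.
#' @return A list of class `roc_result` with `auc` and `curve`
#'   (data.frame of FPR/TPR points from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  sp <- .split_scores(scores, labels)
  r <- rank(c(sp$pos, sp$neg), ties.method = "average")
  n_pos <- length(sp$pos); n_neg <- length(sp$neg)
  auc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(c(sp$pos, sp$neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(sp$pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(sp$neg >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  curve <- curve[!duplicated(curve), , drop = FALSE]
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

#' Precision-recall curve and F-max
#'
#' Sweeps every distinct score threshold, computes precision and recall of
#' the induced positive call set, and reports the maximum harmonic mean
#' F = 2PR/(P+R) together with its operating point.
#'
#' @inheritParams roc_auc
#' @return A list of class `pr_result` with `curve` (recall/precision),
#'   `fmax`, `precision_at_fmax`, `recall_at_fmax`.
#' @export
pr_fmax <- function(scores, labels) {
  sp <- .split_scores(scores, labels)
  all_s <- c(sp$pos, sp$neg)
  thr <- sort(unique(all_s), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(sp$pos >= t), numeric(1))
  called <- vapply(thr, function(t) sum(all_s >= t), numeric(1))
  precision <- tp / called
  recall <- tp / length(sp$pos)
  f <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  i <- which.max(f)
  structure(list(curve = data.frame(recall = recall, precision = precision),
                 fmax = f[i], precision_at_fmax = precision[i],
                 recall_at_fmax = recall[i], threshold_at_fmax = thr[i]),
            class = "pr_result")
}

#' Naive drug-count prioritization baseline
#'
#' Scores each gene by the number of distinct drugs already targeting it
#' (any development phase); genes absent from the table score 0. This is
#' the repurposing-only baseline a prioritization must beat to be able to
#' propose genuinely new targets.
#'
#' @param drug_targets Drug-target table (see [read_drug_targets()]).
#' @param universe Character vector of candidate genes.
#' @return Named integer vector over `universe`.
#' @export
naive_scores <- function(drug_targets, universe) {
  counts <- tapply(drug_targets$drug, drug_targets$gene,
                   function(d) length(unique(d)))
  out <- setNames(integer(length(universe)), universe)
  common <- intersect(names(counts), universe)
  out[common] <- as.integer(counts[common])
  out
}
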