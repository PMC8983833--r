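# Predictor evaluation and combination: benchmark labels, random-forest
# permutation importance against the nGene baseline, rank-based p-value
# transform, meta-analysis combination, and the 0-5 priority rating.

#' Assemble benchmark labels from drug-target annotations
#'
#' Positives are genes in the universe targeted by a drug that reached
#' clinical development phase `min_phase` or above (proof-of-concept
#' targets); controls are a seeded uniform sample without replacement of
#' size `control_ratio` times the positives, drawn from the rest of the
#' universe.
#'
#' @param drug_targets Drug-target table (see [read_drug_targets()]).
#' @param universe Character vector of candidate genes.
#' @param control_ratio Controls per positive. Default 10.
#' @param seed Integer seed for the control draw.
#' @param min_phase Minimum development phase defining a positive. Default 2.
#' @return A list of class `label_set` with `positives`, `controls`, `seed`.
#' @export
assemble_labels <- function(drug_targets, universe, control_ratio = 10L,
                            seed = 1L, min_phase = 2L) {
  pos <- intersect(unique(drug_targets$gene[drug_targets$max_phase >= min_phase]),
                   universe)
  if (!length(pos)) stop("no proof-of-concept target gene found in the universe")
  pool <- setdiff(universe, pos)
  n_ctrl <- control_ratio * length(pos)
  if (length(pool) < n_ctrl)
    stop(sprintf("universe too small: need %d controls but only %d genes available",
                 n_ctrl, length(pool)))
  controls <- withr::with_seed(seed, sample(pool, n_ctrl))
  structure(list(positives = pos, controls = controls, seed = seed),
            class = "label_set")
}

#' Random-forest permutation importance of predictors
#'
#' Fits a random forest classifying proof-of-concept positives against
#' controls from the affinity predictor matrix and reports each
#' predictor's mean decrease in out-of-bag accuracy when its values are
#' permuted (unscaled), i.e. the accuracy lost by disabling the predictor.
#'
#' @param matrix Genes-by-predictors matrix from [build_predictor_matrix()].
#' @param labels A `label_set` from [assemble_labels()].
#' @param n_trees Number of trees. Default 500.
#' @param seed Integer seed; results are reproducible given it.
#' @param baseline Name of the baseline predictor column. Default `"nGene"`.
#' @return A `data.frame` (class `importance_table`) with columns
#'   `predictor`, `importance`, plus a `baseline` attribute.
#' @export
predictor_importance <- function(matrix, labels, n_trees = 500L, seed = 1L,
                                 baseline = "nGene") {
  stopifnot(ncol(matrix) >= 2)
  if (!baseline %in% colnames(matrix))
    stop(sprintf("baseline predictor '%s' not in the matrix", baseline))
  genes <- intersect(c(labels$positives, labels$controls), rownames(matrix))
  if (!length(intersect(labels$positives, genes)) ||
      !length(intersect(labels$controls, genes)))
    stop("labels do not overlap the matrix rows in both classes")
  X <- matrix[genes, , drop = FALSE]
  y <- factor(ifelse(genes %in% labels$positives, "target", "control"),
              levels = c("control", "target"))
  const <- apply(X, 2L, function(col) length(unique(col)) == 1L)
  if (any(const))
    warning(sprintf("constant predictor column(s): %s (importance 0)",
                    paste(colnames(X)[const], collapse = ", ")))
  rf <- withr::with_seed(seed,
    randomForest::randomForest(x = X, y = y, ntree = n_trees,
                               importance = TRUE))
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
  imp[const] <- 0
  out <- data.frame(predictor = colnames(X), importance = unname(imp[colnames(X)]),
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  class(out) <- c("importance_table", class(out))
  out
}

#' Select predictors no less informative than the baseline
#'
#' The proximity baseline is always kept; any other predictor is kept iff
#' its importance is greater than or equal to the baseline's.
#'
#' @param importances An `importance_table` from [predictor_importance()].
#' @param baseline Baseline name; defaults to the table's attribute.
#' @return Character vector of retained predictor names (baseline first).
#' @export
select_informative <- function(importances, baseline = NULL) {
  if (is.null(baseline)) baseline <- attr(importances, "baseline")
  if (is.null(baseline)) baseline <- "nGene"
  if (!baseline %in% importances$predictor)
    stop(sprintf("baseline '%s' missing from the importance table", baseline))
  b <- importances$importance[importances$predictor == baseline]
  keep <- importances$predictor[importances$importance >= b]
  union(baseline, keep)
}

#' Transform affinities to empirical p-values by within-predictor rank
#'
#' Per predictor column, `p = rank / N` with ranks taken over descending
#' affinity (average ranks for ties); genes with zero affinity get `p = 1`
#' exactly.
#'
#' @param matrix Genes-by-predictors affinity matrix.
#' @return Matrix of the same shape with entries in (0, 1\].
#' @export
affinity_to_pvalues <- function(matrix) {
  P <- apply(matrix, 2L, function(col) {
    if (length(unique(col)) < 2L)
      stop("constant predictor column: cannot rank-transform (drop it first)")
    p <- rank(-col, ties.method = "average") / length(col)
    p[col == 0] <- 1
    p
  })
  dimnames(P) <- dimnames(matrix)
  P
}

# -- meta-analysis combiners ------------------------------------------------

#' Fisher's combined probability
#'
#' `X = -2 * sum(log p)` referred to the upper tail of chi-squared with
#' `2k` degrees of freedom.
#'
#' @param p Numeric vector (or matrix, combined row-wise) of p-values in (0,1].
#' @return Combined p-value(s).
#' @export
fisher_combine <- function(p) {
  P <- .as_p_matrix(p)
  k <- ncol(P)
  X <- -2 * rowSums(log(P))
  pchisq(X, df = 2 * k, lower.tail = FALSE)
}

#' Logistic (Mudholkar-George) combined probability
#'
#' `L = -sum(log(p/(1-p)))` (p clamped to \[1e-16, 1-1e-16\]) with
#' `t* = L * sqrt(3 (5k+4) / (k pi^2 (5k+2)))` referred to Student's t
#' with `5k+4` degrees of freedom.
#'
#' @inheritParams fisher_combine
#' @return Combined p-value(s).
#' @export
logistic_combine <- function(p) {
  P <- .as_p_matrix(p)
  k <- ncol(P)
  P <- pmin(pmax(P, 1e-16), 1 - 1e-16)
  L <- -rowSums(log(P / (1 - P)))
  tstar <- L * sqrt(3 * (5 * k + 4) / (k * pi^2 * (5 * k + 2)))
  pt(tstar, df = 5 * k + 4, lower.tail = FALSE)
}

#' Joint order-statistic score
#'
#' For sorted rank ratios `r1 <= ... <= rk`, returns `Q = k! * Vk` with
#' `V0 = 1`, `Vi = sum_{j=1..i} (-1)^(j-1) (V_{i-j}/j!) r_{k-i+1}^j`. Under
#' k independent uniforms, small Q indicates jointly extreme ranks; Q is
#' calibrated to an empirical p-value by [orderstat_combine()].
#'
#' @param p Numeric vector or matrix (rows combined) of values in (0,1].
#' @return Q statistic(s).
#' @export
orderstat_q <- function(p) {
  P <- .as_p_matrix(p)
  k <- ncol(P)
  R <- t(apply(P, 1L, sort))
  if (k == 1L) R <- matrix(P, ncol = 1L)
  V <- vector("list", k + 1L)
  V[[1L]] <- rep(1, nrow(R))          # V_0
  for (i in seq_len(k)) {
    acc <- 0
    for (j in seq_len(i)) {
      acc <- acc + (-1)^(j - 1) * (V[[i - j + 1L]] / factorial(j)) *
        R[, k - i + 1L]^j
    }
    V[[i + 1L]] <- acc
  }
  factorial(k) * V[[k + 1L]]
}

# cache of Monte-Carlo null tables for the order-statistic calibration
.orderstat_cache <- new.env(parent = emptyenv())

#' Order-statistic combined probability, Monte-Carlo calibrated
#'
#' Computes [orderstat_q()] per gene and converts it to an empirical
#' p-value against a seeded null table of `n_null` draws of k independent
#' uniforms (cached per k/seed): `p = (1 + #{Q_null <= Q}) / (n_null + 1)`.
#'
#' @inheritParams fisher_combine
#' @param n_null Null draws for the calibration table. Default 100000.
#' @param seed Seed for the null table.
#' @return Combined p-value(s).
#' @export
orderstat_combine <- function(p, n_null = 100000L, seed = 20260901L) {
  P <- .as_p_matrix(p)
  k <- ncol(P)
  key <- sprintf("k%d_n%d_s%d", k, n_null, seed)
  if (is.null(.orderstat_cache[[key]])) {
    U <- withr::with_seed(seed, matrix(runif(n_null * k), ncol = k))
    .orderstat_cache[[key]] <- sort(orderstat_q(U))
  }
  null_q <- .orderstat_cache[[key]]
  q <- orderstat_q(P)
  (findInterval(q, null_q) + 1) / (length(null_q) + 1)
}

.as_p_matrix <- function(p) {
  P <- if (is.matrix(p)) p else matrix(p, nrow = 1L)
  if (!ncol(P)) stop("no predictor to combine (k = 0)")
  if (any(P <= 0 | P > 1)) stop("p-values must lie in (0, 1]")
  P
}

#' Combine predictors into a per-gene score
#'
#' Direct strategies operate on affinities: `sum` (total affinity), `max`
#' (best affinity), `harmonic` (harmonic sum `sum s_(i) / i^2` over each
#' gene's affinities sorted descending, the aggregation style used by the
#' Open Targets baseline). Meta-analysis strategies operate on the
#' rank-based p-value matrix (see [affinity_to_pvalues()]): `fisher`,
#' `logistic`, `orderstat`; for these the combined score is
#' `-log10(combined p)`.
#'
#' @param x Affinity matrix (direct methods) or p-value matrix (meta
#'   methods), genes in rows.
#' @param method Combination strategy.
#' @param n_null,seed Calibration controls for `orderstat`
#'   (see [orderstat_combine()]).
#' @return A `data.frame` with columns `gene`, `combined_score` and, for
#'   meta methods, `combined_p`.
#' @export
combine_predictors <- function(x, method = c("orderstat", "fisher", "logistic",
                                             "sum", "max", "harmonic"),
                               n_null = 100000L, seed = 20260901L) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), ncol(x) >= 1)
  genes <- rownames(x)
  if (method %in% c("sum", "max", "harmonic")) {
    score <- switch(method,
      sum = rowSums(x),
      max = apply(x, 1L, max),
      harmonic = apply(x, 1L, function(s) {
        s <- sort(s, decreasing = TRUE)
        sum(s / seq_along(s)^2)
      }))
    return(data.frame(gene = genes, combined_score = unname(score),
                      stringsAsFactors = FALSE))
  }
  pc <- switch(method,
    fisher = fisher_combine(x),
    logistic = logistic_combine(x),
    orderstat = orderstat_combine(x, n_null = n_null, seed = seed))
  data.frame(gene = genes, combined_score = -log10(pc), combined_p = pc,
             stringsAsFactors = FALSE)
}

#' Rate genes from combined scores
#'
#' Min-max rescales combined scores to a 0-5 priority rating and ranks
#' genes by descending score with ties broken lexicographically by gene
#' symbol; the percentile is `100 * rank / N`.
#'
#' @param scores A data.frame with columns `gene`, `combined_score` (from
#'   [combine_predictors()]) or a named numeric vector.
#' @return A `data.frame` (class `priority_table`) with columns `gene`,
#'   `combined_score`, `rating`, `rank`, `percentile`, ordered by rank.
#' @export
rate_genes <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores)))
    scores <- data.frame(gene = names(scores), combined_score = unname(scores),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "combined_score") %in% names(scores)),
            nrow(scores) >= 2)
  s <- scores$combined_score
  if (max(s) == min(s)) stop("all combined scores are equal: cannot rate")
  rating <- 5 * (s - min(s)) / (max(s) - min(s))
  ord <- order(-s, scores$gene)
  out <- data.frame(gene = scores$gene[ord],
                    combined_score = s[ord],
                    rating = rating[ord],
                    rank = seq_along(ord),
                    percentile = 100 * seq_along(ord) / length(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("priority_table", class(out))
  out
}
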