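# End-to-end prioritization: seeds -> propagation -> predictor evaluation
# -> combination -> rating.

#' Run the full prioritization pipeline
#'
#' Chains the stages on a set of input tables (as produced by the readers
#' or by [generate_prioritization_fixture()]): lead-variant selection, LD
#' expansion, nGene/cGene/eGene seed scoring, random walk with restart
#' over the interaction network, predictor-importance evaluation against
#' the nGene baseline, rank-based p-value transform, meta-analysis
#' combination and 0-5 rating. Predictors whose evidence channel yields no
#' seed gene are dropped with a message; the importance filter is applied
#' only when at least two predictors survive.
#'
#' @param inputs List with `variants`, `genes`, `ld`, `hic`, `eqtl`,
#'   `network`, `drug_targets` (any of `ld`/`hic`/`eqtl` may be `NULL`).
#' @param cfg A [predictor_config()].
#' @param method Combination strategy (see [combine_predictors()]).
#' @param seed Integer seed (controls, random forest, order-statistic
#'   calibration).
#' @param control_ratio,min_phase Label construction (see
#'   [assemble_labels()]).
#' @param n_trees Random-forest size.
#' @param filter_predictors Apply the importance filter. Default TRUE.
#' @return A list of class `prioritization` with `priority`
#'   (a `priority_table`), `matrix` (all predictors), `pvalues`,
#'   `importance`, `informative`, `labels`, `affinities`.
#' @export
run_prioritization <- function(inputs, cfg = predictor_config(),
                               method = "orderstat", seed = 1L,
                               control_ratio = 10L, min_phase = 2L,
                               n_trees = 500L, filter_predictors = TRUE) {
  leads <- select_lead_variants(inputs$variants, cfg)
  if (!nrow(leads)) stop("no genome-wide significant variant: nothing to prioritize")
  expanded <- expand_by_ld(leads, inputs$ld, cfg)

  seeds <- list()
  seeds$nGene <- tryCatch(
    score_seeds("nGene", expanded, inputs$genes, variants = inputs$variants,
                cfg = cfg),
    error = function(e) { message("nGene predictor dropped: ", conditionMessage(e)); NULL })
  if (!is.null(inputs$hic))
    seeds$cGene <- tryCatch(
      score_seeds("cGene", expanded, inputs$genes, variants = inputs$variants,
                  links = inputs$hic, cfg = cfg),
      error = function(e) { message("cGene predictor dropped: ", conditionMessage(e)); NULL })
  if (!is.null(inputs$eqtl))
    seeds$eGene <- tryCatch(
      score_seeds("eGene", expanded, inputs$genes, links = inputs$eqtl,
                  cfg = cfg),
      error = function(e) { message("eGene predictor dropped: ", conditionMessage(e)); NULL })
  seeds <- Filter(Negate(is.null), seeds)
  if (!length(seeds)) stop("no predictor produced any seed gene")

  affinities <- lapply(seeds, function(s)
    rwr(inputs$network, s, restart = cfg$restart))
  universe <- igraph::V(inputs$network)$name
  M <- build_predictor_matrix(unname(affinities), universe)

  labels <- assemble_labels(inputs$drug_targets, universe,
                            control_ratio = control_ratio, seed = seed,
                            min_phase = min_phase)
  importance <- NULL
  keep <- colnames(M)
  if (filter_predictors && ncol(M) >= 2L) {
    importance <- predictor_importance(M, labels, n_trees = n_trees, seed = seed)
    keep <- select_informative(importance)
  }
  Mk <- M[, keep, drop = FALSE]

  x <- if (method %in% c("sum", "max", "harmonic")) Mk else affinity_to_pvalues(Mk)
  combined <- combine_predictors(x, method = method, seed = seed)
  priority <- rate_genes(combined)

  structure(list(priority = priority, matrix = M,
                 pvalues = if (is.matrix(x) && !method %in% c("sum", "max", "harmonic")) x else NULL,
                 importance = importance, informative = keep, labels = labels,
                 affinities = affinities),
            class = "prioritization")
}
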