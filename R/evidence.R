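# Seed-gene scoring: lead-variant selection, LD expansion, and the three
# variant-to-gene predictors (nGene by proximity, cGene by chromatin
# conformation, eGene by expression QTL).

#' Predictor configuration
#'
#' Bundles the tunable parameters of the seed-scoring and propagation
#' steps. `p_threshold` is the genome-wide significance cutoff applied to
#' GWAS p-values; `r2_min` is the minimum r-squared for a proxy variant to
#' be pulled in during LD expansion; `ngene_window` is the maximum
#' TSS-to-variant distance (bp) for the proximity predictor, with a
#' `decay` shape applied within the window; `log10p_cap` caps the
#' -log10(p) evidence weight; `restart` is the random-walk restart
#' probability.
#'
#' @param p_threshold GWAS significance threshold, in (0,1). Default 5e-8.
#' @param r2_min Minimum LD r-squared for proxy inclusion, in \[0,1\].
#' @param ngene_window Proximity window in bp (> 0).
#' @param decay `"linear"` or `"exponential"` distance decay within the window.
#' @param log10p_cap Cap on -log10(p) used in evidence weights.
#' @param restart Random walk restart probability, in (0,1\].
#' @return A list of class `predictor_config`.
#' @export
predictor_config <- function(p_threshold = 5e-8, r2_min = 0.8,
                             ngene_window = 500000L,
                             decay = c("linear", "exponential"),
                             log10p_cap = 12, restart = 0.75) {
  decay <- match.arg(decay)
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_min >= 0, r2_min <= 1,
            ngene_window > 0, log10p_cap > 0,
            restart > 0, restart <= 1)
  structure(list(p_threshold = p_threshold, r2_min = r2_min,
                 ngene_window = as.numeric(ngene_window), decay = decay,
                 log10p_cap = log10p_cap, restart = restart),
            class = "predictor_config")
}

#' Select genome-wide significant lead variants
#'
#' Keeps exactly the variants with `pvalue < cfg$p_threshold`.
#'
#' @param variants Validated variant table (see [read_gwas()]).
#' @param cfg A [predictor_config()].
#' @return Subset of `variants`; a warning is emitted when empty.
#' @export
select_lead_variants <- function(variants, cfg = predictor_config()) {
  stopifnot(nrow(variants) > 0)
  out <- variants[variants$pvalue < cfg$p_threshold, , drop = FALSE]
  if (!nrow(out))
    warning("no variant passes the significance threshold; downstream predictors will be empty")
  out
}

#' Expand lead variants through linkage disequilibrium
#'
#' Returns the union of the lead variants and every variant linked to a
#' lead at `r2 >= cfg$r2_min`, each annotated with the best (smallest)
#' p-value among the leads it proxies.
#'
#' @param leads Lead variant table from [select_lead_variants()].
#' @param ld LD pair table (see [read_ld_table()]); may be empty.
#' @param cfg A [predictor_config()].
#' @return A `data.frame` with columns `variant_id`, `lead_pvalue`.
#' @export
expand_by_ld <- function(leads, ld, cfg = predictor_config()) {
  stopifnot(nrow(leads) > 0)
  best <- setNames(leads$pvalue, leads$variant_id)
  if (!is.null(ld) && nrow(ld)) {
    keep <- ld$r2 >= cfg$r2_min
    pairs <- rbind(
      data.frame(lead = ld$variant_a[keep], proxy = ld$variant_b[keep]),
      data.frame(lead = ld$variant_b[keep], proxy = ld$variant_a[keep])
    )
    pairs <- pairs[pairs$lead %in% leads$variant_id, , drop = FALSE]
    if (nrow(pairs)) {
      pairs$p <- best[pairs$lead]
      prox <- tapply(pairs$p, pairs$proxy, min)
      for (v in names(prox)) {
        best[v] <- if (is.na(best[v])) prox[[v]] else min(best[v], prox[[v]])
      }
    }
  }
  data.frame(variant_id = names(best), lead_pvalue = unname(best),
             stringsAsFactors = FALSE)
}

# Evidence weight: capped, rescaled -log10(p) in (0, 1].
.evidence_weight <- function(p, cap) pmin(-log10(p), cap) / cap

#' Score seed genes for one predictor
#'
#' Maps a set of disease-associated variants to genes through one of three
#' evidence channels and returns per-gene seed scores in \[0,1\]
#' (min-max normalized so the best gene scores 1):
#' \describe{
#'   \item{nGene}{gene scored by the best variant within `ngene_window` of
#'     its TSS: weight `min(-log10 p, cap)/cap` times a distance decay
#'     (linear `1 - d/window`, or exponential `2^(-d/(window/2))`).}
#'   \item{cGene}{gene scored by the best variant falling inside a Hi-C
#'     fragment linked to it, weight times the link score rescaled to
#'     (0,1\] within the table.}
#'   \item{eGene}{gene scored by the best eQTL pair with the variant in the
#'     set, using the capped, rescaled -log10 eQTL p-value.}
#' }
#'
#' @param kind One of `"nGene"`, `"cGene"`, `"eGene"`.
#' @param variant_set Output of [expand_by_ld()] (columns `variant_id`,
#'   `lead_pvalue`); for nGene/cGene the variants must appear in `variants`
#'   to obtain coordinates.
#' @param genes Gene annotation table (see [read_gene_annotation()]).
#' @param variants Full variant table supplying coordinates (nGene/cGene).
#' @param links Hi-C link table for cGene, eQTL table for eGene; ignored
#'   for nGene.
#' @param cfg A [predictor_config()].
#' @param name Predictor label; defaults to `kind`.
#' @return A list of class `seed_scores` with elements `predictor` and
#'   `scores` (named numeric, all in \[0,1\], max 1).
#' @export
score_seeds <- function(kind = c("nGene", "cGene", "eGene"), variant_set,
                        genes, variants = NULL, links = NULL,
                        cfg = predictor_config(), name = NULL) {
  kind <- match.arg(kind)
  stopifnot(nrow(variant_set) > 0)
  if (is.null(name)) name <- kind
  w <- .evidence_weight(variant_set$lead_pvalue, cfg$log10p_cap)
  names(w) <- variant_set$variant_id

  scores <- numeric(0)
  if (kind == "nGene") {
    if (is.null(variants)) stop("nGene scoring requires the variant coordinate table")
    vv <- variants[variants$variant_id %in% variant_set$variant_id, , drop = FALSE]
    scores <- .score_ngene(vv, w, genes, cfg)
  } else if (kind == "cGene") {
    if (is.null(links) || !all(c("fragment_chrom", "fragment_start",
                                 "fragment_end", "gene", "link_score") %in% names(links)))
      stop("cGene scoring requires a Hi-C link table")
    if (is.null(variants)) stop("cGene scoring requires the variant coordinate table")
    vv <- variants[variants$variant_id %in% variant_set$variant_id, , drop = FALSE]
    scores <- .score_cgene(vv, w, links)
  } else {
    if (is.null(links) || !all(c("variant_id", "gene", "eqtl_pvalue") %in% names(links)))
      stop("eGene scoring requires an eQTL link table")
    scores <- .score_egene(variant_set, links, cfg)
  }
  seeds <- structure(list(predictor = name, scores = scores),
                     class = "seed_scores")
  normalize_seeds(seeds)
}

.score_ngene <- function(vv, w, genes, cfg) {
  scores <- numeric(0)
  for (chrom in unique(vv$chromosome)) {
    vi <- vv[vv$chromosome == chrom, , drop = FALSE]
    gi <- genes[genes$chromosome == chrom, , drop = FALSE]
    if (!nrow(gi) || !nrow(vi)) next
    # point positions are 1-based on both sides; unsigned distance
    d <- abs(outer(gi$tss, vi$position, "-"))
    decay <- if (cfg$decay == "linear") {
      pmax(1 - d / cfg$ngene_window, 0)
    } else {
      ifelse(d <= cfg$ngene_window, 2^(-d / (cfg$ngene_window / 2)), 0)
    }
    decay[d > cfg$ngene_window] <- 0
    s <- decay * matrix(w[vi$variant_id], nrow = nrow(gi),
                        ncol = nrow(vi), byrow = TRUE)
    best <- apply(s, 1L, max)
    pos <- best > 0
    if (any(pos)) scores[gi$gene[pos]] <- pmax(scores[gi$gene[pos]], best[pos],
                                               na.rm = TRUE)
  }
  scores[!is.na(scores)]
}

.score_cgene <- function(vv, w, links) {
  # rescale link scores to (0,1] within the table
  ls <- links$link_score
  mx <- max(ls)
  if (mx <= 0) return(numeric(0))
  rel <- ls / mx
  scores <- numeric(0)
  for (i in seq_len(nrow(links))) {
    # BEDPE 0-based half-open fragment vs 1-based point: position p overlaps
    # [start, end) iff start < p <= end, i.e. p-1 in [start, end)
    hit <- vv$chromosome == links$fragment_chrom[i] &
      (vv$position - 1L) >= links$fragment_start[i] &
      (vv$position - 1L) < links$fragment_end[i]
    if (!any(hit)) next
    s <- max(w[vv$variant_id[hit]]) * rel[i]
    g <- links$gene[i]
    scores[g] <- max(scores[g], s, na.rm = TRUE)
  }
  scores[!is.na(scores)]
}

.score_egene <- function(variant_set, links, cfg) {
  hit <- links[links$variant_id %in% variant_set$variant_id, , drop = FALSE]
  if (!nrow(hit)) return(numeric(0))
  s <- .evidence_weight(hit$eqtl_pvalue, cfg$log10p_cap)
  out <- tapply(s, hit$gene, max)
  setNames(as.numeric(out), names(out))
}

#' Normalize seed scores
#'
#' Divides by the maximum so the best gene scores exactly 1; ordering is
#' preserved. All-zero (or empty) input is an error.
#'
#' @param seeds A `seed_scores` object or a named numeric vector.
#' @return Same shape as the input, rescaled.
#' @export
normalize_seeds <- function(seeds) {
  vec <- if (inherits(seeds, "seed_scores")) seeds$scores else seeds
  if (!length(vec) || max(vec) <= 0)
    stop("cannot normalize: no positive seed score")
  vec <- vec / max(vec)
  if (inherits(seeds, "seed_scores")) {
    seeds$scores <- vec
    seeds
  } else vec
}
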