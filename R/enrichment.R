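# Rank-based target set enrichment with leading-prioritization extraction
# (weighted Kolmogorov-Smirnov running statistic, gene-label permutation
# null) and Fisher-exact over-representation for thresholded gene lists.

# Order a rating vector by the priority-table tie rule: descending value,
# ties broken lexicographically by gene symbol.
.ranked_order <- function(ratings) {
  stopifnot(is.numeric(ratings), !is.null(names(ratings)))
  ord <- order(-ratings, names(ratings))
  ratings[ord]
}

# Running enrichment score for membership indicator `ind` (logical over
# ranked positions) with per-position weights w (used where ind is TRUE).
.running_es <- function(ind, w) {
  n <- length(ind)
  n_hit <- sum(ind)
  wh <- w * ind
  denom_hit <- sum(wh)
  p_hit <- if (denom_hit > 0) cumsum(wh) / denom_hit else cumsum(ind) / n_hit
  p_miss <- cumsum(!ind) / (n - n_hit)
  unname(p_hit - p_miss)
}

.es_extremum <- function(running) {
  i <- which.max(abs(running))
  list(es = running[i], peak = i)
}

#' Rank-based gene-set enrichment at the leading prioritization
#'
#' For each set, computes the weighted running enrichment statistic over
#' the ranked gene list (hit increments proportional to `rating^theta`
#' normalized over set members, miss increments uniform over
#' non-members), takes the extremum as the enrichment score (ES), and
#' extracts the leading prioritization: for positive ES, the set members
#' ranked at or before the ES peak -- the core subset accounting for the
#' signal. Nominal p-values come from seeded gene-label permutations; NES
#' is ES over the mean absolute permuted ES of matching sign, and FDR
#' follows the standard pooled-NES procedure.
#'
#' Sets overlapping the ranked list in fewer than 3 genes are skipped and
#' recorded in the `skipped` attribute.
#'
#' @param ratings Named numeric vector of priority ratings (or a
#'   `priority_table`, whose `rating` column is used).
#' @param sets Named list of character vectors (see [read_gmt()]).
#' @param theta Rating weight exponent (>= 0); `theta = 0` recovers the
#'   classic unweighted Kolmogorov-Smirnov statistic. Default 1.
#' @param n_perm Number of gene-label permutations. Default 1000; fewer
#'   than 100 triggers a warning.
#' @param seed Integer seed for the permutations.
#' @return A `data.frame` (class `enrichment_result`) with one row per
#'   tested set: `set_name`, `size`, `es`, `nes`, `pvalue`, `fdr`,
#'   `leading_fraction`, `leading_genes` (semicolon-joined, ranked order).
#' @export
leading_enrichment <- function(ratings, sets, theta = 1, n_perm = 1000L,
                               seed = 1L) {
  if (inherits(ratings, "priority_table"))
    ratings <- setNames(ratings$rating, ratings$gene)
  if (theta < 0) stop("theta must be >= 0")
  if (n_perm < 100L) warning("fewer than 100 permutations: p-values will be coarse")
  ranked <- .ranked_order(ratings)
  genes <- names(ranked)
  n <- length(genes)
  w <- abs(ranked)^theta

  keep <- vapply(sets, function(s) sum(s %in% genes) >= 3L, logical(1))
  skipped <- names(sets)[!keep]
  sets <- sets[keep]
  if (!length(sets)) {
    out <- data.frame(set_name = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), pvalue = numeric(0), fdr = numeric(0),
                      leading_fraction = numeric(0), leading_genes = character(0))
    attr(out, "skipped") <- skipped
    return(out)
  }

  res <- withr::with_seed(seed, lapply(names(sets), function(nm) {
    ind <- genes %in% sets[[nm]]
    m <- sum(ind)
    ex <- .es_extremum(.running_es(ind, w))
    if (ex$es > 0) {
      lead <- genes[ind & seq_len(n) <= ex$peak]
    } else {
      lead <- character(0)
    }
    # gene-label permutation: membership positions shuffled, weights stay
    # attached to ranked positions
    perm_es <- vapply(seq_len(n_perm), function(i) {
      pind <- logical(n)
      pind[sample.int(n, m)] <- TRUE
      .es_extremum(.running_es(pind, w))$es
    }, numeric(1))
    same <- perm_es[sign(perm_es) == sign(ex$es)]
    pval <- (1 + sum(abs(same) >= abs(ex$es))) / (1 + length(same))
    nes <- if (length(same)) ex$es / mean(abs(same)) else NA_real_
    list(set_name = nm, size = m, es = ex$es, nes = nes, pvalue = pval,
         leading_fraction = length(lead) / m,
         leading_genes = paste(lead, collapse = ";"),
         perm_nes = perm_es / ifelse(length(same), mean(abs(same)), NA_real_))
  }))

  out <- data.frame(
    set_name = vapply(res, `[[`, character(1), "set_name"),
    size = vapply(res, `[[`, numeric(1), "size"),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = vapply(res, `[[`, numeric(1), "nes"),
    pvalue = vapply(res, `[[`, numeric(1), "pvalue"),
    leading_fraction = vapply(res, `[[`, numeric(1), "leading_fraction"),
    leading_genes = vapply(res, `[[`, character(1), "leading_genes"),
    stringsAsFactors = FALSE)
  out$fdr <- .gsea_fdr(out$nes, unlist(lapply(res, `[[`, "perm_nes")))
  out <- out[, c("set_name", "size", "es", "nes", "pvalue", "fdr",
                 "leading_fraction", "leading_genes")]
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", class(out))
  out
}

# Standard pooled-NES FDR: for each observed NES*, the fraction of pooled
# permutation NES at least as extreme (matching sign) divided by the
# fraction of observed NES at least as extreme, clipped to [0, 1].
.gsea_fdr <- function(nes, pooled) {
  pooled <- pooled[is.finite(pooled)]
  vapply(nes, function(x) {
    if (!is.finite(x)) return(NA_real_)
    if (x >= 0) {
      num_pool <- pooled[pooled >= 0]; obs <- nes[nes >= 0]
      num <- if (length(num_pool)) mean(num_pool >= x) else 0
      den <- mean(obs >= x)
    } else {
      num_pool <- pooled[pooled < 0]; obs <- nes[nes < 0]
      num <- if (length(num_pool)) mean(num_pool <= x) else 0
      den <- mean(obs <= x)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
}

#' Fisher-exact over-representation of gene sets in a top gene list
#'
#' One-sided (greater) hypergeometric test of overlap between `top_genes`
#' and each set, within a fixed gene universe. Odds ratios come from the
#' 2x2 table with a Haldane 0.5 correction when any cell is zero (an
#' empty overlap therefore reports a small positive OR rather than 0/0).
#' FDR is Benjamini-Hochberg across the sets in the collection.
#'
#' @param top_genes Character vector, a subset of `universe` (e.g. the top
#'   1 percent prioritized genes).
#' @param sets Named list of character vectors.
#' @param universe Character vector of all eligible genes.
#' @return A `data.frame` (class `ora_result`) with `set_name`, `overlap`,
#'   `set_size`, `list_size`, `universe_size`, `odds_ratio`, `pvalue`,
#'   `fdr`. Sets with no gene in the universe are skipped (attribute
#'   `skipped`).
#' @export
fisher_ora <- function(top_genes, sets, universe) {
  if (!length(universe)) stop("empty universe")
  top_genes <- unique(top_genes)
  if (!all(top_genes %in% universe))
    stop("top_genes must be a subset of the universe")
  n_u <- length(universe)
  n_l <- length(top_genes)
  in_universe <- lapply(sets, intersect, universe)
  skipped <- names(sets)[lengths(in_universe) == 0L]
  keep <- lengths(in_universe) > 0L
  rows <- lapply(names(sets)[keep], function(nm) {
    s <- in_universe[[nm]]
    k <- length(intersect(s, top_genes))
    m <- length(s)
    # one-sided upper tail P(X >= k), X ~ Hypergeom(m, n_u - m, n_l)
    p <- phyper(k - 1, m, n_u - m, n_l, lower.tail = FALSE)
    a <- k; b <- n_l - k; c2 <- m - k; d <- n_u - m - n_l + k
    if (any(c(a, b, c2, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c2 <- c2 + 0.5; d <- d + 0.5 }
    data.frame(set_name = nm, overlap = k, set_size = m, list_size = n_l,
               universe_size = n_u, odds_ratio = (a * d) / (b * c2),
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_name = character(0), overlap = integer(0),
                      set_size = integer(0), list_size = integer(0),
                      universe_size = integer(0), odds_ratio = numeric(0),
                      pvalue = numeric(0))
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("ora_result", class(out))
  out
}

#' Slice the top fraction of a priority table
#'
#' Convenience accessor for thresholded analyses (top 10 percent for
#' hallmark enrichment, top 1 percent for pathway over-representation,
#' top 5 percent for the cross-disease map).
#'
#' @param priority A `priority_table` from [rate_genes()].
#' @param fraction Fraction of genes to keep, in (0, 1\].
#' @return Character vector of the top-ranked genes.
#' @export
top_fraction <- function(priority, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- max(1L, floor(fraction * nrow(priority)))
  priority$gene[priority$rank <= n]
}
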