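# Pathway-crosstalk extraction and attack analysis: maximum-weight
# connected subnetwork of highly prioritized genes (exact by enumeration on
# small graphs, greedy component-merging heuristic above that), permutation
# significance, and single/combinatorial node-removal disconnection effects.

#' Build a scored network for crosstalk search
#'
#' Restricts the interaction network to the genes of the supplied pathway
#' sets (the enriched pathways) and scores each node as its priority
#' rating minus the `quantile` rating among the restricted nodes, so that
#' only "highly prioritized" genes score positive.
#'
#' @param network An undirected `igraph` with gene vertex names.
#' @param priority A `priority_table` from [rate_genes()] (or named rating
#'   vector).
#' @param pathway_sets Optional named list of gene sets; when given, the
#'   network is induced on their union.
#' @param quantile Rating quantile subtracted as the score threshold.
#'   Default 0.9.
#' @return A list of class `scored_network` with `graph`, `scores` (named,
#'   may be negative) and `threshold`.
#' @export
score_crosstalk_network <- function(network, priority, pathway_sets = NULL,
                                    quantile = 0.9) {
  ratings <- if (inherits(priority, "data.frame"))
    setNames(priority$rating, priority$gene) else priority
  keep <- intersect(igraph::V(network)$name, names(ratings))
  if (!is.null(pathway_sets))
    keep <- intersect(keep, unique(unlist(pathway_sets)))
  g <- igraph::induced_subgraph(network, keep)
  thr <- stats::quantile(ratings[keep], quantile, names = FALSE)
  structure(list(graph = g,
                 scores = ratings[igraph::V(g)$name] - thr,
                 threshold = thr),
            class = "scored_network")
}

# Exact maximum-weight connected subgraph by subset enumeration with
# bitmasks; n <= 15 nodes. Returns node names and total score.
.mwcs_exact <- function(graph, scores) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 15L, n >= 1L)
  nodes <- igraph::V(graph)$name
  sc <- scores[nodes]
  bits <- bitwShiftL(1L, 0:(n - 1L))
  adj <- igraph::as_adj_list(graph)
  nbmask <- vapply(adj, function(nb) {
    ids <- as.integer(nb)
    if (!length(ids)) 0L else Reduce(bitwOr, bits[ids])
  }, integer(1))
  # subset score sums (and positive-part upper bounds) by peeling the
  # lowest bit; the positive part bounds any connected subset's score, so
  # most subsets are skipped without a connectivity check
  total <- 2L^n
  ssum <- numeric(total)
  possum <- numeric(total)
  lowidx <- integer(total)
  for (s in 1:(total - 1L)) {
    low <- bitwAnd(s, -s)
    i <- which(bits == low)
    lowidx[s + 1L] <- i
    rest <- bitwXor(s, low) + 1L
    ssum[s + 1L] <- ssum[rest] + sc[i]
    possum[s + 1L] <- possum[rest] + max(sc[i], 0)
  }
  best <- max(sc)                      # a single node is always connected
  best_s <- bits[which.max(sc)]
  for (s in 1:(total - 1L)) {
    if (ssum[s + 1L] <= best || possum[s + 1L] <= best) next
    # BFS over bitmask to test connectivity within s
    reach <- bits[lowidx[s + 1L]]
    frontier <- reach
    while (frontier != 0L) {
      members <- which(bitwAnd(frontier, bits) != 0L)
      ext <- 0L
      for (i in members) ext <- bitwOr(ext, nbmask[i])
      nxt <- bitwAnd(ext, bitwAnd(s, bitwNot(reach)))
      reach <- bitwOr(reach, nxt)
      frontier <- nxt
    }
    if (reach == s) { best <- ssum[s + 1L]; best_s <- s }
  }
  members <- which(bitwAnd(best_s, bits) != 0L)
  list(nodes = nodes[members], total_score = best)
}

# Heuristic: seed at connected components of the positive-score induced
# subgraph, merge components through lowest-penalty paths (traversing a
# node costs max(0, -score) + eps) whenever the merge increases the total,
# then prune negative-score leaves.
.mwcs_heuristic <- function(graph, scores, eps = 1e-6) {
  nodes <- igraph::V(graph)$name
  sc <- scores[nodes]
  pos <- nodes[sc > 0]
  gp <- igraph::induced_subgraph(graph, pos)
  comp <- igraph::components(gp)
  comps <- split(igraph::V(gp)$name, comp$membership)
  comp_score <- vapply(comps, function(m) sum(sc[m]), numeric(1))
  ord <- order(-comp_score)
  comps <- comps[ord]; comp_score <- comp_score[ord]

  # directed penalty graph: entering node v costs max(0, -score(v)) + eps
  cost <- setNames(pmax(0, -sc) + eps, names(sc))
  el <- igraph::as_edgelist(graph)
  del <- rbind(el, el[, 2:1, drop = FALSE])
  gd <- igraph::graph_from_edgelist(del, directed = TRUE)
  igraph::E(gd)$weight <- cost[del[, 2L]]

  current <- comps[[1L]]
  remaining <- comps[-1L]
  repeat {
    if (!length(remaining)) break
    gains <- numeric(length(remaining))
    paths <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      tgt <- intersect(remaining[[i]], igraph::V(gd)$name)
      src <- intersect(current, igraph::V(gd)$name)
      if (!length(tgt) || !length(src)) { gains[i] <- -Inf; next }
      d <- igraph::distances(gd, v = src, to = tgt, mode = "out",
                             weights = igraph::E(gd)$weight)
      if (!length(d) || all(!is.finite(d))) { gains[i] <- -Inf; next }
      ij <- which(d == min(d), arr.ind = TRUE)[1L, ]
      sp <- igraph::shortest_paths(gd, from = rownames(d)[ij[1L]],
                                   to = colnames(d)[ij[2L]], mode = "out",
                                   weights = igraph::E(gd)$weight,
                                   output = "vpath")
      path_nodes <- names(sp$vpath[[1L]])
      inter <- setdiff(path_nodes, c(current, remaining[[i]]))
      penalty <- sum(pmax(0, -sc[inter]))
      gains[i] <- sum(sc[remaining[[i]]]) - penalty
      paths[[i]] <- union(inter, remaining[[i]])
    }
    b <- which.max(gains)
    if (!length(b) || gains[b] <= 0) break
    current <- union(current, paths[[b]])
    remaining <- remaining[-b]
  }
  # prune strictly-negative-score leaves of the induced subgraph
  repeat {
    gi <- igraph::induced_subgraph(graph, current)
    deg <- igraph::degree(gi)
    bad <- names(deg)[deg <= 1L & sc[names(deg)] < 0]
    if (!length(bad)) break
    current <- setdiff(current, bad)
  }
  list(nodes = current, total_score = sum(sc[current]))
}

#' Search for the maximum-weight connected crosstalk subnetwork
#'
#' Finds a connected subgraph maximizing the total node score. Networks
#' with at most 15 nodes are solved exactly by enumerating all connected
#' node subsets; larger networks use a deterministic heuristic that seeds
#' at each positive-score component, connects components through
#' lowest-penalty paths (a traversed node costs `max(0, -score) + 1e-6`)
#' when the merge increases the total, and prunes negative-score leaves.
#'
#' @param scored A `scored_network` from [score_crosstalk_network()], or
#'   an `igraph` (then `scores` must be given).
#' @param scores Named numeric node scores (ignored when `scored` is a
#'   `scored_network`).
#' @return A list of class `crosstalk_subgraph` with `nodes`, `graph`
#'   (induced subgraph), `total_score`.
#' @export
search_crosstalk <- function(scored, scores = NULL) {
  if (inherits(scored, "scored_network")) {
    graph <- scored$graph; scores <- scored$scores
  } else graph <- scored
  nodes <- igraph::V(graph)$name
  stopifnot(!is.null(scores), all(nodes %in% names(scores)))
  if (!any(scores[nodes] > 0))
    stop("no node has a positive score: nothing to search for")
  res <- if (igraph::vcount(graph) <= 15L) .mwcs_exact(graph, scores)
         else .mwcs_heuristic(graph, scores)
  structure(list(nodes = sort(res$nodes),
                 graph = igraph::induced_subgraph(graph, res$nodes),
                 total_score = res$total_score),
            class = "crosstalk_subgraph")
}

#' Permutation significance of the crosstalk score
#'
#' Permutes the node scores across nodes `n_perm` times, re-runs the
#' subnetwork search, and fits the null total scores with a normal
#' distribution. The parametric upper-tail p-value can resolve extreme
#' significance beyond the permutation resolution; the empirical p-value
#' `(1 + #{null >= observed}) / (n_perm + 1)` is always reported
#' alongside. A degenerate null (zero variance) yields only the empirical
#' p-value.
#'
#' @inheritParams search_crosstalk
#' @param n_perm Number of score permutations (>= 100).
#' @param seed Integer seed.
#' @return A list with `observed`, `pvalue` (parametric, may be `NA`),
#'   `empirical_p`, `null_mean`, `null_sd`.
#' @export
crosstalk_significance <- function(scored, scores = NULL, n_perm = 100L,
                                   seed = 1L) {
  if (inherits(scored, "scored_network")) {
    graph <- scored$graph; scores <- scored$scores
  } else graph <- scored
  stopifnot(n_perm >= 100L)
  nodes <- igraph::V(graph)$name
  obs <- search_crosstalk(graph, scores)$total_score
  null_scores <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- setNames(sample(scores[nodes]), nodes)
    if (!any(perm > 0)) return(0)
    search_crosstalk(graph, perm)$total_score
  }, numeric(1)))
  mu <- mean(null_scores); s <- sd(null_scores)
  p_par <- if (is.na(s) || s == 0) NA_real_ else pnorm(obs, mu, s, lower.tail = FALSE)
  p_emp <- (1 + sum(null_scores >= obs)) / (n_perm + 1)
  list(observed = obs, pvalue = p_par, empirical_p = p_emp,
       null_mean = mu, null_sd = s)
}

#' Disconnection effect of removing nodes
#'
#' The fraction of the surviving network disconnected from the largest
#' remaining component: `1 - |LCC(G - removed)| / (|V| - |removed|)`. The
#' alternative `denominator = "original"` divides by `|V|` instead.
#'
#' @param graph An `igraph`.
#' @param removed Character vector of node names to remove (a proper,
#'   non-empty subset of the vertices).
#' @param denominator `"remaining"` (default) or `"original"`.
#' @return The effect in \[0, 1\].
#' @export
disconnection_effect <- function(graph, removed,
                                 denominator = c("remaining", "original")) {
  denominator <- match.arg(denominator)
  nodes <- igraph::V(graph)$name
  stopifnot(all(removed %in% nodes))
  if (length(removed) >= length(nodes))
    stop("cannot remove all nodes")
  g2 <- igraph::delete_vertices(graph, removed)
  lcc <- max(igraph::components(g2)$csize)
  den <- if (denominator == "remaining") length(nodes) - length(removed)
         else length(nodes)
  1 - lcc / den
}

#' Rank node-removal combinations by disconnection effect
#'
#' Exhaustively evaluates every way of completing a `k`-node removal: the
#' `fixed_context` nodes (chosen in earlier rounds, e.g. the best single
#' node, then the best pair) are always removed together with each
#' candidate combination of the remaining `k - |fixed_context|` nodes.
#' Results are sorted by effect descending, ties broken lexicographically
#' by the candidate gene names.
#'
#' @param graph An `igraph` (typically the crosstalk subgraph).
#' @param k Total number of removed nodes (>= 1).
#' @param fixed_context Character vector of at most `k - 1` context nodes.
#' @param denominator Passed to [disconnection_effect()].
#' @return A `data.frame` with `candidate` (semicolon-joined genes),
#'   `removed` (context + candidate), `effect`, and a logical `best` flag.
#' @export
attack_combinations <- function(graph, k, fixed_context = character(),
                                denominator = "remaining") {
  stopifnot(k >= 1L)
  if (length(fixed_context) >= k)
    stop(sprintf("fixed_context has %d nodes but k = %d: at most k - 1 allowed",
                 length(fixed_context), k))
  nodes <- igraph::V(graph)$name
  stopifnot(all(fixed_context %in% nodes))
  cands <- sort(setdiff(nodes, fixed_context))
  m <- k - length(fixed_context)
  combos <- combn(cands, m, simplify = FALSE)
  eff <- vapply(combos, function(cc)
    disconnection_effect(graph, c(fixed_context, cc), denominator), numeric(1))
  lab <- vapply(combos, paste, character(1), collapse = ";")
  ord <- order(-eff, lab)
  out <- data.frame(candidate = lab[ord],
                    removed = vapply(combos[ord], function(cc)
                      paste(c(fixed_context, cc), collapse = ";"), character(1)),
                    effect = eff[ord], stringsAsFactors = FALSE)
  out$best <- out$effect == out$effect[1L]
  rownames(out) <- NULL
  out
}
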