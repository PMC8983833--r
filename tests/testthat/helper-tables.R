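# Small in-code fixtures shared across tests.

tiny_variants <- function() {
  data.frame(variant_id = c("v1", "v2", "v3"),
             chromosome = c("chr1", "chr1", "chr2"),
             position = c(100L, 5000L, 200L),
             pvalue = c(1e-9, 1e-7, 0.5),
             stringsAsFactors = FALSE)
}

tiny_genes <- function() {
  data.frame(gene = c("A", "B", "C"),
             chromosome = c("chr1", "chr1", "chr2"),
             tss = c(100L, 600000L, 250L),
             strand = c("+", "-", "+"),
             stringsAsFactors = FALSE)
}

write_tsv_tmp <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Erdos-Renyi scored graph with gene-like names, for crosstalk oracles
random_scored_graph <- function(n, p_edge = 0.35, score_sd = 1) {
  g <- igraph::sample_gnp(n, p_edge)
  igraph::V(g)$name <- sprintf("g%02d", seq_len(n))
  scores <- setNames(rnorm(n, 0, score_sd), igraph::V(g)$name)
  list(graph = g, scores = scores)
}

# brute-force maximum-weight connected subgraph via igraph subgraph checks
mwcs_brute <- function(graph, scores) {
  nodes <- igraph::V(graph)$name
  best <- -Inf
  for (k in seq_along(nodes)) {
    for (comb in combn(nodes, k, simplify = FALSE)) {
      sg <- igraph::induced_subgraph(graph, comb)
      if (igraph::is_connected(sg)) {
        s <- sum(scores[comb])
        if (s > best) best <- s
      }
    }
  }
  best
}

# position-by-position running enrichment sum, straight from the definition
running_es_brute <- function(genes_ranked, weights, set) {
  n <- length(genes_ranked)
  ind <- genes_ranked %in% set
  denom_hit <- sum(weights[ind])
  out <- numeric(n)
  acc_hit <- 0; acc_miss <- 0
  for (i in seq_len(n)) {
    if (ind[i]) acc_hit <- acc_hit + weights[i] / denom_hit
    else acc_miss <- acc_miss + 1 / (n - sum(ind))
    out[i] <- acc_hit - acc_miss
  }
  out
}
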