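# Network propagation of seed scores by random walk with restart (RWR).

# Column-stochastic transition operator from an undirected igraph; edge
# weights are used when present, isolated nodes get a self-transition of 1.
.transition_operator <- function(network) {
  has_w <- "weight" %in% igraph::edge_attr_names(network)
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE,
                                   attr = if (has_w) "weight" else NULL)
  A <- methods::as(A, "CsparseMatrix")
  deg <- Matrix::colSums(A)
  iso <- which(deg == 0)
  if (length(iso)) {
    A <- A + Matrix::sparseMatrix(i = iso, j = iso, x = 1,
                                  dims = dim(A), dimnames = dimnames(A))
    deg[iso] <- 1
  }
  A %*% Matrix::Diagonal(x = 1 / deg)
}

#' Random walk with restart over a protein network
#'
#' Iterates `p <- (1 - restart) * W %*% p + restart * p0` to its fixed
#' point, where `W` is the column-stochastic (degree-normalized, weighted
#' if weights are present) transition operator and `p0` the seed vector
#' restricted to network nodes and renormalized to sum 1. The result is
#' the stationary affinity distribution biased toward the seeds; it always
#' sums to 1.
#'
#' @param network An undirected `igraph` with gene-symbol vertex names.
#' @param seeds A `seed_scores` object or named numeric vector of
#'   non-negative seed scores; at least one seed gene must lie on the
#'   network.
#' @param restart Restart probability in (0, 1\]. Default 0.75.
#' @param tol L1 convergence tolerance on successive iterates.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return A list of class `affinity_vector` with elements `predictor` and
#'   `affinity` (named numeric over all network nodes, summing to 1).
#' @export
rwr <- function(network, seeds, restart = 0.75, tol = 1e-10, max_iter = 1000L) {
  stopifnot(restart > 0, restart <= 1)
  name <- if (inherits(seeds, "seed_scores")) seeds$predictor else "seeds"
  vec <- if (inherits(seeds, "seed_scores")) seeds$scores else seeds
  stopifnot(all(vec >= 0))
  nodes <- igraph::V(network)$name
  off <- setdiff(names(vec)[vec > 0], nodes)
  on_net <- intersect(names(vec)[vec > 0], nodes)
  if (!length(on_net))
    stop(sprintf("no seed gene lies on the network; dropped: %s",
                 paste(head(off, 10L), collapse = ", ")))
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[on_net] <- vec[on_net]
  p0 <- p0 / sum(p0)

  W <- .transition_operator(network)
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - restart) * (W %*% p)) + restart * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      names(p) <- nodes
      return(structure(list(predictor = name, affinity = p),
                       class = "affinity_vector"))
    }
  }
  stop(sprintf("random walk did not converge within %d iterations", max_iter))
}

#' Assemble the genes-by-predictors affinity matrix
#'
#' Stacks affinity vectors into a matrix over the candidate universe
#' (network nodes). Genes absent from a vector get 0; every column sums to
#' 1. The nGene predictor, when present, is placed first.
#'
#' @param affinities List of `affinity_vector` objects (or named numeric
#'   vectors with a `predictor` attribute).
#' @param universe Character vector of candidate genes (the network nodes).
#' @return A numeric matrix with `universe` rows and one column per
#'   predictor.
#' @export
build_predictor_matrix <- function(affinities, universe) {
  stopifnot(length(affinities) >= 1)
  nms <- vapply(affinities, function(a) a$predictor, character(1))
  if (anyDuplicated(nms))
    stop(sprintf("duplicate predictor name: %s", nms[duplicated(nms)][1L]))
  ord <- order(!startsWith(nms, "nGene"), seq_along(nms))
  affinities <- affinities[ord]
  nms <- nms[ord]
  M <- matrix(0, nrow = length(universe), ncol = length(affinities),
              dimnames = list(universe, nms))
  for (j in seq_along(affinities)) {
    a <- affinities[[j]]$affinity
    common <- intersect(names(a), universe)
    M[common, j] <- a[common]
  }
  M
}
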