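# Cross-disease prioritization map: pairwise rating correlations, a
# self-organizing map on a supra-hexagonal lattice (concentric hexagon
# rings), topology-preserving clusters on the trained map, and a bootstrap
# consensus neighbour-joining tree over diseases.

#' Spearman correlations of priority ratings against a reference disease
#'
#' @param matrix Genes-by-diseases rating matrix (no missing entries).
#' @param reference Column name of the reference disease.
#' @return A `data.frame` with `disease`, `spearman_rho`, `pvalue`, `fdr`
#'   (Benjamini-Hochberg across the comparisons).
#' @export
rating_correlations <- function(matrix, reference) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2,
            reference %in% colnames(matrix))
  if (any(apply(matrix, 2L, function(x) length(unique(x)) == 1L)))
    stop("constant rating column: Spearman correlation undefined")
  others <- setdiff(colnames(matrix), reference)
  res <- lapply(others, function(d) {
    ct <- suppressWarnings(cor.test(matrix[, reference], matrix[, d],
                                    method = "spearman", exact = FALSE))
    data.frame(disease = d, spearman_rho = unname(ct$estimate),
               pvalue = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}

# axial hex directions (pointy-top)
.hex_dirs <- matrix(c(1, 0, 1, -1, 0, -1, -1, 0, -1, 1, 0, 1),
                    ncol = 2, byrow = TRUE)

#' Build a supra-hexagonal lattice
#'
#' A central hexagon surrounded by `radius - 1` complete rings, giving
#' `1 + 3 * radius * (radius - 1)` hexagons in total (91 at radius 6).
#' Hexagons are indexed center first, then ring by ring in walk order, and
#' carry axial coordinates; adjacency is the 6-neighborhood.
#'
#' @param radius Integer >= 1.
#' @return A list of class `supra_lattice` with `radius`, `coords`
#'   (n x 2 axial q/r), `xy` (Cartesian layout), `neighbors` (list of
#'   integer neighbor indices) and `dist` (hex grid distance matrix).
#' @export
build_lattice <- function(radius) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("radius must be an integer >= 1")
  coords <- matrix(0L, nrow = 1L, ncol = 2L)
  if (radius > 1L) {
    for (ring in 1:(radius - 1L)) {
      hex <- ring * .hex_dirs[5L, ]        # start ring at (-ring, ring)... walk
      ring_coords <- matrix(0L, nrow = 6L * ring, ncol = 2L)
      k <- 0L
      for (side in 1:6) {
        for (step in seq_len(ring)) {
          k <- k + 1L
          ring_coords[k, ] <- hex
          hex <- hex + .hex_dirs[side, ]
        }
      }
      coords <- rbind(coords, ring_coords)
    }
  }
  n <- nrow(coords)
  # hex grid distance on axial coordinates
  dq <- outer(coords[, 1L], coords[, 1L], "-")
  dr <- outer(coords[, 2L], coords[, 2L], "-")
  D <- (abs(dq) + abs(dr) + abs(dq + dr)) / 2
  neighbors <- lapply(seq_len(n), function(i) which(D[i, ] == 1))
  xy <- cbind(x = coords[, 1L] + coords[, 2L] / 2,
              y = coords[, 2L] * sqrt(3) / 2)
  structure(list(radius = radius, coords = coords, xy = xy,
                 neighbors = neighbors, dist = D),
            class = "supra_lattice")
}

.bmu <- function(X, codebook) {
  # squared Euclidean distances genes x hexagons; ties to the lowest index
  d2 <- outer(rowSums(X^2), rowSums(codebook^2), "+") - 2 * X %*% t(codebook)
  max.col(-d2, ties.method = "first")
}

#' Train a batch self-organizing map on the supra-hexagonal lattice
#'
#' Deterministic batch SOM: the codebook is initialized by linear
#' interpolation of the data's first two principal axes over the lattice
#' layout, then trained in a rough phase (Gaussian neighborhood radius
#' decaying linearly from the lattice radius to 1 over `epochs_rough`
#' epochs) and a fine phase (1 to 0.5 over `epochs_fine`). Each epoch
#' assigns every gene to its best-matching hexagon (minimum Euclidean
#' distance, ties to the lowest index) and replaces each codebook vector
#' by the neighborhood-weighted mean of the assigned genes.
#'
#' @param matrix Genes-by-diseases rating matrix.
#' @param lattice A `supra_lattice` from [build_lattice()].
#' @param epochs_rough,epochs_fine Epoch counts for the two phases.
#' @return A list of class `som_codebook` with `codebook` (hexagons x
#'   diseases), `lattice`, and `quantization_error` (per-epoch mean
#'   gene-to-BMU distance).
#' @export
train_som <- function(matrix, lattice, epochs_rough = 50L, epochs_fine = 100L) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1, ncol(matrix) >= 1)
  n_hex <- nrow(lattice$coords)
  if (nrow(matrix) < n_hex)
    warning("fewer genes than hexagons: the map will be sparsely populated")
  X <- matrix
  mu <- colMeans(X)
  # PCA-plane initialization over the lattice layout
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  u <- lattice$xy
  for (a in 1:2) {
    rng <- diff(range(u[, a]))
    u[, a] <- if (rng > 0) 2 * (u[, a] - min(u[, a])) / rng - 1 else 0
  }
  codebook <- matrix(rep(mu, each = n_hex), nrow = n_hex)
  for (a in 1:2) {
    if (ncol(pr$rotation) >= a && pr$sdev[a] > 0)
      codebook <- codebook + outer(u[, a] * pr$sdev[a], pr$rotation[, a])
  }
  dimnames(codebook) <- list(NULL, colnames(X))

  sigmas <- c(seq(lattice$radius, 1, length.out = max(epochs_rough, 1L)),
              seq(1, 0.5, length.out = max(epochs_fine, 1L)))
  qe <- numeric(length(sigmas))
  D <- lattice$dist
  for (t in seq_along(sigmas)) {
    bmu <- .bmu(X, codebook)
    qe[t] <- mean(sqrt(rowSums((X - codebook[bmu, , drop = FALSE])^2)))
    H <- exp(-D^2 / (2 * sigmas[t]^2))
    counts <- tabulate(bmu, nbins = n_hex)
    S <- matrix(0, n_hex, ncol(X))
    agg <- rowsum(X, group = bmu)
    S[as.integer(rownames(agg)), ] <- agg
    num <- H %*% S
    den <- as.numeric(H %*% counts)
    upd <- den > 0
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  structure(list(codebook = codebook, lattice = lattice,
                 quantization_error = qe,
                 n_rough = max(epochs_rough, 1L)),
            class = "som_codebook")
}

#' Partition the trained map into topology-preserving clusters
#'
#' Computes each hexagon's U-height (mean codebook distance to its lattice
#' neighbors), takes local minima as cluster seeds, and assigns every
#' hexagon by a steepest-descent walk on U-height to its seed, so every
#' cluster is a connected patch of hexagons. When `n_clusters` is given
#' and smaller than the natural number of basins, the closest pair of
#' lattice-adjacent clusters (by seed codebook distance) is merged
#' repeatedly until the target count is met.
#'
#' @param som A `som_codebook` from [train_som()].
#' @param n_clusters Optional target cluster count.
#' @return A list of class `map_partition` with `cluster` (integer per
#'   hexagon, ids 1..k), `n_clusters`, `uheight`.
#' @export
partition_map <- function(som, n_clusters = NULL) {
  cb <- som$codebook
  lat <- som$lattice
  n <- nrow(cb)
  uh <- vapply(seq_len(n), function(i) {
    nb <- lat$neighbors[[i]]
    if (!length(nb)) return(0)
    mean(sqrt(rowSums((cb[nb, , drop = FALSE] -
                         matrix(cb[i, ], length(nb), ncol(cb), byrow = TRUE))^2)))
  }, numeric(1))

  # contract adjacent hexagons of exactly equal U-height into plateaus, then
  # run the steepest-descent walk on the plateau graph: a plateau with no
  # lower neighbor is a local minimum and seeds a basin, every other plateau
  # drains to its lowest neighboring plateau (ties to the lowest hexagon
  # index), so each basin is a connected patch
  eq_edges <- NULL
  for (i in seq_len(n)) for (j in lat$neighbors[[i]])
    if (j > i && uh[j] == uh[i]) eq_edges <- rbind(eq_edges, c(i, j))
  gp <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(eq_edges)) gp <- igraph::add_edges(gp, t(eq_edges))
  plat <- as.integer(igraph::components(gp)$membership)
  P <- max(plat)
  plat_u <- vapply(seq_len(P), function(p) uh[which(plat == p)[1L]], numeric(1))
  downhill <- vapply(seq_len(P), function(p) {
    members <- which(plat == p)
    nbhex <- setdiff(unique(unlist(lat$neighbors[members])), members)
    if (!length(nbhex)) return(p)
    j <- nbhex[order(uh[nbhex], nbhex)][1L]
    if (uh[j] < plat_u[p]) plat[j] else p
  }, integer(1))
  proot <- seq_len(P)
  for (p in seq_len(P)) {
    r <- p
    while (downhill[r] != r) r <- downhill[r]
    proot[p] <- r
  }
  seed_plats <- sort(unique(proot))
  # representative hexagon of each seed plateau: its lowest-index member
  seeds <- vapply(seed_plats, function(p) min(which(plat == p)), integer(1))
  cluster <- match(proot[plat], seed_plats)
  k <- length(seed_plats)

  if (!is.null(n_clusters) && n_clusters < k) {
    while (k > n_clusters) {
      # lattice-adjacent cluster pairs, closest by seed codebook distance
      pairs <- NULL
      for (i in seq_len(n)) for (j in lat$neighbors[[i]]) {
        a <- cluster[i]; b <- cluster[j]
        if (a < b) pairs <- rbind(pairs, c(a, b))
      }
      pairs <- unique(pairs)
      dd <- apply(pairs, 1L, function(pr)
        sqrt(sum((cb[seeds[pr[1L]], ] - cb[seeds[pr[2L]], ])^2)))
      m <- pairs[which.min(dd), ]
      cluster[cluster == m[2L]] <- m[1L]
      keep <- sort(unique(cluster))
      seeds <- seeds[keep]
      cluster <- match(cluster, keep)
      k <- length(keep)
    }
  } else if (!is.null(n_clusters) && n_clusters > k) {
    warning(sprintf("only %d natural basins: cannot split to %d clusters", k, n_clusters))
  }
  structure(list(cluster = cluster, n_clusters = k, uheight = uh),
            class = "map_partition")
}

#' Assign genes to hexagons and clusters
#'
#' Each gene goes to its best-matching hexagon (minimum Euclidean
#' distance to the codebook vector, ties to the lowest index) and inherits
#' that hexagon's cluster.
#'
#' @param matrix Genes-by-diseases rating matrix.
#' @param som A `som_codebook`.
#' @param partition A `map_partition` from [partition_map()].
#' @return A `data.frame` with `gene`, `hexagon`, `cluster`.
#' @export
assign_genes <- function(matrix, som, partition) {
  bmu <- .bmu(matrix, som$codebook)
  data.frame(gene = rownames(matrix), hexagon = bmu,
             cluster = partition$cluster[bmu], stringsAsFactors = FALSE)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining (Q-criterion agglomeration, via
#' [ape::nj()]); on an additive distance matrix the generating topology
#' and branch lengths are recovered exactly.
#'
#' @param d A `dist` or symmetric matrix of pairwise distances.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  ape::nj(d)
}

.disease_dist <- function(matrix, method) {
  if (method == "spearman") {
    rho <- suppressWarnings(cor(matrix, method = "spearman"))
    stats::as.dist(1 - rho)
  } else stats::dist(t(matrix))
}

#' Bootstrap consensus neighbour-joining tree over diseases
#'
#' Disease distance is `1 - Spearman rho` of priority ratings over genes
#' (Euclidean available). Genes are resampled with replacement `n_boot`
#' times, a neighbour-joining tree is built per replicate, and the
#' majority-rule consensus is returned with split support fractions.
#'
#' @param matrix Genes-by-diseases rating matrix (>= 3 diseases; >= 4 for
#'   a non-trivial topology).
#' @param n_boot Bootstrap replicates. Default 100.
#' @param seed Integer seed.
#' @param dist_method `"spearman"` (default) or `"euclidean"`.
#' @return A list of class `consensus_nj` with `tree` (the full-data NJ
#'   tree), `consensus` (majority-rule consensus `phylo`), and `support`
#'   (bootstrap fraction per internal edge of `tree`).
#' @export
consensus_nj <- function(matrix, n_boot = 100L, seed = 1L,
                         dist_method = c("spearman", "euclidean")) {
  dist_method <- match.arg(dist_method)
  stopifnot(is.matrix(matrix))
  if (ncol(matrix) < 3L) stop("need at least 3 diseases for a tree")
  tree <- nj_tree(.disease_dist(matrix, dist_method))
  boots <- withr::with_seed(seed, lapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(matrix), replace = TRUE)
    nj_tree(.disease_dist(matrix[idx, , drop = FALSE], dist_method))
  }))
  class(boots) <- "multiPhylo"
  cons <- ape::consensus(boots, p = 0.5)
  clade_counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  structure(list(tree = tree, consensus = cons,
                 support = clade_counts / n_boot, n_boot = n_boot),
            class = "consensus_nj")
}

#' Per-cluster over-representation enrichments
#'
#' Fisher-exact over-representation of annotation sets among a cluster's
#' genes, with the universe fixed to the genes on the map; delegates to
#' [fisher_ora()].
#'
#' @param cluster_genes Character vector of genes in the cluster.
#' @param annotations Named list of annotation gene sets.
#' @param universe All genes on the map.
#' @return An `ora_result` data.frame.
#' @export
cluster_enrichment <- function(cluster_genes, annotations, universe) {
  fisher_ora(intersect(cluster_genes, universe), annotations, universe)
}
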