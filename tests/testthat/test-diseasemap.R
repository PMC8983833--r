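# Supra-hexagonal lattice, batch SOM, topology-preserving partition,
# consensus neighbour-joining tree, and rating correlations.

test_that("lattice hexagon counts obey 1 + 3r(r-1) and the ring summation", {
  for (r in 1:10) {
    lat <- build_lattice(r)
    n <- nrow(lat$coords)
    expect_equal(n, 1 + 3 * r * (r - 1))
    expect_equal(n, 1 + 6 * sum(seq_len(r - 1)))   # independent ring sum
    # neighbor relation symmetric, at most 6 neighbors, lattice connected
    for (i in seq_len(n)) {
      expect_lte(length(lat$neighbors[[i]]), 6L)
      for (j in lat$neighbors[[i]]) expect_true(i %in% lat$neighbors[[j]])
    }
    if (r > 1) expect_true(all(is.finite(lat$dist)) && max(lat$dist) <= 2 * r)
  }
  expect_equal(nrow(build_lattice(1)$coords), 1L)
  expect_length(build_lattice(1)$neighbors[[1]], 0L)
  lat2 <- build_lattice(2)
  expect_equal(nrow(lat2$coords), 7L)
  expect_length(lat2$neighbors[[1]], 6L)            # center touches the ring
  expect_error(build_lattice(0), "radius")
})

test_that("SOM fixed points: constant data and the single-hexagon limit", {
  lat <- build_lattice(3)
  X <- matrix(2.5, nrow = 40, ncol = 4,
              dimnames = list(sprintf("g%02d", 1:40), paste0("d", 1:4)))
  som <- train_som(X, lat, epochs_rough = 5, epochs_fine = 5)
  expect_true(all(abs(som$codebook - 2.5) < 1e-9))

  lat1 <- build_lattice(1)
  withr::with_seed(10, {
    X2 <- matrix(runif(60), nrow = 15, ncol = 4,
                 dimnames = list(sprintf("g%02d", 1:15), paste0("d", 1:4)))
    som1 <- train_som(X2, lat1, epochs_rough = 3, epochs_fine = 3)
    expect_equal(as.numeric(som1$codebook), unname(colMeans(X2)), tolerance = 1e-9)
  })
})

test_that("quantization error does not increase across the fine phase", {
  withr::with_seed(77, {
    fx <- generate_rating_fixture(seed = 77, n_genes = 300)
    lat <- build_lattice(4)
    som <- train_som(fx$matrix, lat, epochs_rough = 20, epochs_fine = 40)
    fine <- som$quantization_error[(som$n_rough + 1):length(som$quantization_error)]
    expect_true(all(diff(fine) <= 1e-8))
  })
})

test_that("partitioning recovers a planted two-block codebook and is connected", {
  lat <- build_lattice(4)
  n <- nrow(lat$coords)
  # two well-separated constant halves split along the lattice x-axis
  side <- lat$xy[, "x"] >= 0
  cb <- matrix(0, n, 3)
  cb[side, ] <- 5
  som <- structure(list(codebook = cb, lattice = lat), class = "som_codebook")
  part <- partition_map(som)
  expect_equal(part$n_clusters, 2L)
  # the flat interior of each half lands wholly in one cluster (ridge
  # hexagons on the U-height watershed may drain to either basin)
  interior <- part$uheight == 0
  cl_a <- unique(part$cluster[side & interior])
  cl_b <- unique(part$cluster[!side & interior])
  expect_length(cl_a, 1L)
  expect_length(cl_b, 1L)
  expect_false(cl_a == cl_b)

  # every cluster is a connected patch of hexagons
  for (cl in seq_len(part$n_clusters)) {
    hexes <- which(part$cluster == cl)
    g <- igraph::graph_from_adjacency_matrix(
      (lat$dist[hexes, hexes, drop = FALSE] == 1) * 1, mode = "undirected")
    expect_true(igraph::is_connected(g))
  }

  # constant codebook collapses to a single cluster
  som0 <- structure(list(codebook = matrix(1, n, 3), lattice = lat),
                    class = "som_codebook")
  expect_equal(partition_map(som0)$n_clusters, 1L)
})

test_that("gene assignment maps each gene to its nearest codebook vector", {
  lat <- build_lattice(2)
  cb <- matrix(c(0, 1, 2, 3, 4, 5, 6), ncol = 1)
  som <- structure(list(codebook = cb, lattice = lat), class = "som_codebook")
  part <- structure(list(cluster = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
                         n_clusters = 2L), class = "map_partition")
  X <- matrix(c(0.1, 5.9, 3), ncol = 1,
              dimnames = list(c("a", "b", "c"), "d1"))
  asg <- assign_genes(X, som, part)
  expect_equal(asg$hexagon, c(1L, 7L, 4L))
  expect_equal(asg$cluster, c(1L, 2L, 2L))
  # identical genes get identical assignments; codebook match is exact
  X2 <- matrix(c(2, 2), ncol = 1, dimnames = list(c("x", "y"), "d1"))
  asg2 <- assign_genes(X2, som, part)
  expect_equal(asg2$hexagon, c(3L, 3L))
})

test_that("neighbour joining recovers an additive 4-taxon tree exactly", {
  # additive tree: (A:2, B:3) joined to (C:4, D:5) through an internal
  # branch of length 1
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 5
  D["A", "C"] <- D["C", "A"] <- 7
  D["A", "D"] <- D["D", "A"] <- 8
  D["B", "C"] <- D["C", "B"] <- 8
  D["B", "D"] <- D["D", "B"] <- 9
  D["C", "D"] <- D["D", "C"] <- 9
  tr <- nj_tree(D)
  # four-point condition oracle: patristic distances reproduce the input
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), colnames(D)]),
               unname(D), tolerance = 1e-10)
  # AB|CD is the unique internal split
  parts <- ape::prop.part(ape::unroot(tr))
  expect_true(any(vapply(parts, function(p)
    setequal(tr$tip.label[p], c("A", "B")) || setequal(tr$tip.label[p], c("C", "D")),
    logical(1))))
})

test_that("consensus tree over bootstraps gets full support on a clean split", {
  withr::with_seed(202, {
    n <- 200
    base1 <- rnorm(n); base2 <- rnorm(n)
    M <- cbind(A = base1 + rnorm(n, 0, 0.05), B = base1 + rnorm(n, 0, 0.05),
               C = base2 + rnorm(n, 0, 0.05), D = base2 + rnorm(n, 0, 0.05))
    rownames(M) <- sprintf("g%03d", 1:n)
    res <- consensus_nj(M, n_boot = 50, seed = 7)
    expect_s3_class(res$consensus, "phylo")
    expect_setequal(res$consensus$tip.label, c("A", "B", "C", "D"))
    # the AB|CD split survives the majority-rule consensus with support 1
    parts <- ape::prop.part(res$consensus)
    labs <- attr(parts, "labels")
    has_split <- any(vapply(parts, function(p)
      setequal(labs[p], c("A", "B")) || setequal(labs[p], c("C", "D")),
      logical(1)))
    expect_true(has_split)
    expect_true(all(res$support[!is.na(res$support)] <= 1))
    internal <- res$support[-1]       # drop the root "clade" of all tips
    expect_true(all(internal[!is.na(internal)] == 1))
  })
})

test_that("three diseases give the unique star; duplicated column pairs up", {
  withr::with_seed(17, {
    M <- matrix(runif(60), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
    res <- consensus_nj(M, n_boot = 20, seed = 1)
    expect_equal(ape::Ntip(res$tree), 3L)
    expect_equal(res$tree$Nnode, 1L)    # star topology

    M2 <- cbind(M, D = M[, "C"])        # duplicate disease column
    res2 <- consensus_nj(M2, n_boot = 30, seed = 2)
    parts <- ape::prop.part(res2$consensus)
    labs <- attr(parts, "labels")
    expect_true(any(vapply(parts, function(p)
      setequal(labs[p], c("C", "D")) ||
        setequal(labs[p], c("A", "B")), logical(1))))
    expect_error(consensus_nj(M[, 1:2, drop = FALSE]), "at least 3")
  })
})

test_that("rating correlations hit the closed-form Spearman and BH adjust", {
  g <- sprintf("g%02d", 1:10)
  x <- 1:10
  M <- cbind(ref = x, same = x, rev = rev(x), perm = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  rownames(M) <- g
  res <- rating_correlations(M, "ref")
  rho <- setNames(res$spearman_rho, res$disease)
  expect_equal(unname(rho["same"]), 1)
  expect_equal(unname(rho["rev"]), -1)
  # closed form 1 - 6 sum d^2 / (n(n^2-1)) without ties
  d2 <- sum((rank(M[, "ref"]) - rank(M[, "perm"]))^2)
  expect_equal(unname(rho["perm"]), 1 - 6 * d2 / (10 * 99))
  expect_true(all(res$fdr >= res$pvalue - 1e-12))
  expect_error(rating_correlations(cbind(ref = rep(1, 10), b = x), "ref"),
               "constant")
})

test_that("cluster enrichment counts match hand-built 2x2 tables", {
  universe <- sprintf("m%02d", 1:20)
  cluster <- universe[1:6]
  ann <- list(hit = universe[c(1:4, 15:16)], absent = c("zz1", "zz2"))
  res <- cluster_enrichment(cluster, ann, universe)
  expect_identical(res$set_name, "hit")
  expect_identical(attr(res, "skipped"), "absent")
  expect_equal(res$overlap, 4L)
  expect_equal(res$set_size, 6L)
  expect_equal(res$pvalue, phyper(3, 6, 14, 6, lower.tail = FALSE),
               tolerance = 1e-12)
})
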