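# Maximum-weight connected subnetwork search, permutation significance,
# and node-attack analysis.

test_that("an all-positive connected graph is returned whole", {
  toys <- generate_toy_graphs()
  sc <- setNames(rep(1, 5), igraph::V(toys$cycle5)$name)
  res <- search_crosstalk(toys$cycle5, sc)
  expect_setequal(res$nodes, names(sc))
  expect_equal(res$total_score, 5)
})

test_that("a mildly negative connector is traversed when the merge pays", {
  g <- igraph::graph_from_edgelist(rbind(c("A", "M"), c("M", "B")),
                                   directed = FALSE)
  sc <- c(A = 2, M = -0.5, B = 2)
  res <- search_crosstalk(g, sc)
  expect_setequal(res$nodes, c("A", "M", "B"))
  expect_equal(res$total_score, 3.5)

  # too costly a connector: keep the single best node
  sc2 <- c(A = 2, M = -5, B = 2)
  res2 <- search_crosstalk(g, sc2)
  expect_equal(res2$total_score, 2)
  expect_length(res2$nodes, 1L)

  expect_error(search_crosstalk(g, c(A = -1, M = -1, B = -1)), "positive")
})

test_that("exact search equals brute-force enumeration on random 12-node graphs", {
  withr::with_seed(808, {
    for (i in 1:20) {
      rg <- random_scored_graph(12)
      if (!any(rg$scores > 0)) next
      got <- search_crosstalk(rg$graph, rg$scores)
      want <- mwcs_brute(rg$graph, rg$scores)
      expect_equal(got$total_score, want, tolerance = 1e-9)
      expect_true(igraph::is_connected(got$graph))
    }
  })
})

test_that("the heuristic matches the exact optimum on small dense graphs", {
  withr::with_seed(809, {
    for (i in 1:10) {
      rg <- random_scored_graph(11, p_edge = 0.5)
      if (!any(rg$scores > 0)) next
      exact <- priormap:::.mwcs_exact(rg$graph, rg$scores)
      heur <- priormap:::.mwcs_heuristic(rg$graph, rg$scores)
      expect_true(heur$total_score <= exact$total_score + 1e-9)
      # heuristic output is connected and never keeps a negative leaf
      sub <- igraph::induced_subgraph(rg$graph, heur$nodes)
      expect_true(igraph::is_connected(sub))
      if (length(heur$nodes) > 1) {
        deg <- igraph::degree(sub)
        leaves <- names(deg)[deg == 1]
        expect_true(all(rg$scores[leaves] >= 0))
      }
    }
  })
})

test_that("disconnection effect matches hand values on canonical graphs", {
  toys <- generate_toy_graphs()
  expect_equal(disconnection_effect(toys$complete5, "k1"), 0.0)
  expect_equal(disconnection_effect(toys$star5, "hub"), 0.75)
  expect_equal(disconnection_effect(toys$path5, "p3"), 0.5)
  expect_equal(disconnection_effect(toys$star5, "hub", denominator = "original"),
               1 - 1 / 5)
  expect_error(disconnection_effect(toys$path5, paste0("p", 1:5)), "all nodes")
  bridge_eff <- disconnection_effect(toys$two_community, "bridge")
  expect_equal(bridge_eff, 0.5)   # two equal 5-cliques remain
})

test_that("attack rankings equal brute force and respect the fixed context", {
  toys <- generate_toy_graphs()
  res1 <- attack_combinations(toys$star5, k = 1)
  expect_identical(res1$candidate[1], "hub")
  expect_true(res1$best[1] && !any(res1$best[-1]))

  withr::with_seed(66, {
    g <- igraph::sample_gnp(15, 0.25)
    igraph::V(g)$name <- sprintf("n%02d", 1:15)
    while (!igraph::is_connected(g)) {
      g <- igraph::sample_gnp(15, 0.25)
      igraph::V(g)$name <- sprintf("n%02d", 1:15)
    }
    # k = 2 with empty context: all pairs, against exhaustive enumeration
    res2 <- attack_combinations(g, k = 2)
    expect_equal(nrow(res2), choose(15, 2))
    for (row in c(1L, 10L, nrow(res2))) {
      rm <- strsplit(res2$removed[row], ";")[[1]]
      expect_equal(res2$effect[row], disconnection_effect(g, rm))
    }
    expect_false(is.unsorted(-res2$effect))

    # fixed context node never appears among candidates
    ctx <- "n01"
    res3 <- attack_combinations(g, k = 2, fixed_context = ctx)
    expect_false(any(grepl(ctx, res3$candidate, fixed = TRUE)))
    expect_equal(nrow(res3), 14L)
    # and equals brute force over single completions
    for (row in seq_len(nrow(res3))) {
      expect_equal(res3$effect[row],
                   disconnection_effect(g, c(ctx, res3$candidate[row])))
    }

    # monotone opportunity: best k-removal effect non-decreasing in k
    e1 <- attack_combinations(g, k = 1)$effect[1]
    e2 <- attack_combinations(g, k = 2)$effect[1]
    e3 <- attack_combinations(g, k = 3)$effect[1]
    expect_true(e1 <= e2 + 1e-12 && e2 <= e3 + 1e-12)
  })
  expect_error(attack_combinations(toys$star5, k = 1, fixed_context = "hub"),
               "at most k - 1")
})

test_that("permutation significance reports both tails coherently", {
  withr::with_seed(99, {
    rg <- random_scored_graph(10, p_edge = 0.4)
    rg$scores <- abs(rg$scores)   # make the observed subgraph strong
    sig <- crosstalk_significance(rg$graph, rg$scores, n_perm = 100, seed = 4)
    expect_true(sig$empirical_p > 0 && sig$empirical_p <= 1)
    expect_equal(sig$observed, search_crosstalk(rg$graph, rg$scores)$total_score)

    # doubling the scores leaves the empirical permutation rank unchanged
    sig2 <- crosstalk_significance(rg$graph, rg$scores * 2, n_perm = 100, seed = 4)
    expect_equal(sig2$empirical_p, sig$empirical_p)

    # an observed score below the null mean lands in the upper tail p > 0.5
    g2 <- igraph::make_ring(8); igraph::V(g2)$name <- paste0("r", 1:8)
    sc <- setNames(c(0.1, rep(-2, 7)), paste0("r", 1:8))
    sig3 <- crosstalk_significance(g2, sc, n_perm = 100, seed = 5)
    expect_gte(sig3$empirical_p, 0.5)
  })
})

test_that("empirical significance is valid under the permutation null", {
  # The null distribution of the subgraph score has an atom (whenever all
  # positive-scored nodes fall in one connected component the total is
  # identical), so the tie-inclusive empirical p is conservative rather
  # than exactly uniform; validity P(p <= alpha) <= alpha is the
  # guaranteed property.
  withr::with_seed(123, {
    g <- igraph::sample_gnp(8, 0.35)
    igraph::V(g)$name <- paste0("v", 1:8)
    base <- setNames(rnorm(8), igraph::V(g)$name)
    pvals <- vapply(1:100, function(i) {
      obs_scores <- setNames(sample(base), names(base))  # a null draw itself
      crosstalk_significance(g, obs_scores, n_perm = 100,
                             seed = 5000 + i)$empirical_p
    }, numeric(1))
    for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
      se <- sqrt(alpha * (1 - alpha) / length(pvals))
      expect_lte(mean(pvals <= alpha), alpha + 2.5 * se)
    }
    expect_gt(stats::sd(pvals), 0.1)   # spread, not degenerate
  })
})

test_that("scored-network construction thresholds at the rating quantile", {
  withr::with_seed(31, {
    g <- igraph::sample_gnp(30, 0.2)
    igraph::V(g)$name <- sprintf("g%02d", 1:30)
    pt <- rate_genes(setNames(runif(30, 0, 10), igraph::V(g)$name))
    sn <- score_crosstalk_network(g, pt, quantile = 0.9)
    expect_equal(sum(sn$scores > 0), sum(pt$rating > sn$threshold))
    expect_setequal(names(sn$scores), igraph::V(sn$graph)$name)
    # restricting to pathway genes shrinks the node set
    paths <- list(P1 = sprintf("g%02d", 1:12))
    sn2 <- score_crosstalk_network(g, pt, pathway_sets = paths)
    expect_true(all(igraph::V(sn2$graph)$name %in% paths$P1))
  })
})
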