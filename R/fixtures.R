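# Synthetic input generator. Produces desk-scale inputs carrying the
# statistical structure the prioritization assumes -- planted causal genes
# reachable proximally (nGene) or only distally via Hi-C/eQTL links
# (cGene/eGene), LD-blocked variants, a scale-free interaction network with
# a planted module, drug-target labels -- plus the truth wiring, so every
# stage is testable without external downloads.

#' Specification of the prioritization fixture
#'
#' @param seed Integer master seed; per-table substreams are derived from
#'   it so adding a table never perturbs the others.
#' @param n_genes,n_chromosomes,n_variants,n_planted Problem sizes.
#' @param frac_distal Fraction of planted genes wired only distally
#'   (split between Hi-C and eQTL channels).
#' @param ld_block_size Variants per LD block.
#' @param network_attachment Preferential-attachment edges per node.
#' @param gene_spacing Approximate TSS spacing in bp.
#' @param n_decoy_hic,n_decoy_eqtl Decoy regulatory links.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 2000L, n_chromosomes = 4L,
                         n_variants = 5000L, n_planted = 25L,
                         frac_distal = 0.4, ld_block_size = 10L,
                         network_attachment = 3L, gene_spacing = 50000L,
                         n_decoy_hic = 200L, n_decoy_eqtl = 300L) {
  stopifnot(n_planted < n_genes, n_genes > 0, n_variants > 0,
            n_chromosomes > 0, frac_distal >= 0, frac_distal <= 1,
            ld_block_size > 0, network_attachment > 0)
  structure(as.list(environment()), class = "fixture_spec")
}

.sub_seed <- function(seed, offset) (as.integer(seed) * 101L + offset) %% 2000000000L

#' Generate the full prioritization fixture
#'
#' Lays out genes with TSS every ~`gene_spacing` bp across chromosomes;
#' draws variants in LD blocks (within-block r-squared high, cross-block
#' absent) with background p-values uniform on (0,1); plants `n_planted`
#' causal genes, each receiving one lead variant with `p = 10^U`,
#' `U ~ Unif(-12, -8)` -- within the proximity window for proximal genes,
#' beyond it (and clear of every other planted window) for distal genes,
#' which are instead wired through a high-score Hi-C fragment overlapping
#' the lead or an eQTL record; adds decoy Hi-C/eQTL links; builds a
#' preferential-attachment interaction network with the planted genes
#' rewired into one dense module; and marks 60 percent of planted genes
#' plus 5 random non-planted genes as phase >= 2 drug targets.
#'
#' @param spec A [fixture_spec()].
#' @param cfg A [predictor_config()]; its `ngene_window` defines
#'   proximal/distal geometry.
#' @return A list with `genes`, `variants`, `ld`, `hic`, `eqtl`,
#'   `network` (igraph), `drug_targets`, `truth` (data.frame gene/wiring),
#'   `spec`.
#' @export
generate_prioritization_fixture <- function(spec = fixture_spec(),
                                            cfg = predictor_config()) {
  window <- cfg$ngene_window
  per_chrom <- ceiling(spec$n_genes / spec$n_chromosomes)
  chrom_len <- (per_chrom + 2L) * spec$gene_spacing
  if (chrom_len <= 2 * window)
    stop("infeasible geometry: chromosome shorter than twice the proximity window")

  # -- genes ---------------------------------------------------------------
  genes <- withr::with_seed(.sub_seed(spec$seed, 1L), {
    idx <- seq_len(spec$n_genes)
    chrom <- paste0("chr", ((idx - 1L) %/% per_chrom) + 1L)
    within <- ((idx - 1L) %% per_chrom) + 1L
    tss <- within * spec$gene_spacing +
      as.integer(round(runif(spec$n_genes, -0.2, 0.2) * spec$gene_spacing))
    data.frame(gene = sprintf("G%04d", idx), chromosome = chrom,
               tss = pmax(tss, 1L),
               strand = sample(c("+", "-"), spec$n_genes, replace = TRUE),
               stringsAsFactors = FALSE)
  })

  # planted genes spaced > 2 windows apart so their evidence never overlaps
  min_gap <- ceiling(2 * window / spec$gene_spacing) + 2L
  planted <- withr::with_seed(.sub_seed(spec$seed, 2L), {
    stride <- max(min_gap, floor(spec$n_genes / spec$n_planted))
    start <- sample.int(stride, 1L)
    idx <- (start + (0:(spec$n_planted - 1L)) * stride - 1L) %% spec$n_genes + 1L
    genes$gene[sort(idx)]
  })
  n_distal <- round(spec$frac_distal * spec$n_planted)
  wiring <- withr::with_seed(.sub_seed(spec$seed, 3L), {
    w <- rep("proximal", spec$n_planted)
    if (n_distal > 0) {
      di <- sample(seq_len(spec$n_planted), n_distal)
      w[di] <- rep(c("distal_hic", "distal_eqtl"), length.out = n_distal)
    }
    w
  })
  truth <- data.frame(gene = planted, wiring = wiring, stringsAsFactors = FALSE)

  # -- variants in LD blocks ----------------------------------------------
  n_blocks <- ceiling(spec$n_variants / spec$ld_block_size)
  tab <- withr::with_seed(.sub_seed(spec$seed, 4L), {
    bchrom <- paste0("chr", sample.int(spec$n_chromosomes, n_blocks, replace = TRUE))
    banchor <- as.integer(runif(n_blocks, 1, chrom_len - 60000))
    vid <- 0L
    rows <- vector("list", n_blocks)
    ld_rows <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      m <- min(spec$ld_block_size, spec$n_variants - vid)
      ids <- sprintf("rs%06d", vid + seq_len(m))
      pos <- banchor[b] + as.integer(sort(runif(m, 0, 50000)))
      rows[[b]] <- data.frame(variant_id = ids, chromosome = bchrom[b],
                              position = pos,
                              pvalue = runif(m), block = b,
                              stringsAsFactors = FALSE)
      if (m >= 2L) {
        pr <- t(combn(ids, 2L))
        ld_rows[[b]] <- data.frame(variant_a = pr[, 1L], variant_b = pr[, 2L],
                                   r2 = runif(nrow(pr), 0.8, 1),
                                   stringsAsFactors = FALSE)
      }
      vid <- vid + m
    }
    list(variants = do.call(rbind, rows), ld = do.call(rbind, ld_rows))
  })
  variants <- tab$variants
  ld <- tab$ld

  # -- plant lead variants and distal wiring -------------------------------
  planted_tss <- setNames(genes$tss[match(planted, genes$gene)], planted)
  planted_chrom <- setNames(genes$chromosome[match(planted, genes$gene)], planted)
  reserved <- data.frame(chromosome = planted_chrom, tss = planted_tss)
  hic_rows <- list(); eqtl_rows <- list()
  lead_ids <- character(spec$n_planted)
  set_pos <- withr::with_seed(.sub_seed(spec$seed, 5L), {
    for (i in seq_len(spec$n_planted)) {
      g <- planted[i]
      vi <- (i - 1L) * spec$ld_block_size + 1L   # head of its own LD block
      bidx <- vi:min(vi + spec$ld_block_size - 1L, spec$n_variants)
      lead_ids[i] <- variants$variant_id[vi]
      variants$pvalue[vi] <- 10^runif(1, -12, -8)
      variants$chromosome[bidx] <- planted_chrom[g]
      if (wiring[i] == "proximal") {
        off <- sample(c(-1, 1), 1L) * as.integer(runif(1, 1000, 0.4 * window))
        lead_pos <- max(1L, planted_tss[g] + off)
      } else {
        # beyond the window (plus the LD-block span) from every planted TSS
        # on the chromosome, including the gene's own
        lead_pos <- NA_integer_
        for (try in 1:200) {
          cand <- as.integer(runif(1, 60001, chrom_len - 60000))
          same <- reserved$chromosome == planted_chrom[g]
          if (all(abs(reserved$tss[same] - cand) > window + 60000)) {
            lead_pos <- cand; break
          }
        }
        if (is.na(lead_pos))
          stop("infeasible geometry: no distal placement clear of planted windows")
        if (wiring[i] == "distal_hic") {
          hic_rows[[g]] <- data.frame(
            fragment_chrom = planted_chrom[g],
            fragment_start = max(0L, lead_pos - 2000L),
            fragment_end = lead_pos + 2000L,
            gene = g, link_score = runif(1, 5, 10), stringsAsFactors = FALSE)
        } else {
          eqtl_rows[[g]] <- data.frame(
            variant_id = lead_ids[i], gene = g,
            eqtl_pvalue = 10^runif(1, -10, -6), stringsAsFactors = FALSE)
        }
      }
      # the whole LD block rides along with its lead
      variants$position[bidx] <- lead_pos +
        c(0L, as.integer(sort(runif(length(bidx) - 1L, 1, 50000))))
    }
    list(variants = variants, hic = hic_rows, eqtl = eqtl_rows)
  })
  variants <- set_pos$variants
  variants$block <- NULL

  # -- decoy regulatory links ----------------------------------------------
  decoys <- withr::with_seed(.sub_seed(spec$seed, 6L), {
    dh <- data.frame(
      fragment_chrom = paste0("chr", sample.int(spec$n_chromosomes,
                                                spec$n_decoy_hic, replace = TRUE)),
      fragment_start = as.integer(runif(spec$n_decoy_hic, 0, chrom_len - 4000)),
      gene = sample(genes$gene, spec$n_decoy_hic, replace = TRUE),
      link_score = runif(spec$n_decoy_hic, 0.5, 3), stringsAsFactors = FALSE)
    dh$fragment_end <- dh$fragment_start + 4000L
    de <- data.frame(
      variant_id = sample(variants$variant_id, spec$n_decoy_eqtl, replace = TRUE),
      gene = sample(genes$gene, spec$n_decoy_eqtl, replace = TRUE),
      eqtl_pvalue = runif(spec$n_decoy_eqtl, 1e-4, 1), stringsAsFactors = FALSE)
    list(hic = dh[, c("fragment_chrom", "fragment_start", "fragment_end",
                      "gene", "link_score")], eqtl = de)
  })
  hic <- rbind(do.call(rbind, set_pos$hic), decoys$hic)
  eqtl <- rbind(do.call(rbind, set_pos$eqtl), decoys$eqtl)
  rownames(hic) <- rownames(eqtl) <- NULL

  # -- interaction network -------------------------------------------------
  network <- withr::with_seed(.sub_seed(spec$seed, 7L), {
    g <- igraph::sample_pa(spec$n_genes, m = spec$network_attachment,
                           directed = FALSE)
    igraph::V(g)$name <- sample(genes$gene)
    module <- t(combn(planted, 2L))
    pick <- runif(nrow(module)) < 0.3
    g <- igraph::add_edges(g, t(module[pick, , drop = FALSE]))
    igraph::simplify(g)
  })

  # -- drug-target labels --------------------------------------------------
  drug_targets <- withr::with_seed(.sub_seed(spec$seed, 8L), {
    poc <- c(sample(planted, round(0.6 * spec$n_planted)),
             sample(setdiff(genes$gene, planted), 5L))
    rows <- lapply(seq_along(poc), function(i) {
      nd <- sample.int(3L, 1L)
      data.frame(gene = poc[i], drug = sprintf("drug_%s_%d", poc[i], seq_len(nd)),
                 max_phase = sample(2:4, nd, replace = TRUE),
                 mechanism = "inhibitor", indication = "index disease",
                 stringsAsFactors = FALSE)
    })
    low <- sample(setdiff(genes$gene, poc), 30L)
    rows_low <- data.frame(gene = low, drug = sprintf("drug_%s_1", low),
                           max_phase = sample(0:1, 30L, replace = TRUE),
                           mechanism = "binder", indication = "other",
                           stringsAsFactors = FALSE)
    do.call(rbind, c(rows, list(rows_low)))
  })

  list(genes = genes, variants = variants, ld = ld, hic = hic, eqtl = eqtl,
       network = network, drug_targets = drug_targets, truth = truth,
       spec = spec)
}

#' Generate a cross-disease rating matrix with planted blocks
#'
#' Emulates a top-slice prioritization matrix across diseases: a
#' shared-high block (high ratings in every disease), a disease-specific
#' block (high in `specific_disease` only), and low background ratings
#' with Gaussian noise, all clipped to \[0, 5\].
#'
#' @param seed Integer seed.
#' @param n_genes,n_diseases Matrix dimensions (defaults 689 x 7).
#' @param n_shared,n_specific Block sizes.
#' @param specific_disease Column index of the disease-specific block.
#' @param high_mean,background_mean,noise_sd Rating level parameters.
#' @return A list with `matrix` (genes x diseases) and `truth`
#'   (data.frame gene/block in `shared`, `specific`, `background`).
#' @export
generate_rating_fixture <- function(seed = 1L, n_genes = 689L, n_diseases = 7L,
                                    n_shared = 60L, n_specific = 60L,
                                    specific_disease = 1L, high_mean = 4.2,
                                    background_mean = 1.2, noise_sd = 0.5) {
  stopifnot(n_shared + n_specific <= n_genes, specific_disease <= n_diseases)
  withr::with_seed(seed, {
    M <- matrix(rnorm(n_genes * n_diseases, background_mean, noise_sd),
                nrow = n_genes)
    shared <- seq_len(n_shared)
    specific <- n_shared + seq_len(n_specific)
    M[shared, ] <- rnorm(n_shared * n_diseases, high_mean, noise_sd / 2)
    M[specific, specific_disease] <- rnorm(n_specific, high_mean, noise_sd / 2)
    M <- pmin(pmax(M, 0), 5)
    rownames(M) <- sprintf("G%04d", seq_len(n_genes))
    colnames(M) <- c("index", paste0("D", seq_len(n_diseases - 1L)))[seq_len(n_diseases)]
    block <- rep("background", n_genes)
    block[shared] <- "shared"; block[specific] <- "specific"
    list(matrix = M,
         truth = data.frame(gene = rownames(M), block = block,
                            stringsAsFactors = FALSE))
  })
}

#' Small named graphs for crosstalk and attack tests
#'
#' @return Named list of `igraph` objects: `star5` (hub + 4 leaves),
#'   `path5`, `cycle5`, `complete5`, and `two_community` (two 5-cliques
#'   joined through a single bridge node).
#' @export
generate_toy_graphs <- function() {
  star5 <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star5)$name <- c("hub", paste0("leaf", 1:4))
  path5 <- igraph::make_ring(5, circular = FALSE)
  igraph::V(path5)$name <- paste0("p", 1:5)
  cycle5 <- igraph::make_ring(5)
  igraph::V(cycle5)$name <- paste0("c", 1:5)
  complete5 <- igraph::make_full_graph(5)
  igraph::V(complete5)$name <- paste0("k", 1:5)
  a <- paste0("a", 1:5); b <- paste0("b", 1:5)
  edges <- rbind(t(combn(a, 2)), t(combn(b, 2)),
                 c("a1", "bridge"), c("bridge", "b1"))
  two_community <- igraph::graph_from_edgelist(edges, directed = FALSE)
  list(star5 = star5, path5 = path5, cycle5 = cycle5, complete5 = complete5,
       two_community = two_community)
}
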