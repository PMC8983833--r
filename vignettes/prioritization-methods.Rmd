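---
title: "Genomics-led target prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomics-led target prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priormap)
```

# The prioritization model

`priormap` scores every gene on a protein-protein interaction network for
its likelihood of being a useful therapeutic target in a disease, starting
from nothing but GWAS summary statistics and variant-to-gene regulatory
links. The model has three stages.

**Stage 1 — seed-score predictors.** Genome-wide significant variants
(`pvalue < 5e-8` by default) are expanded through linkage disequilibrium
(proxies at r² ≥ 0.8) and mapped to genes through three independent
evidence channels:

* *nGene* (proximity): a gene receives the best score
  $w(v)\,d(v,g)$ over variants $v$ within 500 kb of its TSS, where
  $w(v) = \min(-\log_{10} p_v, 12)/12$ caps the GWAS evidence and
  $d(v,g) = 1 - \mathrm{dist}/\mathrm{window}$ decays linearly with
  distance (an exponential decay is available).
* *cGene* (chromatin conformation): a gene linked to a promoter-capture
  Hi-C fragment is scored $w(v) \cdot s$ for the best variant falling in
  the fragment, with the link score $s$ rescaled to (0, 1] within its
  dataset.
* *eGene* (expression): a gene with an eQTL whose variant is in the
  expanded set is scored by the capped, rescaled $-\log_{10}$ eQTL
  p-value.

Each predictor is min–max normalized so its best gene scores exactly 1.
The seed-scoring formulas are design choices of this package: the capped
log-p weight keeps a single ultra-significant locus from dominating, and
the within-table rescaling makes heterogeneous Hi-C scoring schemes
comparable. All knobs live in `predictor_config()`.

One direction deserves a note: LD "expansion at r² < 0.8" would include
essentially all variants and contradict the meaning of linkage
disequilibrium, so proxies are included at r² **≥** `r2_min` (default
0.8), the convention of standard proxy-lookup pipelines.

**Stage 2 — network propagation.** Each predictor's seeds are diffused
over the interaction network by random walk with restart,

$$p \leftarrow (1 - r)\,W p + r\,p_0,$$

with $W$ the column-stochastic (degree-normalized, edge-weighted when
weights exist) transition operator, $p_0$ the seeds renormalized to sum
1, restart probability $r = 0.75$ (the usual value for gene networks;
higher $r$ stays closer to the seeds), and convergence at
$\lVert\Delta p\rVert_1 < 10^{-10}$ (at most 1000 iterations, error on
failure). Every affinity vector sums to 1, and `rwr()` is verified in the
tests against the analytic fixed point
$r\,(I - (1-r)W)^{-1} p_0$. The candidate universe is the network's node
set; genes off the network are not scored.

**Stage 3 — evaluation and combination.** A random forest separating
proof-of-concept targets (genes with a drug at clinical phase ≥ 2) from
seeded random controls (10 controls per positive) measures each
predictor's permutation importance — the mean decrease in out-of-bag
accuracy when that predictor's values are shuffled, i.e. the accuracy
lost by disabling it. The conventional proximity predictor is the
baseline: regulatory predictors are kept only if no less important than
*nGene*. Surviving affinities are rank-transformed per predictor
($p_g = \mathrm{rank}/N$, descending affinity, average ranks on ties,
$p = 1$ for zero affinity) and combined by one of:

* direct: `sum`, `max`, or the Open Targets-style `harmonic` sum
  $\sum_i s_{(i)}/i^2$ over each gene's scores sorted descending;
* meta-analysis: Fisher ($-2\sum\ln p$ on $\chi^2_{2k}$), logistic
  (Mudholkar–George, Student-t with $5k+4$ df), or the joint
  **order statistic** $Q = k!\,V_k$ with
  $V_i = \sum_{j=1}^{i} (-1)^{j-1} \frac{V_{i-j}}{j!} r_{k-i+1}^j$
  over the sorted rank ratios $r_1 \le \dots \le r_k$ (the default, and
  the best-performing combination in this framework's benchmarks).

$Q$ is the joint lower-tail probability of the order statistics under
independence, but for small $k$ its distribution is far from uniform, so
it is calibrated to an empirical p-value against a seeded Monte-Carlo
table of 100 000 draws of $k$ uniforms (cached per $k$). The tail beyond
the table resolution is floored at $1/(n_{\mathrm{null}}+1)$; the
combined score is $-\log_{10} p$. The final **priority rating** min–max
rescales combined scores to [0, 5]; ranks are unique, with ties broken
lexicographically by gene symbol so that outputs are byte-stable.

# Benchmarking

`roc_auc()` uses the Mann–Whitney form (ties get half credit), so AUC is
threshold-free and invariant under monotone transforms; `pr_fmax()`
sweeps every distinct score threshold for the maximum harmonic mean of
precision and recall. The `naive_scores()` baseline counts distinct drugs
already targeting a gene — the repurposing-only strategy a genetics-led
prioritization must beat to propose genuinely new targets.

# Enrichment at the leading prioritization

`leading_enrichment()` runs a weighted Kolmogorov–Smirnov statistic over
the ranked gene list: hits increment by $\mathrm{rating}^\theta$
(normalized over set members), misses uniformly over non-members;
$\theta = 1$ by default and $\theta = 0$ recovers the classic unweighted
statistic. The *leading prioritization* of a positively enriched set is
its members ranked at or before the ES peak — the core genes carrying
the signal. Because the input is a single ranked list (not per-sample
expression), the permutation null shuffles gene labels; NES divides ES
by the mean |permuted ES| of matching sign and FDR follows the standard
pooled-NES procedure. Sets overlapping the list in fewer than 3 genes
are skipped and recorded. Thresholded analyses use `top_fraction()`
slices (top 10% for hallmark-style collections, top 1% for pathway
over-representation, top 5% for the cross-disease map) with one-sided
Fisher/hypergeometric tests and Benjamini–Hochberg FDR; odds ratios use
a Haldane 0.5 correction when a cell of the 2×2 table is zero.

# Pathway crosstalk and attack analysis

`score_crosstalk_network()` restricts the network to enriched-pathway
genes and scores each node `rating - threshold`, the threshold being the
90th-percentile rating among those nodes (configurable), so only highly
prioritized genes score positive. `search_crosstalk()` then finds a
connected subgraph maximizing the total node score:

* networks of ≤ 15 nodes are solved **exactly** by enumerating all node
  subsets with bitmask connectivity checks (a positive-part upper bound
  prunes most subsets);
* larger networks use a deterministic heuristic: seed at each connected
  component of positive-score nodes, connect components through
  lowest-penalty paths (traversing a node costs
  $\max(0, -\mathrm{score}) + 10^{-6}$, the epsilon breaking zero-cost
  ties deterministically), accept a merge only if it raises the total,
  and finally prune negative-score leaves.

Significance permutes node scores across nodes and refits the null total
scores with a normal distribution: the parametric upper tail can resolve
extreme significance far beyond the $1/(n_{\mathrm{perm}}+1)$
permutation resolution, and the empirical p-value is always reported
alongside. The permutation null has a point mass (whenever all
positive-scored nodes are mutually connectable the optimum is the same
sum), so the empirical p is conservative rather than exactly uniform —
the tests check validity, $P(p \le \alpha) \le \alpha$, not uniformity.

The disconnection effect of removing a node set is
$1 - |\mathrm{LCC}|/(|V| - |\mathrm{removed}|)$; dividing by the
original $|V|$ instead is available via `denominator = "original"`
(reported single-node effects in the 10% range are consistent with the
remaining-node convention on a ~30-node crosstalk).
`attack_combinations()` enumerates every completion of a $k$-node
removal given up to $k-1$ fixed context nodes (an empty context
enumerates all $\binom{n}{k}$ combinations), sorted by effect with
lexicographic tie-breaks.

# Cross-disease prioritization map

The supra-hexagonal lattice has a central hexagon plus $r - 1$ complete
rings — $1 + 3r(r-1)$ hexagons, 91 at the default radius 6. The
self-organizing map is trained in **batch** mode with a deterministic
initialization (codebook interpolated along the data's first two
principal axes over the lattice layout), so training needs no seed and
is exactly reproducible: a rough phase shrinks the Gaussian neighborhood
radius linearly from the lattice radius to 1 over 50 epochs, a fine
phase from 1 to 0.5 over 100 epochs; each epoch assigns genes to their
best-matching hexagon (ties to the lowest index) and replaces each
codebook vector by the neighborhood-weighted mean of assigned genes.

Clusters come from a watershed on the **U-height** (mean codebook
distance of a hexagon to its lattice neighbors): adjacent hexagons of
exactly equal U-height are contracted into plateaus, local-minimum
plateaus seed basins, and every plateau drains to its lowest neighbor,
which makes every cluster a connected patch by construction. When a
target cluster count is requested, the closest pair of lattice-adjacent
clusters (by seed codebook distance) is merged repeatedly; restricting
merges to adjacent clusters is what preserves the connected-patch
invariant. The natural basin count is the default — a fixed count like 6
is a property of particular data, not of the method.

Disease relationships use Spearman correlation of ratings
(`rating_correlations()`, BH-adjusted) and a bootstrap consensus
neighbour-joining tree: distance $1 - \rho_{\mathrm{Spearman}}$ between
disease columns (Euclidean available), genes resampled with replacement,
majority-rule consensus with split support fractions. Neighbour joining
itself is delegated to `ape::nj()`, which recovers additive trees
exactly.

# What the synthetic generator emulates — and what it does not

`generate_prioritization_fixture()` builds, deterministically per seed
(each table draws from its own derived substream, so adding a table
never perturbs the others):

* 2000 genes, TSS every ~50 kb across 4 chromosomes; 5000 variants in
  LD blocks of 10 (within-block r² ~ U(0.8, 1), no cross-block LD);
  background p-values uniform on (0, 1);
* 25 planted causal genes spaced more than two proximity windows apart,
  each with one lead variant at $p = 10^{U}$, $U \sim U(-12, -8)$, its
  whole LD block riding along. 40% (configurable) are *distal-only*:
  their lead lies beyond the 500 kb window of every planted TSS and the
  gene is reachable only through a high-score Hi-C fragment over the
  lead or a strong eQTL record;
* 200 decoy Hi-C links and 300 decoy eQTLs at unrelated genes;
* a preferential-attachment (scale-free) network with the planted genes
  rewired into one dense module (pairwise edge probability 0.3);
* drug-target labels: 60% of planted genes plus 5 random non-planted
  genes carry phase ≥ 2 drugs; 30 more genes carry phase 0–1 drugs.

These sizes keep a full pipeline run under ~10 s on one CPU while still
exercising every code path; the test suite runs 5 seeds end to end. What
the generator does **not** model: realistic human LD decay and allele
frequencies, genomic clustering of functionally related genes,
cell-type-specific regulatory sharing, correlated predictors, or
annotation noise in drug-target tables. Recovery results on fixtures
(AUC ≈ 1 for planted genes) therefore demonstrate correctness of the
machinery, not expected real-data performance, where signal-to-noise is
far lower and the proof-of-concept label set is tiny and biased toward
well-studied genes.

`generate_rating_fixture()` emulates a 689-gene × 7-disease rating
matrix with a shared-high block (high in all diseases), a
disease-specific block (high in one disease only) and noisy background —
the structure that a cross-disease map should separate into distinct
connected clusters.

# Numerical choices and degenerate inputs

* Convergence: RWR tol $10^{-10}$ (L1), max 1000 iterations, hard error
  on failure. Isolated network nodes get a self-transition of 1 so the
  operator stays stochastic.
* p-values are validated into (0, 1]; the logistic combiner clamps to
  $[10^{-16}, 1 - 10^{-16}]$ before the logit.
* Constant predictor columns: importance 0 with a warning at the
  random-forest stage; a hard error at the rank-transform stage (the
  predictor should have been dropped).
* All-equal combined scores cannot be rated (error); all-zero seed
  vectors cannot be normalized (error).
* Ties: BMU and rank ties break to the lowest index / lexicographic
  gene symbol everywhere, making every output deterministic.
* Results tables are written with reals at 10 significant digits;
  rewriting with the same inputs is byte-identical, and the YAML
  manifest records seed, parameters and MD5 checksums.

# Known limitations

* The importance filter compares predictors on a label set that is
  itself derived from drug-target annotations; with very few positives
  the random-forest importances are noisy and the filter may drop a
  genuinely informative predictor. The filter can be disabled
  (`filter_predictors = FALSE`).
* Order-statistic p-values are floored at $1/(n_{\mathrm{null}}+1)$;
  genes tied at the floor are ordered by their $Q$ statistic only
  through the rating's tie rule.
* The crosstalk heuristic is exact only up to 15 nodes; above that it
  is a greedy merge with no optimality guarantee (the tests verify it
  matches the exact optimum on small dense graphs).
* Cross-chromosome Hi-C links are honored as given; the package does
  not check fragment/gene chromosome consistency beyond the join.
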