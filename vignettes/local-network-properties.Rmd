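---
title: "Local network properties from metacommunity metawebs: models and methods"
author: "localweb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local network properties from metacommunity metawebs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
association model, the metaweb-to-local projection, the null models, the
downstream statistics, the synthetic benchmark, and the numerical and
design choices behind each. Nothing here reports an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The association model

All inference starts from a presence/absence matrix: counts are rarefied
to a common depth, low-prevalence OTUs are removed, and positive counts
become 1. Working on occupancy rather than abundance avoids the
compositionality problems of correlation-based association inference on
relative abundances, at the cost of discarding abundance information.

For two OTUs occupying $n_1$ and $n_2$ of $N$ samples, the number of
shared samples under independent placement is hypergeometric:

$$P(J=j) = \frac{\binom{n_1}{j}\binom{N-n_1}{n_2-j}}{\binom{N}{n_2}}.$$

The package evaluates this in log-space via `lchoose()` so that surveys
of hundreds of sites with occupancies up to $N$ are handled without
overflow; the test suite pins the implementation against exhaustive
enumeration of all site placements for $N \le 8$ and against the
closed-form hypergeometric for random tuples up to $N = 200$.

Both tail probabilities include the observed count, so
$p_{lt} + p_{gt} = 1 + P(J = j_{obs})$ — a pair can never be classified
both positive and negative at any $\alpha < 0.5$. Decisions taken where
the procedure leaves room:

* **Inclusive tails**, the convention of the standard implementations of
  this model.
* **No multiple-testing correction by default**: raw pairwise tails are
  thresholded at $\alpha = 0.05$. A Benjamini–Hochberg option exists
  (`fdr = TRUE`) but is off, matching the thresholding convention this
  analysis family uses; with tens of thousands of pairs, users should be
  aware the edge sets contain a known false-positive fraction (the
  calibration test bounds it near $2\alpha$ under independence).
* **Pairs without variation** ($n \in \{0, N\}$) are classified `none`:
  no variation, no evidence.
* Pairs with expected co-occurrence below 1 are **not excluded**; a
  `flag_low_expectation` option marks them instead.

## 2. Rarefaction and filtering

* `rarefy_counts()` draws, per sample, a single uniform subsample of
  reads without replacement, summing exactly to the depth (default
  20,000). Samples below depth are dropped with a logged count — keeping
  them unrarefied would break the equal-detectability premise of the
  occupancy model. A property test checks the draw is hypergeometric in
  expectation over 200 seeds.
* `prevalence_filter()` keeps OTUs present in at least 2% of samples
  (inclusive boundary), applied per stratum, after rarefaction. The
  Mantel screen (`mantel_test()` of Bray–Curtis dissimilarities before
  vs after filtering) is the recommended check that the filtered matrix
  still represents the full communities; the suite requires $r > 0.9$ on
  the synthetic benchmark.
* Alpha diversity is computed on the rarefied, *unfiltered* matrix
  (nats; the log base is a convention choice). Association inference uses
  the rarefied, filtered, binarized matrix. Ordinations default to
  rarefied counts.

## 3. Metawebs, modules, and graph metrics

Significant pairs are assembled per stratum into a signed metaweb whose
node set is the whole filtered OTU pool — edge-less species stay in the
node list because they enter the denominators of edge proportions.

Modules are detected on the **positive subgraph only**: modularity of
signed graphs is not defined for the random-walk method used here, so
negative edges are kept as an overlay for reporting. `walktrap_communities()`
wraps the cited random-walk agglomerative algorithm (igraph's
implementation, $t = 4$ steps by default) and recomputes the partition's
$Q$ with the package's own `newman_modularity()`, so the "partition Q
equals the modularity formula" invariant holds identically. The
implementation is deterministic; a `seed` argument exists only for
interface symmetry.

Graph metrics follow these conventions, each checked against brute-force
oracles (triangle counting, BFS, Floyd–Warshall, the direct $Q$ double
sum) on random graphs:

* *Clustering* is average transitivity over nodes of degree ≥ 2; if no
  node is eligible the value is missing, never 0.
* *Average path length* is the mean geodesic over connected pairs only —
  unreachable pairs are excluded, not infinite, which keeps the metric
  meaningful on disconnected local networks.
* *Components* are counted on the non-isolated node set.
* *Edge proportion* divides by $\binom{S}{2}$ with $S$ the species pool
  size passed in, not the connected-node count.

## 4. Local projection

`local_profile()` induces each sign's subgraph on the sample's species
and computes the metrics above with $S$ = the sample's OTUs inside the
*filtered* metaweb universe (a `raw` denominator is available in the CLI
for sensitivity analysis). Local modularity is the walktrap $Q$ of the
local subgraph, recomputed locally rather than inherited from metaweb
modules. Isolated species count in $S$ but not in the graph metrics.
Samples with fewer than two metaweb species cannot have proportions and
are reported missing, never zero. Two exact invariants anchor the
projection: induced edge counts are monotone over nested species sets,
and a sample containing every metaweb node reproduces the metaweb's
global properties identically.

## 5. Null models

`null_zscores()` draws equal-richness species sets from the metaweb node
pool uniformly without replacement (default 1,000 randomizations),
recomputes the requested properties per draw, and reports
$z = (obs - \bar{x}_{null}) / s_{null}$ with the $n-1$ standard
deviation. The paper-family convention $|z| > 2$ gives the deviation
bands (`higher` / `lower` / `within`, band edges counting as within).
Decisions:

* "Randomizing a sample across the metaweb" is read as uniform
  equal-richness node resampling — it preserves richness and destroys
  identity. An occurrence-frequency-weighted mode (`weights =`) is
  provided since the choice is not forced; a degree-preserving null is
  deliberately absent.
* Draws where a property is undefined (e.g. an empty induced subgraph)
  are excluded from that property's null distribution, with the used
  count reported.
* A degenerate null ($s_{null} = 0$, e.g. the sample contains the whole
  pool) flags $z$ as undefined rather than propagating NaN.

## 6. Downstream statistics

* **Property correlations**: Spearman, per stratum and pooled; a pair is
  flagged a relationship iff $|r| > 0.5$ in at least one stratum *and*
  $p < 0.01$ — the joint rule is reproduced verbatim, and no further
  multiplicity correction is layered on top.
* **Ordination statistics**: nMDS (Bray–Curtis, $k = 2$, 20 random
  restarts, stress reported), ANOSIM (Clarke's $R$ with denominator
  $n(n-1)/4$, so perfect separation gives $R = 1$), Mantel, and
  betadispersion (PCoA distance to group centroid) — via vegan where the
  computation is vegan's, in-package where exhaustive permutation
  enumeration is needed. Permutation tests enumerate the full space when
  it has at most $7! = 5040$ orderings (p-values exact), and otherwise
  use seeded random permutations with the $(hits+1)/(B+1)$ estimator.
* **Variation partitioning**: redundancy fits of the 2-D nMDS scores on
  three variable blocks; unique/shared fractions by inclusion–exclusion
  on Ezekiel-adjusted $R^2$ (vegan's varpart). Negative shared fractions
  are reported, not truncated; fractions plus residual sum to 1.
* **Forward selection** precedes partitioning: candidates with variance
  inflation above 10 are dropped first, then variables enter by largest
  adjusted-$R^2$ gain subject to a nested permutation test
  ($p < \alpha$), stopping once the running adjusted $R^2$ reaches the
  full-model adjusted $R^2$. The stop rule is applied *after* adding a
  significant variable: rejecting the step that crosses the threshold
  (as some implementations do) empties the selection whenever a single
  strong predictor out-explains the shrinkage-penalised full model,
  which fails the package's own selection-consistency simulations.
* **Mixed models**: the management/weather models are Gaussian linear
  mixed models on $\ln(\text{property})$ — the magnitudes of cell-mean
  estimates for proportions (≈ $\ln(0.003\ldots0.006) \approx -5.8$)
  identify the log-Gaussian reading of the published estimates; a Beta
  GLMM would be the alternative and is out of scope. Management is coded
  as cell means (no global intercept), continuous covariates are centred
  and scaled within country ("mean deviance per country"), fitting is
  REML with Satterthwaite degrees of freedom, and marginal
  $R^2 = \sigma^2_{fixed} / (\sigma^2_{fixed} + \sigma^2_{region} +
  \sigma^2_{resid})$. Singular random-effect fits fall back to the
  fixed-effects model, flagged.
* **Two-way ANOVA**: Type-II sums of squares, because the survey design
  is unbalanced; empty cells trigger a logged fallback to the additive
  model. Significance is annotated at $p < 0.01$.
* **Pathogen model**: richness is the count of listed pathogen OTUs
  present; presence means richness ≥ 1 (an abundance threshold is the
  undecidable alternative). The binomial GLM uses clustering(+),
  modularity(+), average path length(−) and the co-exclusion proportion;
  complete separation triggers a flagged ridge-penalized fallback
  without p-values; a constant outcome is refused with a clear error.
* **Environmental PCA**: natural log (optional shift for non-positive
  values), per-variable z-scaling, correlation-matrix
  eigendecomposition.

## 7. The synthetic benchmark

`generate_metacommunity()` emulates the *processed* survey inputs — it
is the package's testbed, not a sequencing simulator. Defaults mirror a
two-country vineyard survey: 175 sites per country; management counts
65/39/20 (+51 undeclared) and 78/79/15 (+3 undeclared); depths uniform
on 20,000–60,000 reads; temperature gradient 12–38 °C with three
contiguous regional bands per country; humidity uniform on 0.2–0.9;
gamma-distributed wind speeds.

The ecological structure is occupancy-based, because the inference chain
is presence/absence-based; the lognormal-abundance/multinomial-read
layer exists to exercise rarefaction realistically. OTUs belong to $K=4$
guilds with evenly spaced thermal centres (optima $\mathcal{N}(c_k,
2.5\,°\mathrm{C})$). Sites follow one of two regimes, mapped from
management (conventional → partitioned, biodynamic → cooperative,
organic and undeclared → 50/50 mixture):

* A **cooperative** site draws occupants from a single narrow kernel
  around its temperature ($\sigma = 2\,°\mathrm{C}$): one well-mixed
  clump of mutually co-occurring species — locally dense, weakly
  modular, almost free of co-exclusions.
* A **partitioned** site hosts its dominant guild under a wide kernel
  ($\sigma = 6\,°\mathrm{C}$) plus a temperature-flat "satellite"
  occupancy for cross-guild species, suppressed by
  $(1-\varepsilon)\cdot s$ with exclusion strength $\varepsilon = 0.85$
  and satellite level $s = 1.5$. The sample mixes a dominant clump with
  satellites of globally co-excluding guilds — locally modular, with
  co-exclusions inside the sample.

The satellite term is the part that makes niche partitioning *local*: a
pure dominant-guild site would itself be one dense module and would
invert the intended regime contrast. Baseline occupancy is calibrated
per regime so both hit the same target mean richness (no richness
confound between regimes). Pathogen flags (default 1% of OTUs — a
curated pathogen list is a handful of taxa, and presence must vary for a
presence model to exist) carry an occupancy multiplier favouring the
cooperative regime, planting the negative pathogen-richness vs
co-exclusion-proportion association; the direction is configurable and
deliberately not forced through the network properties themselves.

What the generator does *not* emulate: spatial autocorrelation beyond
the regional temperature bands, taxonomy, season, abundance-mediated
interactions, read-level noise (chimeras, index hopping), and any link
between alpha diversity and network structure — so a diversity–modularity
correlation measured on synthetic data is expected to hover near zero,
and passing tests say nothing about that relation in real data.

Passing the regime-separation and correlation-sign tests shows the
chain *can* recover such structure when it exists at these effect sizes;
it does not show real vineyard soils have it.

## 8. Problem sizes and determinism

The test suite and acceptance script use a small fixture (30 sites × 150
OTUs) for structural and determinism checks and a standard fixture (120
sites × 600 OTUs, 60 conventional / 60 biodynamic, three seeds) for the
relationship-structure and regime-separation checks; null-model
calibration uses 200 samples at 500 randomizations, and the
parameter-recovery suites use 200 simulations — sizes chosen to give the
property checks adequate power while keeping a full run in minutes on a
single core. Every random stage takes an explicit seed; pipeline re-runs
are bit-identical (the run manifest records parameters and a
location-independent config hash; wall-clock timings go to a separate
log file, the only non-deterministic output; BIOM files are written with
a pinned date field).

## 9. Known limitations

* Associations are spatial co-occurrence patterns; they are proxies of
  assembly processes, not evidence of ecological interaction.
* The exact model conditions on occupancies and treats samples as
  exchangeable sites; strong spatial or temporal autocorrelation
  violates that premise.
* Local properties of small species sets are noisy; profiles with
  $S < 2$ are refused and walktrap modularity of very sparse induced
  subgraphs is reported as computed, with the null model as the
  calibration instrument.
* The log-Gaussian mixed model is an interpretation of the published
  estimate scale; proportions very close to 0 would be better served by
  the (out-of-scope) Beta GLMM.
* The uniform null destroys species identity entirely; a
  degree-preserving null would test a different, sharper hypothesis and
  is intentionally not provided.
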