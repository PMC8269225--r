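# localweb

Community-level network properties of microbial samples, inferred by
projecting a metacommunity-wide association network (a *metaweb*) onto the
species present in each individual sample.

## The problem and the approach

Microbiome surveys routinely summarise samples by diversity indices, but
those say little about how the community is *organised*. An alternative is
to infer, across a whole survey, which taxa co-occur or co-exclude more
often than chance predicts, and then ask what the association structure
looks like *within* each sample. `localweb` implements that chain for
OTU count tables (e.g. soil fungal ITS surveys):

1. **Associations.** After rarefaction (default 20,000 reads/sample), a
   prevalence filter (default: OTUs in ≥ 2% of samples) and
   presence/absence transformation, every OTU pair is scored with the
   exact probabilistic co-occurrence model. For two taxa occupying $n_1$
   and $n_2$ of $N$ sites, the number of shared sites $J$ under
   independent placement follows

   $$P(J=j) = \frac{\binom{n_1}{j}\binom{N-n_1}{n_2-j}}{\binom{N}{n_2}},$$

   a hypergeometric law, evaluated in log-space. Inclusive tail sums
   $P(J \le j_{obs})$ and $P(J \ge j_{obs})$ below the significance level
   (default $P < 0.05$, no multiple-testing correction) classify the pair
   as a co-exclusion or a co-occurrence.
2. **Metaweb.** Significant pairs form the signed metaweb of a stratum
   (typically a country, analysed separately). Modules of the positive
   subgraph are detected with the random-walk (walktrap) algorithm and
   scored by Newman–Girvan modularity
   $Q = \sum_c \left[ e_c/m - (d_c/2m)^2 \right]$.
3. **Local networks.** Each sample's species set induces a subgraph of
   the positive and of the negative metaweb. Per sample the package
   reports: connected components, modularity, clustering coefficient
   (average transitivity over nodes of degree ≥ 2), average path length
   (over connected pairs), and the co-occurrence / co-exclusion
   proportions — induced edge counts over $\binom{S}{2}$, with $S$ the
   sample's filtered richness.
4. **Null models.** Observed local properties are z-scored against
   equal-richness random draws from the metaweb node pool (default 1,000
   randomizations), with the conventional $|z|>2$ deviation bands.
5. **Statistics.** Spearman property–property correlations, nMDS /
   ANOSIM / Mantel / betadispersion, variation partitioning with forward
   selection, log-Gaussian mixed models of properties on management and
   weather with a regional random intercept, unbalanced two-way ANOVA,
   pathogen-presence logistic models, and environmental PCA.

A fully ground-truthed synthetic metacommunity generator
(`generate_metacommunity()`) provides niche-structured benchmarks with
two planted community regimes — "cooperative" (one well-mixed clump:
dense, weakly modular local networks) and "partitioned" (niche-divided
sites: modular local networks rich in co-exclusions) — so every stage of
the chain is testable against known structure.

## Worked example

```r
library(localweb)

cfg <- generator_config(
  n_otus = 300, countries = c(ES = 60),
  management_mix = list(ES = c(conventional = 30, organic = 0,
                               biodynamic = 30, unknown = 0)),
  target_richness = 60, n_regions = 2, seed = 42)
sim <- generate_metacommunity(cfg)

counts   <- rarefy_counts(sim$counts, depth = 20000, seed = 42)
presence <- to_presence(prevalence_filter(counts, 0.02))
assoc    <- all_pair_associations(presence, alpha = 0.05)
mw       <- build_metaweb(assoc, colnames(presence), stratum = "ES")
mw
#> Metaweb [ES]: 300 nodes, 6628 co-occurrence edge(s), 2539 co-exclusion edge(s)
#> Modules (positive subgraph): 4, sizes 106, 97, 61, 36; Q = 0.5795

profiles <- profile_all(mw, presence)
summary(profiles)[c(1, 5, 7, 15), ]
#>                  property     min    mean     max  n
#> 1              richness_S 25.0000 58.6000 76.0000 60
#> 5          modularity_pos  0.0109  0.2281  0.5310 60
#> 7     avg_path_length_pos  1.2839  2.0295  3.4013 60
#> 15 coexclusion_proportion  0.0000  0.0035  0.0159 60
```

The metaweb recovers the four planted thermal guilds as modules
(Q = 0.58). Per-sample properties span a wide range around the metaweb's
global values; the planted management regimes separate — conventional-like
("partitioned") samples average a local modularity of 0.34 against 0.12
for biodynamic-like ("cooperative") samples:

```r
tapply(profiles$modularity_pos, sim$truth$site_regime[profiles$sample_id], mean)
#> cooperative partitioned
#>   0.1164713   0.3398139
cor.test(profiles$modularity_pos, profiles$coexclusion_proportion,
         method = "spearman")$estimate
#>       rho
#> 0.7857574
```

i.e. more modular (niche-partitioned) communities sustain a higher
proportion of co-exclusions.

The full chain — rarefaction through null models, statistics, and a run
manifest enabling bit-identical re-runs — is available as
`run_pipeline(run_config(...))`, or from a shell via the thin wrapper
`inst/scripts/localweb.R` (subcommands `simulate`, `filter`,
`associations`, `metaweb`, `local-props`, `nulls`, `stats`, `run`).

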