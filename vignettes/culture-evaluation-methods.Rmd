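---
title: "Methods: scoring ex vivo gut-microbiome cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring ex vivo gut-microbiome cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culturebench)
```

# The evaluation problem

An ex vivo fecal culture is a proxy for the donor's gut community, and the
proxy's quality depends on medium, harvest time and donor. `culturebench`
treats "how good is this culture?" as a multi-dimensional measurement: how
far the composition drifted from the fresh feces, how much diversity
survived, how much biomass grew, and how well the functional gene repertoire
was preserved — then condenses those measurements into a single comprehensive
rank per culture and a mean rank per medium. Alongside the ranking, a
PERMANOVA partitions the total compositional variation among the design
factors so the relative importance of donor, medium, time and replication is
quantified rather than eyeballed.

# Metrics

All metrics operate on **relative abundances** (total-sum scaling). We do
not rarefy: every metric used here is a function of proportions, and
discarding reads would only add noise. Profile sums are validated to 1
within `1e-9`; zero-probability terms contribute zero throughout
(`0 · log 0 = 0`).

* **Shannon index**, base 2 (bits): `H = -Σ p_i log2 p_i`. Maximal
  (`log2 n`) at the uniform profile.
* **Gini-Simpson**, `1 - Σ p_i²`. The field is loose about whether
  "Simpson index" means `D`, `1 - D` or `1/D`; we use the Gini-Simpson form
  `1 - D` because the composite ranking treats Simpson as
  higher-is-more-diverse (ranked descending), which requires a
  diversity-increasing variant. This is a documented interpretation, not a
  measured fact about any particular dataset.
* **Jensen-Shannon divergence**: `½ KL(P‖M) + ½ KL(Q‖M)`, `M = ½(P+Q)`,
  logs base 2 so the range is [0, 1]. We report the divergence itself, not
  its square root (the square root is the metric that ordination methods
  prefer; the ranking only needs a monotone dissimilarity, for which the
  divergence and its root are interchangeable).
* **Euclidean distance** on proportions — deliberately on proportions, not
  counts and not CLR-transformed values, because it is paired with
  ASV-level relative composition.
* **Bray-Curtis** for the PERMANOVA substrate.

Mismatched taxon sets are reconciled by union-with-zero-fill before any
pairwise metric.

Taxonomic aggregation (`aggregate_taxa()`) sums counts within a rank label
and pools taxa with a missing rank into an explicit
`unclassified_<rank>` bucket, so per-sample totals are conserved exactly
(integer arithmetic) and no reads silently vanish.

# PERMANOVA with sequential sums of squares

`permanova()` follows the classical distance-based ANOVA construction: with
`A = -½ d²` and centring matrix `C = I - J/n`, the inner-product matrix is
`G = CAC`; the sums of squares of a factor added `j`-th is
`tr((H_j - H_{j-1}) G)` where `H_j` is the hat matrix of the design
containing the first `j` factors. Choices worth stating:

* **Sequential (Type I) SS in the user-given order.** The factor order is an
  explicit argument and is never inferred; with an unbalanced design the
  attribution depends on it. This matches the table layout the classic
  `adonis`-style analyses print. The test-suite cross-checks every SS, F and
  R² against `vegan::adonis2(by = "terms")`, which is an independent
  implementation of the same decomposition.
* **One residual stratum.** Every factor's pseudo-F uses the single residual
  mean square; there are no nested error strata.
* **Free permutation of sample labels**, no blocking. The p-value estimator
  is `(1 + #{F* ≥ F}) / (1 + N)` so p is never zero; the default `n_perm =
  999` makes the smallest reportable p `0.001`. When `n!` does not exceed
  `n_perm` the permutation space is enumerated exhaustively and the exact
  tail probability is reported instead (with the observed assignment
  included). `exhaustive_permutation_p()` exposes the exact single-factor
  oracle (distinct multiset label assignments, capped at 10,000) that the
  tests use for parity.
* **Degenerate inputs.** A constant distance matrix has no variation to
  partition: F is undefined and p is reported as 1. A factor that adds no
  rank to the design (aliased with preceding terms) is a hard error naming
  the factor.
* **Accounting invariants.** `permanova_accounting()` derives the total SS
  from the components, and asserts SS additivity and that all R² (residual
  included) sum to 1 within `1e-8` on every construction. Deriving the
  total from the components (rather than trusting a separately supplied
  total) is what makes the R² of rounded published SS columns reproduce the
  published R² values at 3 decimals.

# Enterotyping

Method choices here are conventions of the enterotyping literature, adopted
as assumptions: Jensen-Shannon distances at genus level, partitioning around
medoids (PAM) for each `k` in 2..6, and the Calinski-Harabasz (CH) index —
computed directly from the distance matrix via the within/between SS
decomposition — to choose `k`. Clusters are labelled by the genus with the
highest mean relative abundance among their samples, prefixed `g_`.

Because PAM *optimises* the partition, the CH of the best split of pure
noise is systematically above 1, so "is there any cluster structure at all?"
cannot be answered by comparing CH to a fixed constant. We calibrate
against a column-shuffle null instead: each taxon's column is permuted
independently across samples (destroying sample structure, preserving taxon
marginals), PAM + CH is re-run (5 replicates by default), and if the
observed best CH fails to beat every null replicate, the smallest allowed
`k` is returned with a degeneracy warning. Identical samples (zero distance
matrix) are a hard error.

The pipeline enterotypes **per donor** by default. The operation accepts any
sample subset, so pooled runs are one argument away; per-donor is the
default because enterotype comparisons between a donor's feces and its own
cultures are the scientifically meaningful contrast here.

# The comprehensive rank

`rank_metric()` converts one metric's values to ranks with an explicit
direction: ascending for divergences (closer to feces is better), descending
for diversity and growth. Ties get the mean of the tied positions — a
deterministic, order-independent choice. Missing values get the worst rank
in the block, with a log message: a failed assay should penalise a culture,
not silently vanish from its score. `comprehensive_rank()` averages the
per-metric ranks within a block; all metrics are weighted equally (the
definition of the composite is "the average"), though the direction map is
an ordinary named vector, so weighted variants are a trivial extension for
sensitivity analysis.

Two block structures are provided as presets: a whole-set block (one donor's
15 cultures, three metrics: Euclidean, family-level JSD, Shannon) and
per-donor blocks of 3 media with the full seven-metric panel. Block
structure is always an explicit argument. `summarize_media()` averages
comprehensive ranks per medium across blocks; exact ties for best are
reported as ties, never broken.

Rank invariants asserted by the tests: ranks are invariant under strictly
monotone transforms of a metric; reversing a direction maps ranks `r` to
`n + 1 - r` under no ties; the comprehensive rank is bounded by the
per-culture min and max metric rank.

# Assay metrics

* **ΔOD600** = whole-culture OD minus supernatant OD. Negative values
  (noise) are kept, with a message, so ranking sees raw data.
* **qPCR relative abundance** `2^(CT16S - CTtarget)`; fold change vs the
  donor's own feces in log2. Zero or missing feces abundance makes the fold
  change undefined — reported as missing, never ±∞. No amplification is
  censored at cycle 40 and reported as the upper bound `2^(CT16S - 40)`,
  excluded from fold-change means with a log entry.
* **Gene variation score** = mean |log2 fold change| across assayed genes.
  The one-line description this implements ("variation of gene abundance")
  admits several aggregations; the mean absolute log fold change is the
  package's documented choice (symmetric in direction, zero iff all genes
  unchanged, ranked ascending).
* **Functional divergence** = JSD between normalised pathway-abundance rows
  of culture and matched feces, at the coarsest pathway tier.

# Drug-metabolism quantification

Calibration is ordinary least squares of peak-area ratio on concentration.
The stored fit quality is **r²** with the conventional acceptance threshold
0.99 applied to it ("correlation coefficient > 0.99" in assay protocols
usually refers to r; applying the threshold to r² is the stricter reading,
and the discrepancy is noted here). Inverse prediction is `x = (y - b)/a`,
clipped at 0 with a warning (signal below the intercept means
nondetectable) and flagged when extrapolating outside the calibration
range; `quantify ∘ predict` is the identity within `1e-9`.

The *remaining fraction* of a parent drug defaults to the time-matched
no-microbiome control as reference, which isolates microbial metabolism from
passive chemical degradation; normalising to the nominal 500 µM dose is
available as an option because published remaining-fraction plots are often
ambiguous between the two. Inter-donor variation is mean, sample SD (n−1)
and CV of one readout per donor. Internal-standard pairing is treated as
upstream metadata: the package consumes area *ratios*.

# The synthetic-data generator

`simulate_experiment()` emulates a 16S count-table study downstream of
denoising, with the factor structure the analysis assumes:

* a shared log-abundance backbone `N(0, 1.5)` per taxon (log-normal
  abundances — heavy-tailed, as real communities are);
* donor effects `N(0, donor_effect_sd)` per taxon (default **1.5**);
* medium effects `N(0, medium_effect_sd)` drawn **per family** per medium
  level (default **1.0**) — media shift whole families, which is what
  family-level abundance-shift summaries in culture studies show;
* time effects `N(0, time_effect_sd)` per family per time level (default
  **0.3**);
* replicates differ only through sampling noise (no systematic batch
  effect), matching a reproducibility factor that explains essentially no
  variance;
* per sample, proportions from a Dirichlet centred on the exponentiated
  profile (concentration default **200**) and counts from a multinomial at
  depth **10,000** (a typical post-QC 16S depth; depths are rarely
  reported, so this is a package default, not a measured value).

The default design is 3 donors × 7 media × {6, 24} h × 2 replicates (84
cultures + 3 feces), the screening design whose degrees of freedom the
tests reconstruct, with a 10 donor × 3 media × 24 h variant for the
validation-style runs. Effects are additive on log abundance — standard
compositional practice; no generative model is claimed by the source
analyses, so this is the package's own modelling choice.

What the generator does **not** emulate: phylogenetic correlation between
taxa, taxon-specific growth kinetics and interactions, compositional
zero-inflation beyond multinomial sampling, chimeras/primer artifacts, and
any real medium chemistry. Passing tests therefore demonstrate that the
*statistical machinery* behaves correctly under the assumed factor
structure — they do not certify the biological conclusions of any specific
wet-lab comparison.

All samplers are driven by one seed threaded through the spec; no hidden
global state. Same seed, same tables, byte-identical — the end-to-end
pipeline writes a JSON manifest with md5 checksums, and the determinism test
asserts checksum equality across reruns.

# Problem sizes and runtime choices

The test suite and the acceptance script run on deliberately compact
problems — communities of 40–150 taxa, designs of 30–87 samples, 999
permutations, 200 null simulations for the type-I check, 5 seeds for
effect-ordering recovery. These sizes were chosen so that the full suite
completes in well under a minute while keeping every statistical check
adequately powered; all of them scale up by changing arguments, none are
hard-coded.

# Known limitations

* PERMANOVA supports categorical main effects only: no continuous
  covariates, interactions, dispersion (PERMDISP) testing, or restricted /
  blocked permutations.
* Sequential SS make factor attributions order-dependent in unbalanced
  designs; the order is the user's scientific statement, not the
  package's inference.
* Phylogenetic metrics (UniFrac) and ordination statistics are out of
  scope; distance matrices can be exported to dedicated tools.
* The enterotype degeneracy null (column shuffling) destroys taxon
  co-occurrence along with sample structure; it is a conservative guard
  against clustering pure noise, not a general cluster-validation method.
* The drug track assumes first-order kinetics for simulation and linear
  calibration for quantification; saturating (Michaelis-Menten) metabolism
  and quadratic calibration are not modelled.
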