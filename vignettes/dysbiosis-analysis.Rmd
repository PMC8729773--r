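---
title: "Characterizing diet-induced gut dysbiosis: dispersion, beta-diversity components, and the bacterial interactome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing diet-induced gut dysbiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbionet)
```

## The scientific question

When a host is stressed — here, an insect reared on nutrient-restricted
diets instead of a full-nutrient one — its gut bacterial community can shift
into configurations associated with poor growth and reduced resilience
(dysbiosis). Two competing signatures of such shifts are commonly examined:

* **increased dispersion** (the Anna Karenina Principle): stressed hosts
  drift apart, so within-group sample-to-sample variability grows;
* **deterministic relocation**: groups move to distinct, equally tight
  configurations, and the damage shows instead in the *interactome* — the
  network of statistically supported co-occurrence and mutual-exclusion
  relationships among OTUs — which becomes sparser, less centralized and
  less robust.

`dysbionet` implements the full chain of analyses needed to distinguish
these signatures from an OTU count table with diet and developmental-stage
metadata: ordination and multivariate dispersion, decomposition of beta
diversity into replacement and richness-difference components, signed
co-occurrence network inference with a compositionality-aware permutation
null, topological summaries with hub/keystone classification, and network
robustness under stepwise node removal. A synthetic-data generator with a
planted ground-truth network makes every stage testable end to end.

## Dissimilarity, ordination, and dispersion

Bray–Curtis dissimilarity is computed between samples,
by default on `log1p`-transformed counts (a raw-count option is retained):

$$BC(x,y) = \frac{\sum_i |x_i - y_i|}{\sum_i (x_i + y_i)} \in [0,1].$$

`pcoa()` performs classical metric scaling: Gower double-centering of
$-D^2/2$ followed by an eigendecomposition. Because Bray–Curtis is a
semimetric, some eigenvalues are negative; the corresponding axes are kept
as *imaginary* coordinates scaled by $\sqrt{-\lambda}$, and squared
distances are reproduced as (real squared distance) − (imaginary squared
distance). This matters for dispersion: `permdisp()` measures each sample's
distance to its group centroid in the full PCoA space as
$d^2 = d^2_{\text{real}} - d^2_{\text{imag}}$, floored at zero — the
standard multivariate-dispersion construction for semimetric
dissimilarities. Group differences in dispersion are tested with a one-way
F statistic on those distances and a label-permutation p-value
$(\#\{F^\ast \ge F\} + 1)/(n_{\text{perm}} + 1)$, plus Tukey HSD contrasts
with a compact letter display.

Choices made where the design was open:

* distances are measured to the group **centroid** (a spatial-median
  variant is available via `type = "median"`, delegated to
  `vegan::betadisper`);
* raw distances, not residuals, are permuted — the simplest exchangeable
  scheme for balanced designs;
* ties in the permutation distribution count against rejection
  (`>=` with the +1 correction), making the test conservative at the
  margin. The suite verifies the empirical type-I error over 200 null
  simulations stays inside the 95% binomial envelope of the nominal 0.05.

## Beta-diversity components

For a pair of communities, with `a` the shared component and `b`, `c` the
components unique to either sample, the Podani-family Jaccard-based
triplet is

$$S = \frac{a}{a+b+c},\quad
  \mathrm{Repl} = \frac{2\min(b,c)}{a+b+c},\quad
  \mathrm{RichDiff} = \frac{|b-c|}{a+b+c},$$

which always sums to one — each pair of samples is a point in a ternary
diagram whose corners are pure similarity, pure species replacement
(turnover), and pure richness difference (nestedness-like gain/loss). The
presence–absence family counts species; the quantitative (Ruzicka) family
uses $a=\sum_i \min(x_i,y_i)$, $b=\sum_i (x_i-y_i)_+$,
$c=\sum_i (y_i-x_i)_+$. Both families are provided because published
analyses of this design name the decomposition function but not the
family; neither is asserted as "the" published variant. Group statistics
are computed over within-group pairs only, and component differences
between groups are tested by a permutation one-way F.

The decomposition is validated against an exhaustive set-count oracle on
all $2^6 \times 2^6$ binary vectors of length 6 and a 1000-pair identity
sweep.

## Signed co-occurrence networks

The interactome is inferred per diet (and optionally per diet × stage)
with an ensemble-and-null design in the style of established
co-occurrence tools:

1. **prevalence filter** (default: present in ≥ 1/3 of samples);
2. **method ensemble**: Pearson and Spearman correlation on `log1p`
   relative abundances, plus Bray–Curtis dissimilarity between the two
   OTUs' relative-abundance profiles;
3. **candidate selection**: the most extreme score quantiles per method
   (default 1000 candidate edges per method, all pairs when fewer);
4. **permutation–renormalization null** per candidate: the two OTUs'
   counts are shuffled across samples independently and every sample's
   composition is renormalized before the score is recomputed. The
   spurious association induced by compositional closure is thereby
   absorbed into the null *mean*, and the two-sided p-value compares the
   observed deviation from that mean against the null deviations (+1
   correction). A bootstrap over samples yields a score CI; edges whose
   CI crosses the null mean in two or more methods are discarded as
   unstable;
5. **merging and correction**: per pair, the method p-values are merged
   with Brown's method (Fisher's combination adjusted for inter-method
   covariance, estimated from the permutation streams), then
   Benjamini–Hochberg across pairs; edges are retained at `q <= alpha`
   (default 0.05) with at least two methods agreeing in sign. The edge
   sign is the consensus correlation sign, with Bray–Curtis voting by its
   below/above-null direction.

Defaults are 999 permutations and 999 bootstrap resamples with a mandatory
seed. The null's calibration (fraction of independent pairs with p < 0.05
inside the binomial envelope of 0.05) and the recovery of a planted
interactome (precision/recall against ground truth) are part of the test
suite. Modules are found with the seeded Louvain heuristic.

## Topology and keystones

`topology_summary()` reports the NetworkAnalyzer-style indices: density
$2E/N(N-1)$, average neighbors $2E/N$, degree mean ± sd, Freeman degree
centralization $\sum_i (k_{\max}-k_i) / ((N-1)(N-2))$, heterogeneity
(population CV of the degree distribution), average local clustering
(degree < 2 contributes zero; a transitivity variant is behind a flag),
and characteristic path length averaged over *connected* pairs only — the
convention that stays finite on the modular, possibly disconnected
networks of stressed communities. Percent-change columns of the
comparison table are computed from unrounded values and only then rounded,
which is the only order of operations that reproduces published
comparisons of this kind.

"Degree of connection > 75%" is read as *strictly above the 75th
percentile of the observed degree distribution* (top quartile), not 75% of
the maximum degree; with this reading a regular graph has no hubs, and a
star's center is the sole hub. Keystones are hubs that also sit strictly
above the 75th percentile of betweenness centrality (Brandes, unweighted).
Both quantiles are exposed as parameters.

## Robustness

`attack()` removes nodes one at a time — uniformly at random (averaged
over repetitions), by descending initial degree, by descending initial
betweenness, or by recomputed betweenness after every removal (the
cascading scenario) — and records the connectivity loss

$$L = 1 - \frac{\text{connected node pairs remaining}}
               {\text{connected node pairs initially}},$$

with raw edge loss as a secondary column. Pair connectivity, rather than
edge count, is the stability currency: it is what collapses when a modular
network disaggregates. Ties in targeted strategies break by ascending node
id so curves are exactly reproducible. Curves are validated against a
brute-force reachability recount on random graphs, and against the closed
form on the complete graph ($K_6$: $L(2/6) = 0.6$). `compare_curves()`
summarizes networks by the area under the loss curve (higher = less
robust) and interpolated losses at chosen removal fractions.

## Bioassay metrics

The substrate-consumption formulas are
$\mathrm{SR} = 100\,(W-R)/W$ (percent substrate reduction),
$\mathrm{ECI} = B/(W-R)$ (conversion efficiency of ingested food), and
$\mathrm{WRI} = \mathrm{SR}/\text{days}$ (waste reduction per day). The
WRI form deserves a note: the printed formula in the source literature,
read literally as $(W - R/W)\times days \times 100$, cannot produce
index values on the reported scale, whereas reduction-per-day — the form
standard in the bioconversion literature — reproduces it exactly
(e.g. 60.5% over ~14.3 days ≈ 4.22), so that form is implemented.
Whether "days" means feeding duration or development time is left to the
caller as an input column, since it is a property of the experiment, not
of the formula. Reported percentages round half away from zero.

## The synthetic generator

`synthetic_config()` describes a diet × stage design (default: 3 diets ×
3 stages × 9 replicates, matching the sampling depth typical of such
studies). Counts are generated in four layers:

1. **pools**: a core OTU set shared by all diets plus disjoint diet-unique
   sets; `core_fraction` fixes the pairwise pool overlap exactly, and the
   per-diet `richness_offset` plants net gain/loss of species. Pool overlap
   arithmetic is tested exactly against set counting.
2. **planted network**: module members load on one latent factor per
   module (within-module correlation `within_module_rho`); keystones load
   positively on one module and negatively on a second, carrying both
   co-presence and mutual-exclusion edges and a planted degree of at least
   `2 * module_size`. Ground-truth edges are every pair whose implied
   latent correlation magnitude reaches a threshold (default
   `0.3 * |rho|`), so the truth is exactly the correlation structure the
   sampler realizes.
3. **abundances**: a Gaussian copula over the latent factors drives
   log-normal relative abundances (`lognormal_mu`, `lognormal_sigma`).
   OTUs carrying planted structure draw their base abundance from the
   lower-middle band of the community distribution (between −1 sd and the
   median). This is a deliberate observability choice: planted
   associations on vanishingly rare taxa are statistically invisible at
   realistic depths, while planting them on dominant taxa makes the
   community total co-vary with the modules and manufactures
   closure-induced associations that no pairwise null can remove. Keystone
   taxa in real communities are likewise not necessarily abundant.
4. **counts**: expected proportions are Dirichlet-perturbed with
   concentration `dirichlet_theta × p` (default 2000 — mild replicate
   overdispersion that leaves the planted covariance observable; small
   values push replicates toward independence) and drawn as a multinomial
   at a negative-binomial library size (default mean 20,000, shape 5,
   emulating deep amplicon coverage, consistent with near-one Good's
   coverage).

A single integer seed drives everything through fixed per-stream offsets,
so identical configurations are byte-identical and groups are decoupled.

What the generator deliberately does **not** emulate: taxonomic
phylogeny (taxonomy labels come from a fixed toy lexicon), sequencing
error and chimeras, rank-abundance tails heavier than log-normal,
absolute-abundance dynamics (everything is compositional), and
environment-mediated correlations that are not pairwise-factor shaped.
Passing tests therefore demonstrate the pipeline's statistical
correctness under a controlled, realistic-scale model — not that any
particular real community will be recovered with the same operating
characteristics.

## Problem sizes used in the validation suite

The deeper stochastic checks run at sizes chosen to make their
conclusions statistically meaningful while staying desk-scale: null
calibration on 500 independent OTU pairs at 999 permutations; planted
interactome recovery on 60 OTUs × 50 samples (4 modules of 8, ρ = 0.8, 3
keystones) at 999 permutations and 99 bootstrap resamples; dispersion
type-I error over 200 simulations of 2 × 10 samples at 199 permutations;
exhaustive decomposition checks on all binary vectors of length 6; oracle
comparisons on 50 random graphs (topology) and 30 random graphs × 4
strategies (robustness).

## Known limitations

* The co-occurrence framework cannot distinguish true ecological
  interaction from shared habitat preference or other nonrandom
  processes; edges are statistical associations.
* Brown's covariance adjustment is estimated from finite permutation
  streams; with very small `n_perm` the merged p-values become coarse.
  `n_perm < 20` is rejected outright.
* On compositions, modules that occupy a large share of total abundance
  induce genuine closure correlations with the rest of the community;
  the renormalized null absorbs pair-level closure but not such
  community-level effects. Observed false-discovery proportions against
  a *latent* ground truth are therefore somewhat above the nominal BH
  level even when the null is perfectly calibrated pairwise.
* The permutation F test for dispersion permutes raw distances; for
  strongly unbalanced designs a residual-permutation scheme would be
  preferable.
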