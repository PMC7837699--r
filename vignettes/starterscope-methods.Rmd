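---
title: "starterscope: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{starterscope: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starterscope)
```

This vignette documents the statistical machinery of starterscope the way
a maintainer would want it written down: the model behind each stage, the
tunable parameters with their defaults and units, the design decisions
taken where several defensible options existed, what the synthetic-data
generators do and do not emulate, and the numerical conventions.

## 1. Community tables and dissimilarity

A `community_table` holds a sample-by-taxon matrix of counts or relative
abundances plus per-taxon annotations: kingdom (`bacteria`/`fungi`) and
functional group (`LAB` — lactic acid bacteria, order Lactobacillales;
`AAB` — acetic acid bacteria, order Rhodospirillales; `yeast` — order
Saccharomycetales; `other`). The fermentation-relevant groups are the
unit of most downstream subsetting.

* `rarefy(counts, depth, seed)` subsamples reads **without replacement**
  per sample; conventional depths are 1260 (16S) and 4000 (ITS) reads.
  Samples below depth are dropped and reported. Rarefaction is unbiased
  for proportions: the expected post-rarefaction share of a taxon equals
  its pre-rarefaction share (tested to 3 Monte-Carlo SE over 1000 draws).
* `bray_curtis` computes `BC(x,y) = Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ)`; on relative rows
  this equals `1 − 2Σmin(xᵢ,yᵢ)/Σ(xᵢ+yᵢ)` (tested numerically). Two
  all-zero rows would make the quotient undefined, so all-zero samples
  are an error rather than a silent 0.
* `combine_kingdoms` weights bacteria against fungi (yeasts only;
  non-yeast fungi are molds/endophytes with little fermentation role).
  The equal-weighting statement in the field's protocols does not fix a
  mechanism, so each kingdom block is **renormalized to its weight**
  (default 0.5/0.5) and concatenated; averaging per-kingdom
  dissimilarities instead is possible by calling `bray_curtis` per block.
  The renormalized-block convention was chosen because it yields a single
  composite composition vector per sample, reusable by every downstream
  routine.
* `hierarchical_cluster` delegates to `stats::hclust(method = "ward.D2")`
  (Murtagh–Legendre squared-distance update) and is verified against a
  naive O(n³) Lance–Williams implementation in the test suite. Ties are
  broken by the scan order of `hclust`, which on equidistant triples picks
  the lowest index pair.

Threshold comparisons against the within-sample 1% detection rule are
**strict** (`> 0.01`): an abundance of exactly 1% is "not detected". This
boundary convention propagates to presence/absence, persistence, and
prevalence filtering.

## 2. Probabilistic co-occurrence

Presence/absence is taken at the species level above the 1% within-sample
threshold. Under independent placement of the N₁ and N₂ occurrences of
two species among N samples, the joint count J is hypergeometric.
`pair_distribution` evaluates it in log space (`lchoose`) so N = 500-scale
surveys are exact to machine precision; the distribution sums to 1 within
1e-12 for all tested N ≤ 200 and matches exhaustive enumeration of all
placements for N ≤ 8.

`cooccur_analysis`:

* both tails **include** the observed value (`p_lt = P(J ≤ j)`,
  `p_gt = P(J ≥ j)`), the convention of probabilistic co-occurrence
  models, so `p_lt + p_gt ≥ 1`;
* pairs with expected joint count `N₁N₂/N ≤ 1` ("predicted to co-occur
  no more than once") are removed **before** correction, and the
  Bonferroni factor m counts only surviving pairs. The filter is strict
  `> 1` by default (`min_expected = 1`), configurable because "more than
  once" could also be read as `≥ 1`;
* sign calls: positive when the upper tail is the smaller one and the
  Bonferroni-corrected p is ≤ α (default 0.05); negative symmetrically;
  otherwise random. Pairs are canonicalized alphabetically so output is
  deterministic under column reordering.

## 3. Biogeography

`haversine_matrix` uses the Haversine great-circle formula with Earth
radius 6371 km. `distance_decay` is a one-sided (positive-association)
Spearman Mantel test — the direction that "nearby communities are more
similar" implies. `kmeans_regions` runs Lloyd's algorithm on raw
latitude/longitude degrees; the surveys this mirrors did not state a
projection, so raw degrees is the default and `project = TRUE` enables an
equirectangular local projection for rigor. Empty clusters during
iteration are re-seeded at the point farthest from its assigned centroid.
Restarts (default 10) keep the best inertia; the within-cluster sum of
squares is non-increasing across iterations (tested).

## 4. Indicator analysis

For categorical conditions the indicator statistic is the point-biserial
correlation r between a taxon's abundance and the 0/1 membership of a
level; 0.25 is the conventional "strong association" landmark. In
`indicator_screen`, multi-level factors are handled by taking the
**maximum r over levels** with a permutation null of that same maximum,
which keeps the per-variable test honest without a separate correction
over levels. The classical IndVal (`sqrt(A·B)` with group-equalized
specificity) is available behind `statistic = "IndVal"`; r is the default
for consistency with the continuous-variable screens.

Continuous variables use Spearman rank correlation with midrank ties;
p-values are exact (full permutation enumeration, valid under ties) for
n ≤ 9 and t-approximated otherwise.

Screening filters taxa detected (1% rule) in fewer than 10% of samples.
The multiple-testing family is **all taxa within one variable**
(Benjamini–Hochberg); the family definition is not fixed by the
protocols this mirrors, and per-variable families match how such screens
are usually reported. Permutation p-values use the plus-one rule and are
never 0.

## 5. Permutation multivariate statistics

* **Mantel**: rank (or linear) correlation of the n(n−1)/2 off-diagonal
  distances; the null permutes rows and columns of the second matrix
  simultaneously. When `factorial(n) ≤ n_perm + 1` the full permutation
  group is enumerated and the p-value is exact (this is how the tests
  validate against brute force at n = 5). Default 999 permutations,
  one-sided positive.
* **PERMANOVA**: McArdle–Anderson partition. With
  `A = −½ d²` and `G = CAC` (C the centering matrix), the SS of each
  sequential term is `tr((H_j − H_{j−1})G)` for the cumulative hat
  matrices H. Terms are **sequential in the caller's order** — order
  matters in multi-predictor models and is deliberately exposed rather
  than hidden. p-values come from free permutation of sample labels.
  Samples with missing predictor values are dropped and reported. A
  constant predictor contributes zero SS and no test; a term adding no
  rank while varying (collinear) is an error naming the term.
* **NMDS**: Kruskal stress-1 minimized by majorization
  (`vegan::monoMDS`), best of a classical-scaling start plus random
  starts (default 20). Coordinates are centered, rotated to principal
  axes, and sign-fixed (largest-|score| sample positive per axis) so the
  axis scores used in taxon screens are deterministic given the seed.
* **Kruskal–Wallis / Dunn**: tie-corrected H; groups below
  `min_group_n = 5` are dropped first (e.g. sensory notes dominant in
  fewer than five samples are not tested). Dunn z-statistics use the
  tie-corrected variance; pairwise p-values are reported raw by default
  (with an FDR column alongside), since the analyses this mirrors report
  raw Dunn p-values.

## 6. Competition and concordance

CFU tables from serial-transfer competitions are converted to per-pair
fractions; persistence is judged on the **mean of per-replicate
fractions** (not pooled CFUs) at the focal transfer (default 6), strictly
above the 1% detection limit. Outcomes: co-persistence, exclusion of
either species, or mutual collapse — the last is a distinct class here
even though two-species prescriptions cannot generate it on purpose.

The concordance test asks whether in-vitro outcomes recapitulate in-situ
co-occurrence signs beyond chance. The null mirrors the empirical sign
pool — by default 16 significant interactions of which 8 positive — and
draws each tested pair's sign i.i.d. (`P(+) = 0.5`); drawing without
replacement from the finite pool is available, the with-replacement
reading being the default interpretation of "randomly drew from that
matrix". A positive sign matches co-persistence; a negative sign matches
any non-co-persistence outcome (either species excluded; the match rule
for a *specific* loser is not identifiable from sign data alone).
`mc_p` is the fraction of draws with at least the observed number of
matches; the closed-form Poisson-binomial tail (`9/256 ≈ 0.0352` for 7 of
8 at `P(+) = 0.5`) is computed alongside as a cross-check, and the two
agree within 3 Monte-Carlo standard errors at 10,000 draws.

## 7. Dough-rise kinetics

Pixel series are normalized by `ΔX_mm = (X − X₀)/T_h · tube_mm` with
`tube_mm = 103` (culture-tube height including cap). Series are truncated
from the first point falling **strictly more than** 5% below the
*running* maximum — running rather than global, so a late secondary rise
after a collapse is not resurrected.

The logistic model is the Growthcurver parameterization
`N(t) = K/(1 + ((K−N₀)/N₀)e^{−rt})` with K, N₀ in mm and r per hour.
Initial guesses: K = max height, N₀ = first positive height,
`r = 4·slope_max/K` (the logistic's maximum slope is rK/4). Fitting uses
`nls` (port algorithm, positivity bounds) with a Nelder–Mead fallback.
The goodness-of-fit gate is a nested-model **F-test against the
constant-mean model** with acceptance at p ≤ 0.01 — the protocols this
mirrors cite a p cutoff without defining the test, and the F-test is the
natural stand-in; it is documented as such. Fits recover noiseless
parameters to 1e-4 relative error and keep the median relative error of
r below 10% at 5%-of-K noise (tested over 200 seeded curves).

`rise_rate_anova` reports the one-way fixed-effects ANOVA p and adjusted
R² `= 1 − (1−R²)(n−1)/(n−k)`.

## 8. Volatiles and the community→function link

`background_filter` removes a compound from the whole table when its
maximum sample area is ≤ its maximum area across blank (water/flour)
samples; the maximum across blanks is used because the protocols name the
blank samples without an aggregator, and the maximum is the conservative
choice. `kovats_ri` is the linear temperature-programmed convention
between bracketing n-alkanes (C7–C30 mixtures). `zscore_matrix` uses the
**population** SD (÷ n); heatmap conventions vary and this one is fixed
and documented.

`link_function` computes, over a common (typically per-starter-mean,
n = 40) sample set: Mantel tests of VOC Bray–Curtis dissimilarities
against community dissimilarities (overall and per functional group) and
against Euclidean distances in total %AAB; a k = 2 NMDS of the VOC
dissimilarities with per-taxon Spearman screens on **both** axes
(FDR-corrected per axis — which axis carries a given taxon's signal is
not knowable a priori); the Spearman correlation of %AAB with rise rate;
and the sensory-note Kruskal–Wallis (notes with fewer than five samples
dropped; the *first* reported note is the dominant one). "%AAB" is the
summed relative abundance of taxa annotated `group = "AAB"`. All seeds
are threaded through, so the report is deterministic.

## 9. Species assignment

Patristic distances are branch-length path sums on the phylogeny.
`assign_species` single-links all leaves at the 0.97 patristic threshold
— the protocols say "clustered with" without naming a linkage, and single
linkage is the reading that makes "clustered with two references" well
defined; the threshold is in raw branch-length units. Naming: one
reference species → that name; two → both names joined; more than two →
a curated species-group name when the cluster's references all belong to
one curated group (six such groups ship as an editable default:
*L. plantarum*, *L. casei*, *L. crustorum*, *A. lovaniensis*,
*A. malorum*, *G. frateurii* spp. groups), else the cluster number.
Queries with no reference in their cluster are unassigned.

## 10. The synthetic world

The generators encode the statistical structure the analyses assume; they
are first-class, tested code, and their defaults are the stated world.

`generate_survey` (defaults: n = 500, seed-reproducible):

* a 14-taxon roster of focal sourdough species (4 yeasts, 5 LAB, 3 AAB
  species groups, 2 environmental "other" taxa) with marginal prevalences
  chosen to echo a large starter survey (e.g. *S. cerevisiae* in 77% of
  samples);
* **single-species dominance**: one present yeast and one present
  bacterium receive a large Dirichlet weight;
* **planted pairs**: a positive pair is forced jointly present/absent
  with probability `strength` (default 0.9), a negative pair is thinned
  to at most one member; defaults plant *L. plantarum*–*L. brevis*
  positive and *L. sanfranciscensis*–*L. plantarum* negative;
* **AAB prevalence** 0.294 (147 of 500) of samples carry at least one AAB
  group above 1%;
* present taxa get a 2% abundance floor plus Dirichlet shares; absent
  taxa get at most trace (< 0.5% total) mass, so the generator's
  presence/absence is exactly recovered by the 1% rule;
* geography is **unstructured** by default (uniform over a
  continental-US-like box, composition independent of location);
  `geography = "decay"` drives presence and abundance weights of two
  yeasts and two LAB along a latitude gradient, producing a Mantel
  distance-decay of roughly ρ ≈ 0.1 at n = 100 — a deliberately
  realistic (weak but detectable) signal rather than a caricature;
* metadata (age, grain base, storage, mean annual temperature) with one
  planted categorical indicator by default.

`generate_competitions` realizes a prescribed outcome map on the
8-species (4 yeast + 4 LAB, 28-pair) factorial design at transfers
1/3/6 × 5 replicates: co-persisting pairs end at 60/40, exclusions put
the loser at half the detection limit; earlier transfers interpolate from
an even start. Negative-binomial CFU noise has configurable dispersion
with 0 = deterministic, in which case `classify_persistence` round-trips
the prescription exactly. The default design also fixes eight
"significant in-situ" signs (4+/4−) of which the outcomes recapitulate
seven — the planted mismatch makes the concordance fixture match the
7-of-8, p = 9/256 inference exactly.

`generate_function` couples function to composition for a 40-starter
subset: rise rates `r = 1.4 − 1.2·%AAB + N(0, 0.08)` clamped to
[0.1, 1.5] per hour (the plausible range for dough rise), three replicate
logistic curves per starter (K ~ U(15, 30) mm, N₀ = 0.5 mm, emitted as
*zero-based* pixel series through a synthetic camera calibration); VOC
areas log-linear in %AAB plus noise, with five blank-level background
compounds for filter testing; and a sensory rule sending high-%AAB
samples to a vinegar-like dominant note.

**What a green test does and does not establish.** The generators emulate
planted effect structure, detection-threshold geometry, replicate noise
and seeded reproducibility. They do **not** emulate: sequencing error or
ASV-level noise, compositional artifacts of rarefaction at realistic
depth profiles, spatially autocorrelated metadata, batch effects,
non-logistic rise shapes (diauxic or collapsing doughs beyond the
truncation rule), or the taxon richness of real surveys (14 focal taxa vs
hundreds of ASVs). Recovery of a planted signal therefore validates the
inference machinery, not the field realism of any particular effect size.

## 11. Numerical conventions and limitations

* Permutation p-values use the plus-one rule and are exact (full
  enumeration) whenever the group fits in the permutation budget.
* All stochastic routines accept a `seed` and restore the caller's RNG
  state; outputs are bit-reproducible given the seed.
* Calibration tests in the suite run permutation tests at 99 permutations
  (resolution 0.01) and hundreds-to-thousands of replicates per
  statistic; the pipeline defaults remain 999 permutations.
* The headline numbers of the 500-starter study this pipeline mirrors
  (its real Mantel/PERMANOVA values, taxon counts, Fig-4 correlations)
  require the deposited data; the package recovers their *directions and
  design quantities* (7-of-8 concordance significance, 28/16/12 design
  counts, sign recovery, calibrated type-I error) from synthetic inputs.
* PERMANOVA is sequential-only (no marginal/Type-III option) and offers
  no PERMDISP companion; constrained ordination is out of scope.
* `fit_logistic` fits the three-parameter logistic to zero-based rise
  series as produced by video digitization; when the true process is a
  shifted logistic this carries a small systematic bias in r (see the
  kinetics tests, which bound it).
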