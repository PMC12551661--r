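---
title: "Trait-based functional diversity of paired stream communities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based functional diversity of paired stream communities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitpair)
```

## The question and the design

Wastewater treatment plants discharge into streams and alter flow,
temperature, nutrient and contaminant regimes downstream of their
outfalls. Taxonomic studies of benthic macroinvertebrates repeatedly find
community turnover below outfalls; whether those taxonomic shifts
translate into shifts of *function* — the distribution of feeding modes,
locomotion types, reproduction strategies and other traits — is less
clear, because communities can replace species with functionally similar
ones (functional redundancy).

`traitpair` implements the complete analytical machinery for asking that
question with paired monitoring data: for each treatment plant, one
community sampled upstream and one downstream. The unit of inference is
the pair. All computations are exercised end-to-end on synthetic data in
which the "effect" of the discharge is imposed by construction, so every
stage of the pipeline can be validated against known ground truth.

## Fuzzy traits and their preparation

Traits are fuzzy-coded: each taxon receives an integer affinity score
(default scale 0–3) for every *modality* of a *trait group* (e.g. the
modalities "shredder", "grazer", … of the group "feeding type"). Scores
are converted to relative frequencies within each group
(`normalize_fuzzy()`), so a taxon's profile in a group is a probability
vector. The default synthetic structure is nine groups totalling 49
modalities, the typical size of fuzzy trait sets used for European
macroinvertebrates.

Monitoring datasets never have complete trait coverage. `fill_gaps()`
raises uncoded taxa to the next highest taxonomic level at which
information exists: an uncoded species receives, per trait group, the
unweighted mean of the normalised profiles of the coded members below its
genus (then family), re-normalised. Community taxa collapsing onto the
same raised parent are merged and their abundances summed, conserving
total abundance. Two conventions are deliberate and configurable:

* *sufficient coverage* means at least one coded descendant per trait
  group (`min_donors = 1`); no published rule exists, so the package
  declares one;
* aggregated profiles are unweighted means over coded descendants, not
  abundance-weighted, matching the trait-aggregation practice the
  gap-filling approach is based on.

Taxa unresolvable even at family level are dropped with a warning and
listed — never silently.

## The functional space

Among-taxon dissimilarity uses the Gower formulation appropriate for
fuzzy-coded relative frequencies: within a group, half the Manhattan
distance between frequency vectors (which lies in [0, 1]); overall, the
unweighted mean over groups (`gower_distance()`). Equal group weighting is
a declared choice — the nine groups carry no published weights.

The space itself is a classical principal coordinate analysis. Gower
matrices are generally not Euclidean-embeddable, so a correction is
applied first. The default is the square-root transform — Manhattan-type
distances are of negative type, so their square roots embed exactly, and
the embedded distances reproduce the corrected matrix to numerical
precision (a property test asserts 1e-8). The Cailliez additive constant
is available via `correction = "cailliez"`; the choice affects convex-hull
volumes, which is why it is a configuration key rather than a constant.

The number of axes used by hull-based metrics is chosen by embedding
quality: for each candidate m, Euclidean distances in the first m axes and
the original Gower distances are both rescaled to [0, 1] by their maxima
and compared by the mean squared deviation over taxon pairs
(`dimension_quality()`). The scaling convention is the package's own —
"standardised distance" has no published formula. Under it, mSD typically
falls and then rises again as m grows, so the minimiser is a genuine
choice of dimensionality; the chosen m is additionally capped at 3 axes
for both the richness and the beta space, reflecting the constraint that
convex hulls need more taxa than axes and keeping the geometry exact.
That cap is also why the package computes hull volumes only in up to
three dimensions; analyses that would use many more axes for hull metrics
(e.g. eight) are outside its scope, while evenness and dispersion are
unaffected because they always use the entire positive-eigenvalue space.

A Gaussian kernel density on the first two axes (`trait_density()`,
Scott's-rule bandwidth with weighted effective sample size, 128×128 grid)
is provided as a diagnostic of which trait combinations are common; it
feeds no downstream test.

## Alpha diversity

Per community (relative abundances $p_i$, trait frequencies $t_{ik}$,
coordinates $x_i$, Gower distances $d_{ij}$):

* **CWM**: $\mathrm{CWM}_k = \sum_i p_i t_{ik}$; group sums remain 1.
* **FRic**: convex-hull volume of the community's taxa in the first m
  axes, by default standardised by the pool hull so values lie in (0, 1].
  Communities with $S \le m$ or a degenerate configuration are *undefined*
  (`NA`), never zero. The hull code (in C++) enumerates supporting planes
  with early rejection, merges coplanar triples into polygonal faces, and
  integrates cones from the centroid; it reproduces closed forms (unit
  tetrahedron 1/6) and qhull volumes to machine precision.
* **FEve**: minimum spanning tree (via `vegan::spantree`) over the full
  space; branch weights $EW_l = d_{ij}/(p_i+p_j)$ normalised to $PEW_l$;
  $\mathrm{FEve} = \frac{\sum_l \min(PEW_l, \frac{1}{S-1}) - \frac{1}{S-1}}
  {1 - \frac{1}{S-1}}$. Exactness is checked against exhaustive
  enumeration of all labelled spanning trees (Prüfer sequences) for
  $S \le 7$.
* **FDis**: abundance-weighted mean distance to the abundance-weighted
  centroid.
* **Rao's Q** = $\sum_{ij} d_{ij} p_i p_j$ on the Gower matrix (not the
  embedded coordinates), **Simpson** $D = 1-\sum p_i^2$, and **functional
  redundancy** FR = Q/D — the quotient definition is implemented
  literally; some literature defines redundancy as $1 - Q/D$, so a helper
  interpretation flag is left to the caller. FR is undefined for
  monocultures (D = 0). The identity $Q = \delta D$ under equal pairwise
  distance $\delta$ is asserted to 1e-12.

## Beta diversity

Functional beta diversity between the members of a pair is the overlap of
their convex hulls in the beta space (3 axes by default). The
intersection volume is computed exactly: each hull's edges are clipped
against the other's half-space representation, and the intersection
polytope's volume is assembled face-by-face from the combined plane set —
re-deriving planes from the clipped (hence noisy) vertex coordinates is
deliberately avoided, as it is numerically fragile. A Monte-Carlo
rejection oracle (hull membership via pairwise Frank–Wolfe projection, an
algorithm independent of the facet construction) confirms the exact
volumes on random point sets.

With $B = V_a - V_{shared}$ and $C = V_b - V_{shared}$ the Jaccard-family
decomposition is

$$\beta_{total} = \frac{B + C}{V_{shared} + B + C},\qquad
  \beta_{turn} = \frac{2\min(B,C)}{V_{shared} + 2\min(B,C)},\qquad
  \beta_{nest} = \beta_{total} - \beta_{turn},$$

with the Sørensen family available by flag; the decomposition literature
supports both and the default follows the framework's usual default.
Additivity is asserted to 1e-12 on every computed pair. Pairs in which
either community cannot span a 3-D hull are reported undefined rather
than padded.

## Null models and SES

Observed metrics are compared against a null in which taxon labels are
permuted on the trait matrix over the *full* pool (default R = 999;
analyses in this repository use R = 199 for the standard runs and R = 99
for the determinism checks — these are the package's chosen problem sizes
for its own validation studies). Community membership and abundances stay
fixed; only the functional identity of each taxon changes. Because a
label permutation merely permutes the rows of the fixed pool distance
matrix and coordinate matrix, null metrics are computed by row lookup
without re-running the ordination — and the pool hull that standardises
FRic is invariant, which both speeds the computation and makes the null
exact.

SES = (observed − null mean)/null sd. The two-tailed p uses the add-one
rank convention $p = 2\min(1+\#\{null \le obs\},\ 1+\#\{null \ge
obs\})/(R+1)$, capped at 1 — an observation beyond all 999 nulls gives
p = 0.002, and p is never exactly zero. Degenerate nulls (sd = 0, e.g. a
pool of functionally identical taxa) yield undefined SES, flagged and
excluded from significant-fraction denominators. The same R permutations
are reused across all metrics and units within a run (variance reduction;
metrics stay comparable), drawn independently per randomisation — with a
pool far larger than any community, collisions are negligible.

Type-I calibration is part of the acceptance suite: under a no-effect
scenario with fully coded traits (so trait profiles are independent of
community membership), the significant fraction at α = 0.05 across 200
communities falls inside the exact binomial 99% envelope and mean SES is
within ±0.1 of zero. Gap-filling *induces* trait correlation among
relatives; combined with family-structured sampling this shifts SES
negative even without any treatment effect — a real property of
aggregated trait data worth remembering when interpreting SES from real
monitoring datasets.

## Paired inference

* **Delta-CWM**: per modality, upstream CWM − downstream CWM, tested
  against zero by a one-sample Wilcoxon signed-rank test. The sign
  convention follows upstream − downstream; a plotting flag can flip it.
  Zeros are dropped (Wilcoxon convention); for up to 14 non-zero deltas
  the null is enumerated exactly over all $2^n$ sign patterns on the
  midranks — valid under ties, where the textbook exact distribution is
  not — and a constant shift over 8 pairs yields exactly $2/256$. Larger
  samples use the normal approximation. P-values across the 49 modalities
  are reported uncorrected by default (and labelled as such), with a
  Benjamini–Hochberg option.
* **Paired Wilcoxon** on alpha metrics and on their SES, side by side —
  published practice is ambiguous about which of the two is tested, so
  both are reported. Pairs with undefined values are excluded and
  counted; fewer than 3 usable pairs refuses to test.
* **Spearman correlations** of beta SES components with plant covariates:
  connected households and population equivalents raw; effluent BOD,
  ammonium and total phosphorus natural-log transformed (zeros offset by
  half the minimum positive value — ranks are unaffected, only reported
  values).
* **EPT subset**: pairs whose upstream community holds ≥ 50% (inclusive)
  Ephemeroptera–Plecoptera–Trichoptera individuals. The functional space,
  dimensionality choice, metrics and null models are all *re-run from
  scratch* on the subset; a regression test asserts that subset FRic
  differs from merely filtering full-run values, i.e. the rebuild really
  happens.
* Dual-role intermediate sites (one site serving as downstream of one
  pair and upstream of the next) are supported by the generator and
  tolerated by all pair statistics, which treat pairs as the unit and do
  not adjust for the induced dependence — a documented limitation shared
  with the design it mirrors.

## The synthetic generator

`synthetic_scenario()` fixes the study conditions; `generate_dataset()`
derives everything deterministically from the seed. Defaults: 169 pairs,
a 444-taxon pool in a three-level taxonomy, nine trait groups / 49
modalities with Dirichlet(0.4) profiles discretised to 0–3, 25% of taxa
uncoded at species level (coverage in real monitoring data is similarly
partial), pool EPT fraction 0.35 assigned by family, community richness
uniform on 15–55 taxa, Dirichlet(0.6) abundance profiles (strong
dominance, as in field samples), negative-binomial totals (mean 500, size
5). Treatment-plant size classes follow the empirical five-class
frequency of the emulated monitoring design, and covariates are lognormal
with class-specific moments in which effluent concentrations rise as
plant size falls. No published abundance model exists for these
communities; the generator's defaults are conventions chosen once, not
estimates.

The downstream member of each pair is a multinomial resample of the
upstream relative abundances — coupling the pair as the sampling design
does — after multiplying the abundance of every taxon with affinity
≥ 0.5 for the configured `effect_modality` by `effect_strength` (1 = no
effect, 0 = extirpation). Under strength 1 the two members are
exchangeable; under strength 0 the penalised taxa vanish downstream
exactly. The generator records the penalised taxa and the implied sign of
the expected delta-CWM, enabling parameter-recovery tests: at strength
0.2 with 30 pairs the imposed shift is recovered with the correct sign in
≥ 95% of replicate datasets.

What the generator does *not* emulate: hydrology, chemistry, spatial
autocorrelation, realistic species identities, or trait syndromes
(correlations between trait groups). Passing tests therefore demonstrate
the correctness of the machinery, not that real communities behave like
the generator.

## Numerical choices and limitations

* Hull geometry is exact for up to three axes; sliver (near-degenerate)
  supporting triples are skipped during facet search because every true
  facet also contains a numerically robust triple; intersection volumes
  are assembled from the known half-space representation.
* MST ties inherit `vegan::spantree`'s deterministic index-order
  behaviour.
* All randomness flows through explicit seeds; per-stage seeds are
  derived from the scenario/run seed by a fixed affine rule, and null
  permutations are drawn up front so results are byte-identical across
  repeated runs and independent of the parallel worker count.
* Undefined metrics propagate as `NA`, are excluded pairwise from tests,
  and are counted in every output.
* The package does not compute functional divergence, TPD- or
  hypervolume-based richness, multi-community beta diversity, or
  abundance-weighted hull overlap.
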