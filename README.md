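# traitpair

Trait-based functional diversity analysis for stream macroinvertebrate
communities sampled in **upstream/downstream pairs** around point-source
discharges such as wastewater treatment plants (WWTPs).

Taxonomic surveys repeatedly find species turnover below WWTP outfalls.
Whether that turnover changes what communities *do* — their distribution
of feeding modes, locomotion types, reproduction strategies — depends on
functional redundancy: tolerant replacements may carry the same traits as
the sensitive species they displace. `traitpair` provides the full
analytical chain for testing this with paired monitoring data, plus a
synthetic paired-community generator with a known, tunable downstream
trait filter so that every stage can be validated against ground truth.

## What it computes

For fuzzy-coded traits (taxon × modality affinities in trait groups,
normalised so each group's profile sums to 1):

* **Trait preparation** — normalisation to relative frequencies and
  taxonomic gap-filling: uncoded taxa are raised to genus or family and
  receive the mean profile of coded relatives; merged taxa conserve
  abundance (`normalize_fuzzy()`, `fill_gaps()`).
* **Functional space** — Gower dissimilarity for fuzzy traits
  (per group ½·Manhattan on frequencies, averaged over groups), PCoA with
  square-root (or Cailliez) correction, and dimensionality selection by
  mean squared deviation between original and embedded distances
  (`build_functional_space()`).
* **Alpha diversity** per community (`alpha_diversity()`):
  community-weighted means CWM_k = Σᵢ pᵢ t_ik; functional richness FRic as
  the convex-hull volume in the first m axes (exact geometry, authored in
  C++, standardised by the pool hull); functional evenness FEve from the
  minimum spanning tree with branch weights d_ij/(pᵢ+pⱼ); functional
  dispersion FDis; Rao's quadratic entropy Q = Σᵢⱼ d_ij pᵢ pⱼ; Simpson
  diversity D; functional redundancy FR = Q/D.
* **Beta diversity** per pair (`beta_diversity()`): exact convex-hull
  intersection volumes in 3 axes, decomposed (Jaccard family) into
  turnover 2·min(B,C)/(V∩+2·min(B,C)) and a nestedness-resultant
  component, with β_turn + β_nest = β_total by construction.
* **Null models** (`null_models()`): taxon labels shuffled on the trait
  matrix over the full pool (default R = 999), SES =
  (obs − null mean)/null sd, two-tailed add-one rank p (an observation
  beyond all 999 nulls gets p = 0.002), and significant-fraction
  summaries.
* **Paired inference** (`delta_cwm_tests()`, `paired_tests()`,
  `covariate_correlations()`, `ept_subset()`): one-sample Wilcoxon tests
  of delta-CWM (upstream − downstream) per modality, exact by sign-pattern
  enumeration for small n; paired Wilcoxon on metrics and their SES;
  Spearman correlations of beta SES with WWTP covariates (size class,
  households, population equivalents, log BOD/NH₄⁺/total P); and the
  EPT-dominated subset (≥ 50% Ephemeroptera–Plecoptera–Trichoptera
  individuals upstream, boundary inclusive) with a fully rebuilt
  functional space.

## Worked example

```r
library(traitpair)

scenario <- synthetic_scenario(n_pairs = 12, pool_size = 80,
                               richness_range = c(8, 20),
                               n_ept_dominant = 4,
                               effect_modality = "grp3_m1",
                               effect_strength = 0.5, seed = 42)
dataset <- generate_dataset(scenario)
result  <- run_pipeline(dataset, run_config(R = 99, seed = 42))

result$coverage
#>        level  n   pct
#> 1   original 60 75.00
#> 2 subspecies  0  0.00
#> 3      genus 17 21.25
#> 4     family  3  3.75

head(result$full$alpha$metrics, 3)
#>        site  S       fric      feve      fdis       rao   simpson redundancy
#> 1   P001_up 14 0.43497646 0.7213930 0.4819290 0.5176252 0.7191665  0.7197572
#> 2 P001_down 14 0.43497646 0.7335393 0.4886665 0.5252147 0.7332506  0.7162827
#> 3   P002_up  8 0.04265292 0.6431855 0.4460809 0.4498357 0.6861796  0.6555655

result$full$sig_beta
#> $count
#> [1] 0
#> $n
#> [1] 12
#> $proportion
#> [1] 0
```

Reading this output: 75% of the 80-taxon pool kept species-level traits,
the rest were raised to genus or family by gap-filling. Each site gets
its alpha metrics (here the first pair has identical FRic up- and
downstream — same membership, so the same hull — while abundance-weighted
metrics differ slightly). `sig_beta` counts pairs whose total functional
beta diversity falls outside the trait-shuffling null at α = 0.05: none
of the 12 pairs here, as expected for a weak effect and few pairs.

The `analysis/` directory holds the same workflow as numbered stand-alone
scripts (`01_simulate.R` … `07_ept_subset.R`), each writing its tables
under `results/`.

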