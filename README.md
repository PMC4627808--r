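# rootpatch

Analysis chain linking the **functional composition of grassland plant
communities** to the **small-scale spatial distribution of insect root
herbivores** (wireworms and other soil-dwelling larvae) along transects —
for ecologists studying plant–herbivore interactions below ground and the
effect of land-use intensity on them.

The package implements, as tested reusable stages:

* **Community descriptors.** Shannon diversity H′ = −Σ pᵢ ln pᵢ and
  evenness J′ = H′/ln S per 0.3 × 0.3 m plot; community-weighted mean
  traits CWM_t = Σ c̃ᵢ x_{it} with cover weights renormalised over species
  carrying trait values and an 80 % cover-coverage rule applied per trait
  per plot; the land-use intensity index LUI = F_i/F_R + M_i/M_R + G_i/G_R;
  soil water content and water-holding capacity on a dry-weight basis.
* **Spatial statistics.** Mantel correlograms on Sturges-rule distance
  classes — K = ⌈1 + log₂ n(n−1)/2⌉, giving the canonical 10 classes
  (0–0.72 m, …, 7.44–8.28 m) for a 30-plot, 0.3 m transect — with
  sign-flipped class-membership Mantel r, permutation p-values, a
  progressive Holm correction and a patchy/autocorrelated/none pattern
  rule; global Moran's I with inverse-distance weights used to screen out
  sites with spatially structured counts.
* **Count models.** Zero-inflation-reducing aggregation over blocks of
  three adjacent cores (30 cores → 10 blocks, totals conserved), then one
  Poisson mixed model per z-standardised predictor
  (`count ~ region + z(x) + (1 | site)`) fitted by the package's own
  one-dimensional Laplace engine (`pglmm()`; adaptive Gauss–Hermite as a
  cross-check mode), with likelihood-ratio χ², parametric-bootstrap
  p-values, Nakagawa–Schielzeth conditional R², and ranking by |slope|.
* **Land-use effects.** Backward-stepwise LMMs of Mantel coefficients on
  LUI, water-holding capacity and distance class; site-level linear models
  of abundance, count variance and species richness on LUI.
* **Synthetic transects.** A generator producing the exact structure the
  chain assumes — patchy vegetation from Gaussian patch kernels,
  zero-inflated Poisson counts whose log-mean follows the CWM of a focal
  trait — so that every stage is verifiable against ground truth.

## Worked example

```r
library(rootpatch)

cfg <- run_config(sim = sim_config(seed = 1), n_perm = 199, n_boot = 0,
                  seed = 1)
bundle <- run_full(cfg)

table(bundle$patterns$parameter, bundle$patterns$pattern)
#>                autocorrelated none patchy
#>   counts_focal              1   26      1
#>   counts_total              1   27      0
#>   species                   0    0     28
#>   traits                    0    0     26

head(bundle$rankings$total[, c("predictor", "chisq", "p", "mean_intercept",
                               "slope", "r2")], 3)
#>     predictor     chisq            p mean_intercept       slope        r2
#> 1     cwm_sla 23.566832 1.206494e-06      0.5270138  0.29051446 0.3279220
#> 2 cwm_leaf_cn  2.095878 1.476969e-01      0.5265585 -0.09810966 0.3228097
#> 3    cwm_ldmc  1.367753 2.421984e-01      0.5310977  0.07246465 0.3023634
```

Plant species composition is patchy within every transect (significant
positive Mantel r in the shortest distance classes, negative further out),
herbivore counts almost never are, and the ranking recovers the simulated
effect: counts were generated with slope 0.3 on the z-scored CWM of
specific leaf area, and the fitted slope on the 270 blocks from the 27
sites retained by the Moran screen is 0.291 (likelihood-ratio χ² 23.6,
conditional R² 0.33); no other predictor comes close.

`bundle$site_lms` holds the site-level regressions on land-use intensity,
`bundle$moran_report` the excluded sites, and with `out_dir` set all tables
are written as CSV plus a JSON run manifest. `scripts/run_pipeline.R` wraps
the same call for shell use.

## Package layout

* `R/` — simulation (`sim_config`, `simulate_transects`, `write_fixtures`),
  community metrics (`shannon`, `evenness`, `cwm`, `lui_index`, …), spatial
  statistics (`sturges_classes`, `mantel_correlogram`, `global_morans_i`),
  mixed models (`aggregate_blocks`, `fit_poisson_glmm`, `pglmm`,
  `parametric_bootstrap_p`, `conditional_r2`, `fit_mcc_lmm`), pipeline
  (`run_config`, `run_full`).
* `vignettes/rootpatch-methods.Rmd` — the model, its assumptions, every
  tunable parameter, and what the synthetic generator does and does not
  emulate.
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (hand-rolled IRLS, brute-force Pearson and Moran
  double loops, `lme4::glmer` as external reference).
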