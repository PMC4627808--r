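---
title: "Linking plant functional composition to the small-scale distribution of insect root herbivores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking plant functional composition to the small-scale distribution of insect root herbivores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Soil-dwelling insect larvae (wireworms, weevil and chafer grubs, fly
larvae) feed on plant roots and can shape grassland plant communities by
creating patches of different herbivore pressure. Whether these herbivores
themselves track the *functional* composition of the plant canopy above
them — fast-growing, palatable vegetation versus tough, slow-growing
vegetation — is a question about very small spatial scales: root systems of
grassland plants influence the soil over well under a metre.

`rootpatch` implements a complete analysis chain for this question, built
around a transect design: per site, one 9 m transect of 30 soil cores and
30 adjacent 0.3 × 0.3 m vegetation plots at 0.3 m spacing, replicated over
28 sites in three regions spanning a land-use-intensity gradient. The chain
is

1. **plot-level community descriptors** — Shannon H′, evenness J′,
   community-weighted mean (CWM) traits, soil water content, a land-use
   intensity index (LUI);
2. **within-transect spatial statistics** — Mantel correlograms on
   Sturges-rule distance classes with permutation inference, and global
   Moran's I;
3. **predictor ranking** — Poisson mixed models of herbivore counts on one
   z-standardised predictor at a time, with a site random intercept, region
   fixed effect, parametric-bootstrap term tests and conditional R²;
4. **land-use effects** — mixed models of Mantel coefficients on LUI, soil
   water-holding capacity and distance, and site-level linear models.

Because the original field records are not deposited anywhere, the package
ships a synthetic-transect generator with exactly the statistical structure
the analysis assumes. Every stage can therefore be verified against known
ground truth at desk scale.

## Community descriptors

For a plot with percent covers $c_i$ and cover shares $p_i = c_i / \sum c_i$:

* Shannon diversity $H' = -\sum_i p_i \ln p_i$ and evenness
  $J' = H' / \ln S$ with $S$ the species richness. (The negative-sum form is
  used: it is the only form that yields positive index values.)
* CWM traits: $\mathrm{CWM}_t = \sum_i \tilde c_i \, x_{it}$, where
  $x_{it}$ is species $i$'s value of trait $t$ and $\tilde c_i$ are cover
  shares renormalised over the species that *have* a value for trait $t$.
  A plot is **omitted for trait $t$** when those species hold less than 80 %
  of the plot's total cover (`coverage_threshold`); the rule is applied per
  trait per plot, so a plot can be retained for specific leaf area but
  omitted for root density. Renormalising over covered species (rather than
  keeping the raw shares) is the conventional treatment of missing trait
  values in CWM work.
* Land-use intensity: $\mathrm{LUI} = F_i/F_R + M_i/M_R + G_i/G_R$ —
  fertilisation (kg N ha⁻¹ yr⁻¹), mowing (cuts yr⁻¹) and grazing (livestock
  units × days ha⁻¹), each standardised by its regional mean. A component
  that is zero both at the site and regionally contributes zero.
* Soil water on a dry-weight basis:
  $\mathrm{WC} = (\text{fresh} - \text{dry})/\text{dry} \times 100$ and
  analogously WHC from the two saturated transect-end cores (site value =
  mean of the two). Values above 100 % are legitimate in organic soils.

## Spatial statistics

**Distance classes.** The number of classes follows the Sturges rule
applied to the number of plot *pairs*: $K = \lceil 1 + \log_2 n(n-1)/2
\rceil$, which gives $K = 10$ for a 30-plot transect (435 pairs). Classes
have common width $w = (d_{\max} - d_{\min})/K$ and are centred at
$d_{\min} + k\,w$, $k = 0,\dots,K-1$; the first class is truncated at zero
and pairs beyond the last upper boundary are excluded. On the 9 m / 0.3 m
design this produces the boundaries 0–0.72 m, 0.72–1.56 m, …,
7.44–8.28 m and drops the two longest separations (8.4 m, 8.7 m). Applying
Sturges to the number of plots instead would give 6 classes and different
boundaries; the pair-count convention is the one consistent with the
correlogram literature for this design.

**Mantel correlogram.** For each class $k$, the Mantel statistic $r_k$ is
the Pearson correlation between the unfolded upper triangle of the
dissimilarity matrix (Bray–Curtis for species composition, Euclidean for
the column-scaled CWM trait matrix, absolute differences for univariate
counts) and the binary membership indicator of class $k$, with the sign
flipped so that $r_k > 0$ reads "plots within this class are more similar
than average". Significance is assessed by simultaneously permuting rows
and columns of the dissimilarity matrix (default 999 permutations,
two-sided $p = (1 + \#\{|r^*| \ge |r|\})/(n_\mathrm{perm}+1)$), and a
progressive Holm correction multiplies the $p$-value of class $k$ by $k$ —
classes are evaluated in order of increasing distance, while they contain
pairs.

A transect is classified **autocorrelated** when any class is significant
after correction, and **patchy** when additionally one of the first two
classes is significantly *positive* and some later class coefficient falls
to zero or below — the signature of similarity decaying from patch centres.

**Moran's I** uses inverse-distance weights $w_{ij} = 1/d_{ij}$
(row-unstandardised, a deliberate and documented choice since no weighting
scheme is canonical for transects), null expectation $-1/(n-1)$, and a
two-sided permutation test around that expectation. Sites whose raw counts
show significant Moran's I are excluded from the mixed models, because
spatial structure in the response would bias them.

## Count models

Per-core counts are heavily zero-inflated (typically > 50 % zeros at a mean
well below one individual per core). Rather than fitting an explicit
zero-inflated mixed model, counts are summed and predictors averaged over
blocks of three adjacent cores — 10 blocks per transect — which removes
most zeros while preserving totals exactly. Blocks containing a plot that
is coverage-omitted for a CWM trait are dropped for that trait only.

Each predictor is then modelled separately:

$$y_{sb} \sim \mathrm{Poisson}(\mu_{sb}), \qquad
\log \mu_{sb} = \alpha_{r(s)} + \beta \, z(x_{sb}) + u_s, \qquad
u_s \sim N(0, \sigma^2_\text{site}),$$

with region $r$ a fixed factor (too few regions for a random term) and
$z(\cdot)$ the z-standardisation pooled over all retained blocks of all
sites — pooling is what makes slopes comparable across predictors and is
the scope consistent with reporting a single slope per predictor. Bare-soil
cover is log-transformed (log(x+1)) before standardisation. For reporting,
the per-region intercepts are averaged arithmetically on the link scale.

The marginal likelihood is maximised by the package's own engine
([`pglmm()`]): the site intercept is one-dimensional, so it is profiled out
per site by an exact Newton iteration and the Laplace approximation is
applied around the mode; adaptive Gauss–Hermite quadrature with 10 nodes is
available as an accuracy cross-check (`method = "agq"`). The engine agrees
with `lme4::glmer` to four decimals on typical data (this is asserted in
the test suite, with `glmer` as the independent reference) and collapses
exactly to an ordinary Poisson GLM when $\sigma_\text{site} = 0$. It exists
because the analysis rests on parametric-bootstrap inference — hundreds of
refits per test — and a specialised one-dimensional fitter makes that cheap.

**Term tests.** The likelihood-ratio statistic for dropping a term is
calibrated by a parametric bootstrap: simulate responses from the reduced
fit, refit both models, and take $p = (1 + \#\{\mathrm{LRT}^* \ge
\mathrm{LRT}\})/(n_\mathrm{ok}+1)$ (default 500 samples; failed refits are
dropped and counted). **Conditional R²** follows the variance-partition
form for GLMMs:

$$R^2_c = \frac{\sigma^2_f + \sigma^2_\text{site}}
{\sigma^2_f + \sigma^2_\text{site} + \sigma^2_\varepsilon},$$

with $\sigma^2_f$ the variance of the fixed-effect linear predictor and
$\sigma^2_\varepsilon$ the observation-level Poisson variance mapped to the
log scale by the lognormal approximation $\ln(1 + 1/\bar\lambda)$
($\bar\lambda$ = mean fitted count); the trigamma variant
$\psi_1(\bar\lambda)$ is available behind `approx = "trigamma"`. The
literature defines both variants; the lognormal form is the default here
because it is the more widely reported one.

Predictors are ranked by $|\beta|$ (ties broken alphabetically, so the
order is reproducible).

**Spatial pattern vs land use.** For parameters that display spatial
structure at most sites, the per-class Mantel coefficients enter a Gaussian
LMM (ML) on LUI + WHC + distance-class midpoint with all pairwise
interactions and a site random intercept. Backward elimination removes, at
each step, the candidate term with the largest bootstrap $p > 0.05$,
testing interactions before main effects and never dropping a main effect
while an interaction containing it survives.

## The synthetic generator

The generator's defaults encode the study conditions the analysis was
designed for: 28 sites (10/9/9 across three regions), 30 plots at 0.3 m, a
190-species pool with ten traits (specific leaf area, leaf dry matter
content, leaf density, vegetative/reproductive height, leaf and root C/N,
vegetative spread, root density in soil and topsoil) whose species-level
distributions are centred so that community-weighted means land near 20
mm² mg⁻¹ SLA, 316 mg g⁻¹ LDMC, and so on. Missing trait values are
assigned at per-trait rates chosen so the per-trait fraction of
coverage-omitted plots is small for leaf traits and roughly a fifth for
the root densities — the sparsest traits in practice.

Vegetation is patchy by construction: each species receives a Poisson
number of Gaussian patch kernels (`patch_length_scale`, default 1 m — the
lateral influence zone of grassland root systems) and a lognormal abundance
weight; a few "matrix" species carry smooth background cover so no plot is
bare; plot totals are rescaled to a lognormal around 95 % (sums above 100 %
occur, as layered canopies do). This yields Bray–Curtis similarity decaying
over the patch length scale, i.e. correlograms that are significantly
positive in the first distance class and negative further out — and the
first-class coefficient rises monotonically with `patch_length_scale`,
which is checked by a rank-correlation property test.

Counts follow exactly the model the analysis fits, plus structural zeros:
per core, $y \sim \pi_0\,\delta_0 + (1-\pi_0)\,
\mathrm{Poisson}(\lambda)$ with $\log\lambda = \beta_0 + \text{region} +
u_\text{site} + \beta_t\, z(\mathrm{CWM}_t)$. Defaults:
$\pi_0 = 0.25$, $\beta_0 = -0.13$ (so the marginal mean is ≈ 0.66
individuals per core, ≈ 20 per 30-core transect), $\beta_t = 0.3$ on the
SLA CWM, $\sigma_\text{site} = 0.4$, region offsets (0, 0.15, −0.15).
Totals are split into eight herbivore families by a multinomial whose
shares are dominated by click-beetle (Elateridae) larvae at 43 %. Soil
measurements are lognormal around site means (water content ≈ 33 % of dry
weight between sites with ~4 % variation within a site; WHC 63 ± 26 %;
root dry mass 0.6 ± 0.5 g); management intensities span LUI ≈ 0.5–3.5.

What the generator does *not* emulate: overdispersion beyond the
structural-zero mechanism, within-site correlation of counts beyond the
CWM coupling (the spatial structure of counts under patchiness is not
specified by the design, so coupling through the vegetation is the one
defensible choice), species turnover between regions, measurement error in
traits, and temporal dynamics. Passing tests therefore demonstrate that the
chain recovers the structure it assumes — not that real field data meet
those assumptions.

## Numerical choices and degenerate inputs

* Permutation p-values use the add-one convention, so the smallest
  attainable p is $1/(n_\mathrm{perm}+1)$ and p-values are super-uniform
  under the null.
* Distance-class membership uses half-open intervals (lower, upper] with a
  10⁻⁹ tolerance; class boundaries on this design never coincide with
  realised distances.
* Classes with fewer than three pairs give `NA` coefficients; a constant
  dissimilarity matrix gives an all-`NA` correlogram classified `"none"`.
* All-zero cover plots, constant predictor vectors, single-species
  evenness, fresh weight below dry weight, and a positive site intensity
  with a zero regional mean are all rejected with explicit errors rather
  than silent `NaN`s.
* The GLMM optimiser is L-BFGS-B on $(\beta, \sigma)$ with $\sigma \ge 0$;
  warm-started bootstrap refits skip the polish pass and the Hessian.
  Likelihoods include the full Poisson constant so they are directly
  comparable with `lme4`.
* Problem sizes in the test suite were chosen for desk-scale verification:
  500 null transects at 199 permutations for correlogram calibration, 200
  replicates for slope recovery (28 sites × 10 blocks), 200 outer
  replicates at 199 bootstrap samples (8 sites × 10 blocks) for the
  bootstrap size check, 1000 transects for the Moran null.

## Known limitations

* The per-predictor modelling strategy mirrors the reporting format it
  reproduces (one slope per predictor); it does not address collinearity
  among CWM traits, and no multi-predictor or model-averaged variant is
  provided.
* Zero inflation is handled by aggregation, not by an explicit
  mixture-model likelihood; with extreme $\pi_0$ the block counts remain
  zero-heavy and fits will flag non-convergence.
* The Moran's-I exclusion rule and the inverse-distance weights are one
  defensible convention; exclusion decisions near $\alpha$ are sensitive to
  the permutation seed.
* Mantel correlograms on short transects have limited power in the last
  classes, where few pairs remain; interpret far-class coefficients with
  care.

## Reproducing a full run

```r
library(rootpatch)
cfg <- run_config(sim = sim_config(seed = 1), n_perm = 199, n_boot = 0,
                  seed = 1, out_dir = "results/run1")
bundle <- run_full(cfg)
bundle$rankings$total       # Poisson-GLMM predictor ranking
bundle$patterns             # per-site spatial pattern classification
bundle$site_lms             # site-level responses vs land-use intensity
```

`scripts/run_pipeline.R` wraps the same call for shell use, and
`scripts/acceptance.R` recomputes the package's headline quantities from
scratch (see the README).
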