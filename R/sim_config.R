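#' Default species-pool trait definitions
#'
#' Ten functional traits with species-level distributions chosen so that
#' community-weighted means land in the range observed in managed temperate
#' grasslands: specific leaf area around 20 mm^2 mg^-1, leaf dry matter
#' content around 316 mg g^-1, leaf density 0.29 mg mm^-3, vegetative and
#' reproductive heights 0.24 and 0.39 m, leaf and root C/N 19.6 and 36.6,
#' vegetative spread 0.06 m, and root densities 0.07 and 0.12 %. Positive,
#' right-skewed traits are lognormal; C/N ratios and LDMC are (truncated)
#' normal. `missing_frac` is the fraction of species lacking a value, which
#' exercises the cover-coverage rule downstream (root densities are the
#' sparsest, mirroring how hard root traits are to source).
#'
#' @return Data frame with columns `trait`, `mean`, `sd`, `lognormal`,
#'   `missing_frac`.
#' @export
default_trait_table <- function() {
  data.frame(
    trait = c("sla", "ldmc", "leaf_density", "vh", "rh", "leaf_cn", "root_cn",
              "veg_spread", "root_density_soil", "root_density_topsoil"),
    mean = c(20.1, 316, 0.29, 0.24, 0.39, 19.6, 36.6, 0.06, 0.07, 0.12),
    sd = c(6, 80, 0.09, 0.12, 0.18, 5, 10, 0.05, 0.035, 0.06),
    lognormal = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    missing_frac = c(0, 0, 0.04, 0, 0, 0.04, 0.04, 0, 0.10, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Root-herbivore family composition of the simulated counts
#'
#' Multinomial shares used to split each core's total count into families;
#' defaults reflect a grassland assemblage dominated by click-beetle
#' (Elateridae) larvae at 43% of individuals.
#' @return Named numeric vector of shares summing to 1.
#' @export
default_family_shares <- function() {
  c(Byrrhiidae = 0.002, Chrysomelidae = 0.045, Curculionidae = 0.183,
    Elateridae = 0.430, Scarabaeidae = 0.002, Cecidomyiidae = 0.296,
    Stratiomyidae = 0.004, Tipulidae = 0.038)
}

#' Configuration of the synthetic transect generator
#'
#' Defines the study layout (three regions holding 10/9/9 sites, one 9 m
#' transect of 30 plots at 0.3 m spacing per site), the species pool (190
#' species, 10 traits), the vegetation patch model, the count model (per-core
#' zero-inflated Poisson whose log-mean depends on the z-scored
#' community-weighted mean of a focal trait, with region fixed offsets and a
#' normal site random intercept), soil-measurement distributions, and
#' per-site management intensities.
#'
#' @param n_regions Number of regions.
#' @param sites_per_region Integer vector (length `n_regions`) of sites per
#'   region.
#' @param plots_per_site Plots (= soil cores) per transect.
#' @param spacing Plot spacing in m.
#' @param n_species Species-pool size.
#' @param n_species_site Species drawn from the pool at each site.
#' @param n_matrix_species Site-level "matrix" species with near-constant
#'   background cover (keeps every plot vegetated).
#' @param n_patches_per_site Mean number of patches per species per transect
#'   (Poisson distributed).
#' @param patch_length_scale Gaussian patch kernel length scale, m.
#' @param traits Trait definition table, see [default_trait_table()].
#' @param beta0 Baseline log-mean herbivore count per core.
#' @param beta_trait Effect of the z-scored focal-trait CWM on the log-mean.
#' @param focal_trait Trait driving counts.
#' @param site_intercept_sd SD of the normal site random intercept (>= 0).
#' @param region_effects Fixed log-scale offsets, one per region.
#' @param zero_inflation_pi Probability of a structural zero per core.
#' @param family_shares Family composition of counts,
#'   see [default_family_shares()].
#' @param target_cover_mean,target_cover_cv Lognormal plot total-cover model
#'   (% — sums above 100 occur, as layered canopies do).
#' @param bare_soil_mean Mean bare-soil cover per plot (%; exponential).
#' @param wc_mean,wc_site_cv,wc_within_cv Soil water content: grand mean
#'   (% of dry weight), between-site CV, within-site CV (~4%).
#' @param whc_mean,whc_sd Site water-holding capacity distribution (%).
#' @param core_dry_wt Mean core dry weight, g.
#' @param root_mass_mean,root_mass_sd Root dry mass per core, g.
#' @param seed Integer seed; fixes every random draw of the generator.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_regions = 3,
                       sites_per_region = c(10, 9, 9),
                       plots_per_site = 30,
                       spacing = 0.3,
                       n_species = 190,
                       n_species_site = 35,
                       n_matrix_species = 3,
                       n_patches_per_site = 2,
                       patch_length_scale = 1,
                       traits = default_trait_table(),
                       beta0 = -0.13,
                       beta_trait = 0.3,
                       focal_trait = "sla",
                       site_intercept_sd = 0.4,
                       region_effects = c(0, 0.15, -0.15),
                       zero_inflation_pi = 0.25,
                       family_shares = default_family_shares(),
                       target_cover_mean = 95.6,
                       target_cover_cv = 0.3,
                       bare_soil_mean = 9.7,
                       wc_mean = 32.7,
                       wc_site_cv = 0.55,
                       wc_within_cv = 0.04,
                       whc_mean = 63,
                       whc_sd = 26,
                       core_dry_wt = 120,
                       root_mass_mean = 0.6,
                       root_mass_sd = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(sites_per_region) != n_regions) {
      stop("sites_per_region must have one entry per region")
    }
    if (length(region_effects) != n_regions) {
      stop("region_effects must have one entry per region")
    }
    if (n_species < 2) stop("need at least 2 species")
    if (plots_per_site < 3) stop("need at least 3 plots per transect")
    if (spacing <= 0) stop("spacing must be positive")
    if (patch_length_scale <= 0) stop("patch_length_scale must be positive")
    if (any(traits$sd < 0)) stop("trait sds must be non-negative")
    if (any(traits$missing_frac < 0 | traits$missing_frac > 1)) {
      stop("missing_frac must lie in [0, 1]")
    }
    if (site_intercept_sd < 0) stop("site_intercept_sd must be non-negative")
    if (zero_inflation_pi < 0 || zero_inflation_pi > 1) {
      stop("zero_inflation_pi must lie in [0, 1]")
    }
    if (!focal_trait %in% traits$trait) stop("unknown focal_trait")
    if (abs(sum(family_shares) - 1) > 1e-6) stop("family shares must sum to 1")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic transect configuration:\n")
  cat(" ", sum(x$sites_per_region), "sites in", x$n_regions, "regions;",
      x$plots_per_site, "plots at", x$spacing, "m spacing\n")
  cat(" ", x$n_species, "species pool,", nrow(x$traits), "traits; patch scale",
      x$patch_length_scale, "m\n")
  cat("  counts: beta0 =", x$beta0, "beta_trait =", x$beta_trait,
      "on", x$focal_trait, "; pi0 =", x$zero_inflation_pi,
      "; site sd =", x$site_intercept_sd, "\n")
  invisible(x)
}
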