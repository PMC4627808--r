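#' Shannon diversity of a plot community
#'
#' Computes H' = -sum(p_i * ln(p_i)) where p_i is the share of total ground
#' cover held by species i. Species with zero cover contribute nothing.
#' Because cover shares are relative, H' is invariant to rescaling all covers
#' by a common factor.
#'
#' @param cover_by_species Numeric vector of percent covers (>= 0), one entry
#'   per species. Names optional.
#' @return Shannon index H' (natural log), a non-negative scalar.
#' @examples
#' shannon(c(50, 50))     # log(2)
#' shannon(c(grass = 80)) # 0: single species
#' @export
shannon <- function(cover_by_species) {
  stopifnot(is.numeric(cover_by_species))
  if (any(cover_by_species < 0)) stop("covers must be non-negative")
  total <- sum(cover_by_species)
  if (total <= 0) stop("all covers are zero: Shannon index undefined")
  p <- cover_by_species[cover_by_species > 0] / total
  -sum(p * log(p))
}

#' Pielou's evenness
#'
#' J' = H' / ln(S) with S the species richness. Defined only for S >= 2.
#'
#' @param h Shannon index of the plot.
#' @param s Species richness (count of species with positive cover).
#' @return Evenness in \[0, 1\].
#' @export
evenness <- function(h, s) {
  stopifnot(is.numeric(h), length(h) == 1L, is.numeric(s), length(s) == 1L)
  if (s < 2) stop("evenness undefined for fewer than 2 species (ln(S) = 0)")
  h / log(s)
}

#' Leaf trait derivations from raw leaf measurements
#'
#' Specific leaf area SLA = area / dry mass (mm^2 mg^-1), leaf dry matter
#' content LDMC = dry mass / fresh mass (reported in mg g^-1), and leaf
#' density = dry mass / (area * thickness) (mg mm^-3).
#'
#' @param area_mm2 Leaf area, mm^2.
#' @param fresh_mass_mg Rehydrated fresh mass, mg.
#' @param dry_mass_mg Oven-dry mass, mg.
#' @param thickness_mm Leaf thickness, mm.
#' @return Named list with `sla`, `ldmc`, `leaf_density`.
#' @export
leaf_traits <- function(area_mm2, fresh_mass_mg, dry_mass_mg, thickness_mm) {
  vals <- c(area_mm2, fresh_mass_mg, dry_mass_mg, thickness_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all leaf measurements must be positive and finite")
  }
  if (dry_mass_mg > fresh_mass_mg) stop("dry mass exceeds fresh mass")
  list(
    sla = area_mm2 / dry_mass_mg,
    ldmc = dry_mass_mg / fresh_mass_mg * 1000, # mg dry per g fresh
    leaf_density = dry_mass_mg / (area_mm2 * thickness_mm)
  )
}

#' Community-weighted mean traits for one plot
#'
#' For each trait, the CWM is sum(c_i * trait_i) where c_i is the relative
#' cover contribution of species i, renormalized over the species that carry a
#' value for that trait. A trait is reported only when those species jointly
#' hold at least `coverage_threshold` of the plot's total cover; otherwise the
#' plot is marked omitted for that trait. The rule is applied per trait, so a
#' plot can be retained for one trait and omitted for another.
#'
#' @param cover_by_species Named numeric vector of percent covers (>= 0);
#'   names must match rownames of `traits`.
#' @param traits Data frame or matrix, species x traits; `NA` marks a missing
#'   trait value.
#' @param coverage_threshold Minimum fraction of total cover that must be
#'   contributed by species with a trait value (default 0.8).
#' @return Data frame with one row per trait: `trait`, `cwm`,
#'   `covered_fraction`, `omitted`.
#' @examples
#' tr <- data.frame(sla = c(10, 30), row.names = c("a", "b"))
#' cwm(c(a = 60, b = 40), tr)  # 0.6*10 + 0.4*30 = 18
#' @export
cwm <- function(cover_by_species, traits, coverage_threshold = 0.8) {
  stopifnot(is.numeric(cover_by_species))
  if (any(cover_by_species < 0)) stop("covers must be non-negative")
  total <- sum(cover_by_species)
  if (total <= 0) stop("plot has no cover: CWM undefined")
  if (is.null(names(cover_by_species))) stop("cover vector must be named by species")
  traits <- as.data.frame(traits)
  out <- data.frame(
    trait = colnames(traits), cwm = NA_real_,
    covered_fraction = 0, omitted = TRUE,
    stringsAsFactors = FALSE
  )
  if (ncol(traits) == 0L) return(out)
  present <- names(cover_by_species)[cover_by_species > 0]
  for (k in seq_along(out$trait)) {
    tv <- traits[[k]]
    names(tv) <- rownames(traits)
    contrib <- present[present %in% rownames(traits) & !is.na(tv[present])]
    covered <- sum(cover_by_species[contrib]) / total
    out$covered_fraction[k] <- covered
    if (covered >= coverage_threshold && length(contrib) > 0) {
      ci <- cover_by_species[contrib] / sum(cover_by_species[contrib])
      out$cwm[k] <- sum(ci * tv[contrib])
      out$omitted[k] <- FALSE
    }
  }
  out
}

#' Land-use intensity index
#'
#' LUI = F_i/F_R + M_i/M_R + G_i/G_R: site fertilization (kg N ha^-1), mowing
#' (cuts yr^-1) and grazing (livestock units d ha^-1) each standardized by the
#' regional mean. A component that is zero both at the site and in the
#' regional mean contributes zero.
#'
#' @param f,m,g Site-level fertilization, mowing, grazing intensities (>= 0).
#' @param f_r,m_r,g_r Regional mean intensities.
#' @return The LUI index, a non-negative scalar.
#' @examples
#' lui_index(47, 3, 0, f_r = 94, m_r = 2, g_r = 100)  # 0.5 + 1.5 + 0 = 2
#' @export
lui_index <- function(f, m, g, f_r, m_r, g_r) {
  comp <- function(x, xr, lab) {
    if (x < 0 || xr < 0) stop(lab, ": intensities must be non-negative")
    if (xr == 0) {
      if (x > 0) stop(lab, ": site value positive but regional mean zero")
      return(0)
    }
    x / xr
  }
  comp(f, f_r, "fertilization") + comp(m, m_r, "mowing") + comp(g, g_r, "grazing")
}

#' Gravimetric soil water content
#'
#' WC = (fresh weight - dry weight) / dry weight x 100, i.e. percent of soil
#' dry weight (so values above 100 are possible in wet organic soils).
#'
#' @param fresh_wt,dry_wt Core weights in g (fresh >= dry > 0).
#' @return Water content, % of dry weight.
#' @export
water_content <- function(fresh_wt, dry_wt) {
  if (any(dry_wt <= 0)) stop("dry weight must be positive")
  if (any(fresh_wt < dry_wt)) stop("fresh weight below dry weight")
  (fresh_wt - dry_wt) / dry_wt * 100
}

#' Soil water-holding capacity
#'
#' WHC = (saturated weight - dry weight) / dry weight x 100 on cores dried at
#' 105 degrees C; the site value is the mean over the two transect-end cores.
#'
#' @param saturated_wt,dry105_wt Core weights in g (saturated >= dry > 0);
#'   vectors are averaged after the per-core ratio.
#' @return WHC, % of soil dry weight (site mean if vectors supplied).
#' @export
water_holding_capacity <- function(saturated_wt, dry105_wt) {
  if (any(dry105_wt <= 0)) stop("dry weight must be positive")
  if (any(saturated_wt < dry105_wt)) stop("saturated weight below dry weight")
  mean((saturated_wt - dry105_wt) / dry105_wt * 100)
}

#' z-standardize a predictor
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator). Standardization is computed over the full vector supplied, so
#' pooling across sites is the caller's choice of scope. `NA`s are ignored in
#' the moments and preserved in the output.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Vector of z-scores, same length and names as `x`.
#' @export
z_standardize <- function(x) {
  stopifnot(is.numeric(x))
  ok <- is.finite(x)
  if (sum(ok) < 2L || length(unique(x[ok])) < 2L) {
    stop("z-standardization needs at least two distinct finite values")
  }
  (x - mean(x[ok])) / stats::sd(x[ok])
}

#' Plot-level metrics table for one transect dataset
#'
#' Assembles the tidy per-plot predictor table used downstream: species
#' richness, Shannon H', evenness J', summed plant cover, bare-soil cover,
#' per-core soil measurements, and one CWM column per trait together with its
#' omission flag (coverage rule applied per trait per plot).
#'
#' @param dataset A transect dataset as produced by [simulate_transects()] or
#'   [read_transect_data()] (one element of the `sites` list).
#' @param traits Species x trait table ([generate_species_pool()] format).
#' @param coverage_threshold Coverage rule threshold, default 0.8.
#' @return Data frame with one row per plot.
#' @export
plot_metrics <- function(dataset, traits, coverage_threshold = 0.8) {
  cov <- dataset$cover
  n <- nrow(cov)
  counts_tot <- total_counts(dataset)
  res <- data.frame(
    site_id = dataset$site_id,
    region_id = dataset$region_id,
    plot_index = seq_len(n),
    position = dataset$plot_positions,
    count = counts_tot,
    richness = apply(cov, 1, function(x) sum(x > 0)),
    plant_cover = rowSums(cov),
    bare_soil = dataset$bare_soil,
    stringsAsFactors = FALSE
  )
  res$shannon <- apply(cov, 1, shannon)
  res$evenness <- ifelse(res$richness >= 2,
    mapply(function(h, s) h / log(s), res$shannon, res$richness), NA_real_
  )
  res$water_content <- water_content(dataset$soil$fresh_wt_g, dataset$soil$dry_wt_g)
  res$root_dry_mass <- dataset$soil$root_dry_mass_g
  for (tr in colnames(traits)) {
    res[[paste0("cwm_", tr)]] <- NA_real_
    res[[paste0("omitted_", tr)]] <- TRUE
  }
  for (i in seq_len(n)) {
    cw <- cwm(cov[i, ], traits, coverage_threshold)
    res[i, paste0("cwm_", cw$trait)] <- cw$cwm
    res[i, paste0("omitted_", cw$trait)] <- cw$omitted
  }
  res
}

#' Per-core total herbivore count (all families) in plot order
#'
#' @param dataset One site's transect dataset.
#' @return Integer vector, one total per plot.
#' @export
total_counts <- function(dataset) {
  agg <- tapply(dataset$counts$count, dataset$counts$plot_index, sum)
  as.vector(agg[as.character(seq_along(dataset$plot_positions))])
}
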