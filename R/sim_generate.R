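# Lognormal draws parameterized by arithmetic mean and coefficient of
# variation; degenerate at the mean when cv = 0.
rlnorm_mean <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate the species trait pool
#'
#' Draws one value per species and trait from the per-trait distributions in
#' `cfg$traits` (lognormal for right-skewed positive traits, truncated normal
#' otherwise), then blanks a per-trait fraction of species to `NA` so the
#' cover-coverage rule has something to act on. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Data frame, species (rownames `sp001`...) x traits; `NA` = missing.
#' @export
generate_species_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_species
  tt <- cfg$traits
  pool <- as.data.frame(lapply(seq_len(nrow(tt)), function(k) {
    if (tt$sd[k] == 0) {
      vals <- rep(tt$mean[k], n)
    } else if (tt$lognormal[k]) {
      vals <- rlnorm_mean(n, tt$mean[k], tt$sd[k] / tt$mean[k])
    } else {
      vals <- pmax(stats::rnorm(n, tt$mean[k], tt$sd[k]), tt$mean[k] * 0.05)
    }
    n_miss <- floor(tt$missing_frac[k] * n)
    if (n_miss > 0) vals[sample.int(n, n_miss)] <- NA_real_
    vals
  }))
  colnames(pool) <- tt$trait
  rownames(pool) <- sprintf("sp%03d", seq_len(n))
  pool
}

# Site identifiers "R<r>S<s>" and their region index, in generation order.
site_layout <- function(cfg) {
  region <- rep(seq_len(cfg$n_regions), cfg$sites_per_region)
  data.frame(
    site_id = sprintf("R%dS%02d", region,
                      unlist(lapply(cfg$sites_per_region, seq_len))),
    region_id = region, stringsAsFactors = FALSE
  )
}

#' Generate patchy vegetation cover along each transect
#'
#' Each site draws a species subset from the pool. Every species receives a
#' Poisson number of patch centers on the transect and a lognormal abundance
#' weight; its raw cover at a plot is the weight times the sum of Gaussian
#' kernels exp(-((x - c) / l)^2 / 2) over its centers, with
#' l = `patch_length_scale`. A few "matrix" species carry smooth background
#' cover so no plot is bare. Raw covers below 0.1% are zeroed and each plot is
#' rescaled to a lognormal total cover (sums above 100% occur, as in layered
#' canopies). Expected between-plot Bray-Curtis similarity therefore decays
#' with separation on the scale of `patch_length_scale`.
#'
#' @param cfg A [sim_config()].
#' @param pool Species pool from [generate_species_pool()] (supplies names).
#' @return Named list (by site id) of plot x species cover matrices.
#' @export
generate_vegetation <- function(cfg, pool) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  layout <- site_layout(cfg)
  x <- (seq_len(cfg$plots_per_site) - 1) * cfg$spacing
  extent <- max(x)
  ell <- cfg$patch_length_scale
  out <- vector("list", nrow(layout))
  names(out) <- layout$site_id
  for (s in seq_len(nrow(layout))) {
    n_sub <- min(cfg$n_species_site, cfg$n_species)
    sub <- sort(sample.int(cfg$n_species, n_sub))
    spp <- rownames(pool)[sub]
    cov <- matrix(0, nrow = length(x), ncol = n_sub,
                  dimnames = list(NULL, spp))
    weights <- rlnorm_mean(n_sub, 1, 1.2)
    n_matrix <- min(cfg$n_matrix_species, n_sub)
    for (j in seq_len(n_sub)) {
      if (j <= n_matrix) {
        # background species: broad smooth cover across the whole transect
        base <- rlnorm_mean(1, 0.8, 0.3)
        cov[, j] <- base * (1 + 0.1 * sin(2 * pi * x / extent +
                                            stats::runif(1, 0, 2 * pi)))
        next
      }
      n_pat <- stats::rpois(1, cfg$n_patches_per_site)
      if (n_pat == 0) next
      centers <- stats::runif(n_pat, -ell / 2, extent + ell / 2)
      kern <- rowSums(exp(-0.5 * outer(x, centers, "-")^2 / ell^2))
      cov[, j] <- weights[j] * kern
    }
    cov[cov < 0.02 * max(cov)] <- 0
    totals <- rlnorm_mean(length(x), cfg$target_cover_mean, cfg$target_cover_cv)
    raw_tot <- rowSums(cov)
    raw_tot[raw_tot == 0] <- 1
    cov <- cov * totals / raw_tot
    cov[cov > 0 & cov < 0.1] <- 0.1 # trace cover recorded as 0.1%
    out[[s]] <- cov[, colSums(cov) > 0, drop = FALSE] # unobserved spp absent
  }
  out
}

#' Generate zero-inflated Poisson herbivore counts per core
#'
#' log-mean = beta0 + region effect + site random intercept (normal, sd
#' `site_intercept_sd`) + `beta_trait` x z(CWM of the focal trait, pooled over
#' all cores); a structural zero replaces the Poisson draw with probability
#' `zero_inflation_pi`. The marginal per-core mean is therefore
#' (1 - pi) * lambda.
#'
#' @param cfg A [sim_config()].
#' @param cwm Data frame with columns `site_id`, `region_id`, `plot_index`
#'   and a column named after `focal_trait` (or `cwm_<focal_trait>`) holding
#'   the plot-level community-weighted mean; no missing values.
#' @param focal_trait Trait name; must match `cfg$traits`.
#' @return `cwm` with columns `lambda`, `count` (total per core) appended.
#' @export
generate_counts <- function(cfg, cwm, focal_trait = cfg$focal_trait) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!focal_trait %in% cfg$traits$trait) {
    stop("unknown focal trait: ", focal_trait)
  }
  col <- if (focal_trait %in% names(cwm)) focal_trait
         else paste0("cwm_", focal_trait)
  if (!col %in% names(cwm)) stop("cwm table lacks a column for ", focal_trait)
  if (anyNA(cwm[[col]])) stop("missing CWM values for focal trait")
  set.seed(cfg$seed + 2L)
  z <- z_standardize(cwm[[col]])
  sites <- unique(cwm$site_id)
  b_site <- stats::rnorm(length(sites), 0, cfg$site_intercept_sd)
  names(b_site) <- sites
  eta <- cfg$beta0 + cfg$region_effects[cwm$region_id] +
    b_site[cwm$site_id] + cfg$beta_trait * z
  lambda <- exp(eta)
  n <- length(lambda)
  present <- stats::rbinom(n, 1, 1 - cfg$zero_inflation_pi)
  cwm$lambda <- lambda
  cwm$count <- present * stats::rpois(n, lambda)
  cwm
}

# Split per-core totals into family counts (multinomial, Table-2-like shares).
split_families <- function(total, shares) {
  fam <- names(shares)
  counts <- vapply(total, function(k) {
    if (k == 0) return(integer(length(fam)))
    as.integer(stats::rmultinom(1, k, shares))
  }, integer(length(fam)))
  data.frame(
    plot_index = rep(seq_along(total), each = length(fam)),
    family = rep(fam, times = length(total)),
    count = as.integer(counts), stringsAsFactors = FALSE
  )
}

#' Simulate a full multi-site transect study
#'
#' Chains the generator end to end: species pool, per-site patchy vegetation,
#' plot-level CWM of the focal trait, zero-inflated Poisson counts split into
#' herbivore families, per-core soil measurements (fresh/dry weight with ~4%
#' within-site water-content variation, root dry mass), two water-holding
#' capacity cores per site, and per-site management intensities (F, M, G)
#' from which regional means and the LUI index can be computed. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `transect_collection`: list with `pool` (trait
#'   table), `sites` (named list of per-site datasets), `config`.
#' @export
simulate_transects <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pool <- generate_species_pool(cfg)
  covers <- generate_vegetation(cfg, pool)
  layout <- site_layout(cfg)
  x <- (seq_len(cfg$plots_per_site) - 1) * cfg$spacing

  # focal-trait CWM per core, pooled across all sites
  focal <- cfg$focal_trait
  cwm_df <- do.call(rbind, lapply(seq_len(nrow(layout)), function(s) {
    vals <- apply(covers[[s]], 1, function(cv) {
      cwm(cv, pool[, focal, drop = FALSE])$cwm
    })
    data.frame(site_id = layout$site_id[s], region_id = layout$region_id[s],
               plot_index = seq_along(x), cwm = vals,
               stringsAsFactors = FALSE)
  }))
  names(cwm_df)[names(cwm_df) == "cwm"] <- focal
  if (anyNA(cwm_df[[focal]])) {
    # focal trait should be fully attributed; fall back to pool mean
    cwm_df[[focal]][is.na(cwm_df[[focal]])] <-
      mean(pool[[focal]], na.rm = TRUE)
  }
  cwm_df <- generate_counts(cfg, cwm_df, focal)

  set.seed(cfg$seed + 3L)
  n_sites <- nrow(layout)
  mgmt <- data.frame(
    f = stats::runif(n_sites, 0, 94),
    m = sample(0:3, n_sites, replace = TRUE),
    g = pmin(pmax(rlnorm_mean(n_sites, 120, 1.2), 0), 1060)
  )
  wc_site <- rlnorm_mean(n_sites, cfg$wc_mean, cfg$wc_site_cv)
  whc_site <- pmax(stats::rnorm(n_sites, cfg$whc_mean, cfg$whc_sd), 8)

  sites <- vector("list", n_sites)
  names(sites) <- layout$site_id
  for (s in seq_len(n_sites)) {
    npl <- length(x)
    wc_core <- rlnorm_mean(npl, wc_site[s], cfg$wc_within_cv)
    dry <- rlnorm_mean(npl, cfg$core_dry_wt, 0.08)
    rows <- cwm_df$site_id == layout$site_id[s]
    sites[[s]] <- list(
      site_id = layout$site_id[s],
      region_id = layout$region_id[s],
      plot_positions = x,
      cover = covers[[s]],
      bare_soil = round(pmin(stats::rexp(npl, 1 / cfg$bare_soil_mean), 70), 1),
      veg_height = round(rlnorm_mean(npl, 0.25, 0.4), 3),
      counts = split_families(cwm_df$count[rows], cfg$family_shares),
      soil = data.frame(
        plot_index = seq_len(npl),
        fresh_wt_g = dry * (1 + wc_core / 100),
        dry_wt_g = dry,
        root_dry_mass_g = rlnorm_mean(npl, cfg$root_mass_mean,
                                      cfg$root_mass_sd / cfg$root_mass_mean)
      ),
      whc_cores = {
        d105 <- rlnorm_mean(2, cfg$core_dry_wt * 0.92, 0.08)
        whc2 <- whc_site[s] * rlnorm_mean(2, 1, 0.05)
        data.frame(sat_wt_g = d105 * (1 + whc2 / 100), dry_wt_g = d105)
      },
      management = list(f = mgmt$f[s], m = mgmt$m[s], g = mgmt$g[s])
    )
  }
  structure(list(pool = pool, sites = sites, config = cfg),
            class = "transect_collection")
}

#' @export
print.transect_collection <- function(x, ...) {
  cat("Transect collection:", length(x$sites), "sites,",
      nrow(x$pool), "species pool,",
      x$config$plots_per_site, "plots/site\n")
  invisible(x)
}
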