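test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 5)
  tc1 <- simulate_transects(cfg)
  tc2 <- simulate_transects(cfg)
  expect_identical(tc1$pool, tc2$pool)
  expect_identical(tc1$sites, tc2$sites)
  tc3 <- simulate_transects(small_sim_config(seed = 6))
  expect_false(identical(tc1$sites[[1]]$cover, tc3$sites[[1]]$cover))
})

test_that("species pool respects degenerate and missing-value settings", {
  tt <- default_trait_table()
  tt$sd <- 0
  tt$missing_frac <- 0
  cfg <- small_sim_config(seed = 5, traits = tt)
  pool <- generate_species_pool(cfg)
  expect_false(anyNA(pool))
  for (tr in colnames(pool)) expect_equal(length(unique(pool[[tr]])), 1L)
  tt2 <- default_trait_table()
  tt2$missing_frac <- 0.5
  pool2 <- generate_species_pool(small_sim_config(seed = 5, traits = tt2))
  expect_equal(unname(colSums(is.na(pool2))),
               rep(floor(0.5 * nrow(pool2)), ncol(pool2)))
  tt3 <- default_trait_table()
  tt3$sd[1] <- -1
  expect_error(small_sim_config(traits = tt3), "non-negative")
})

test_that("vegetation is patchy: community similarity decays with plot
           separation", {
  cfg <- sim_config(n_regions = 1, sites_per_region = 4, patch_length_scale = 1,
                    region_effects = 0, seed = 8)
  pool <- generate_species_pool(cfg)
  veg <- generate_vegetation(cfg, pool)
  pos <- (0:29) * 0.3
  sep <- as.matrix(dist(pos))
  for (cov in veg) {
    bc <- bray_curtis(cov)
    near <- mean(bc[sep > 0 & sep <= 1])
    far <- mean(bc[sep >= 6])
    expect_lt(near, far)
  }
})

test_that("patch length scale controls the first-class Mantel coefficient", {
  pos <- (0:29) * 0.3
  cls <- sturges_classes(pos)
  first_r <- function(scale, seed) {
    cfg <- sim_config(n_regions = 1, sites_per_region = 2,
                      patch_length_scale = scale, region_effects = 0,
                      seed = seed)
    veg <- generate_vegetation(cfg, generate_species_pool(cfg))
    mean(vapply(veg, function(cov) {
      -mantel_r(bray_curtis(cov), 1 * outer_class(cls, 1),
                mask = cls$included)
    }, numeric(1)))
  }
  outer_class <- function(cls, k) {
    n <- 30
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- cls$membership[, k]
    m + t(m)
  }
  set.seed(31)
  grid <- c(0.1, 0.5, 1, 2)
  r_bar <- vapply(grid, function(sc) {
    mean(vapply(1:6, function(s) first_r(sc, 100 * s + sc * 10), numeric(1)))
  }, numeric(1))
  expect_gt(cor(grid, r_bar, method = "spearman"), 0)
  expect_gt(r_bar[4], r_bar[1])
})

test_that("near-uniform vegetation shows no significant spatial structure
           at the nominal rate", {
  pos <- (0:29) * 0.3
  cls <- sturges_classes(pos)
  cfg <- sim_config(n_regions = 1, sites_per_region = 10,
                    patch_length_scale = 100, region_effects = 0, seed = 9)
  veg <- generate_vegetation(cfg, generate_species_pool(cfg))
  set.seed(32)
  n_sig <- sum(vapply(veg, function(cov) {
    cg <- mantel_correlogram(bray_curtis(cov), cls, n_perm = 99)
    any(cg$classes$significant, na.rm = TRUE)
  }, logical(1)))
  # family-wise error of the progressive correction keeps this near alpha
  expect_lte(n_sig, 3)
})

test_that("counts follow the zero-inflated Poisson marginal", {
  n <- 12000
  cwm_tab <- data.frame(site_id = rep(sprintf("s%02d", 1:40), each = 300),
                        region_id = 1, plot_index = rep(1:300, 40),
                        sla = rnorm(n, 20, 3))
  cfg <- sim_config(n_regions = 1, sites_per_region = 40,
                    plots_per_site = 300, beta_trait = 0,
                    site_intercept_sd = 0, region_effects = 0,
                    beta0 = log(0.9), zero_inflation_pi = 0.25, seed = 10)
  out <- generate_counts(cfg, cwm_tab)
  expect_true(all(out$count >= 0))
  m_expect <- (1 - 0.25) * 0.9
  se <- sqrt(m_expect * (1 + 0.25 * 0.9) / n) # ZIP variance / n
  expect_lt(abs(mean(out$count) - m_expect), 3 * se)
  # structural-zero extremes
  cfg1 <- sim_config(zero_inflation_pi = 1, n_regions = 1,
                     sites_per_region = 2, region_effects = 0, seed = 10)
  out1 <- generate_counts(cfg1, cwm_tab[1:60, ])
  expect_true(all(out1$count == 0))
  expect_error(generate_counts(cfg1, cwm_tab, focal_trait = "nope"),
               "unknown")
})

test_that("fixtures round-trip through the readers", {
  tc <- simulate_transects(small_sim_config(seed = 7))
  dir <- withr::local_tempdir()
  write_fixtures(tc, dir)
  back <- read_transect_data(dir)
  expect_equal(names(back$sites), names(tc$sites))
  for (sid in names(tc$sites)) {
    a <- tc$sites[[sid]]; b <- back$sites[[sid]]
    expect_equal(b$cover, a$cover, tolerance = 1e-9)
    expect_identical(b$counts$count, a$counts$count)
    expect_equal(b$soil, a$soil, tolerance = 1e-9)
    expect_equal(b$whc_cores, a$whc_cores, tolerance = 1e-9)
    expect_equal(b$management, a$management, tolerance = 1e-9)
    expect_equal(b$plot_positions, a$plot_positions)
  }
  expect_equal(rownames(back$pool), rownames(tc$pool))
  expect_equal(back$pool$sla, tc$pool$sla, tolerance = 1e-9)
})

test_that("fixture files are byte-identical across runs; empty input gives
           an empty manifest", {
  tc <- simulate_transects(small_sim_config(seed = 7))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixtures(tc, d1)
  write_fixtures(tc, d2)
  for (f in c("cover.csv", "traits.csv", "cores.csv", "sites.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  d3 <- withr::local_tempdir()
  man <- write_fixtures(list(), d3)
  expect_equal(man$n_sites, 0)
  expect_length(list.files(d3), 1) # manifest only
})
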