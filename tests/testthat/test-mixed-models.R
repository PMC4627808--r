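test_that("block aggregation sums counts, averages predictors, conserves
           totals", {
  metrics <- data.frame(
    site_id = "A", region_id = 1, plot_index = 1:30,
    count = c(1, 0, 2, rep(0, 27)),
    pred = rep(5, 30)
  )
  agg <- aggregate_blocks(metrics)
  expect_equal(nrow(agg), 10)
  expect_equal(agg$count, c(3, rep(0, 9)))
  expect_equal(agg$pred, rep(5, 10))
  expect_equal(sum(agg$count), sum(metrics$count))
})

test_that("incomplete trailing blocks are dropped with a warning and
           NA predictors propagate", {
  metrics <- data.frame(
    site_id = "A", region_id = 1, plot_index = 1:8,
    count = rep(1, 8), pred = c(rep(1, 3), NA, 1, 1, 1, 1)
  )
  expect_warning(agg <- aggregate_blocks(metrics), "incomplete")
  expect_equal(nrow(agg), 2)
  expect_true(is.na(agg$pred[2])) # block 4-6 contains the omitted plot
  expect_false(is.na(agg$pred[1]))
})

test_that("with sigma fixed at zero the mixed model reproduces the IRLS
           Poisson GLM", {
  set.seed(41)
  blocks <- make_glmm_blocks(n_sites = 12, beta1 = 0.25, sigma_site = 0)
  x <- stats::model.matrix(~factor(region_id) + x, blocks)
  fit <- pglmm(blocks$count, x, blocks$site_id, fix_sigma = 0)
  oracle <- irls_poisson(x, blocks$count)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-6)
  expect_equal(fit$sigma, 0)
})

test_that("Laplace and adaptive Gauss-Hermite fits agree closely", {
  set.seed(42)
  blocks <- make_glmm_blocks(n_sites = 15, beta1 = 0.3, sigma_site = 0.4)
  f1 <- fit_poisson_glmm(blocks, "x")
  f2 <- fit_poisson_glmm(blocks, "x", method = "agq")
  expect_equal(f1$slope, f2$slope, tolerance = 0.01)
  expect_equal(f1$sigma2_site, f2$sigma2_site, tolerance = 0.05)
})

test_that("the mixed model matches glmer on the same data", {
  set.seed(43)
  blocks <- make_glmm_blocks(n_sites = 15, beta1 = 0.3, sigma_site = 0.4)
  fit <- fit_poisson_glmm(blocks, "x")
  gm <- lme4::glmer(count ~ factor(region_id) + z + (1 | site_id),
                    data = transform(blocks, z = z_standardize(x)),
                    family = poisson)
  expect_equal(fit$slope, unname(lme4::fixef(gm)[["z"]]), tolerance = 1e-3)
  expect_equal(fit$sigma2_site, unname(lme4::VarCorr(gm)$site_id[1, 1]),
               tolerance = 1e-2)
  expect_equal(fit$model$logLik, as.numeric(logLik(gm)), tolerance = 1e-4)
})

test_that("slope recovery is approximately unbiased", {
  set.seed(44)
  slopes <- replicate(25, {
    blocks <- make_glmm_blocks(beta1 = 0.3, sigma_site = 0.3)
    fit_poisson_glmm(blocks, "x")$slope
  })
  expect_lt(abs(mean(slopes) - 0.3), 0.06)
})

test_that("degenerate inputs are rejected", {
  blocks <- make_glmm_blocks(n_sites = 4)
  blocks$count <- 0
  expect_error(fit_poisson_glmm(blocks, "x"), "degenerate")
  one_site <- make_glmm_blocks(n_sites = 1)
  expect_error(fit_poisson_glmm(one_site, "x"), "2 sites")
})

test_that("conditional R2 follows the variance-partition formula and is
           monotone in the site variance", {
  set.seed(45)
  blocks <- make_glmm_blocks(n_sites = 15, beta1 = 0.3, sigma_site = 0.4)
  fit <- fit_poisson_glmm(blocks, "x")
  s2f <- var(fit$model$eta_fixed)
  s2s <- fit$sigma2_site
  lam <- mean(fit$model$fitted)
  expect_equal(fit$r2_conditional,
               (s2f + s2s) / (s2f + s2s + log(1 + 1 / lam)))
  r2_tri <- conditional_r2(fit, approx = "trigamma")
  expect_equal(r2_tri, (s2f + s2s) / (s2f + s2s + trigamma(lam)))
  expect_true(fit$r2_conditional >= 0 && fit$r2_conditional <= 1)
  # monotone in sigma2 with everything else held fixed
  grid <- seq(0, 2, by = 0.5)
  vals <- (s2f + grid) / (s2f + grid + log(1 + 1 / lam))
  expect_true(all(diff(vals) > 0))
  # no fixed effect, no site variance: R2 near zero
  set.seed(46)
  null_blocks <- make_glmm_blocks(n_sites = 30, n_blocks = 25, beta1 = 0,
                                  sigma_site = 0, n_regions = 1,
                                  region_effects = 0)
  null_fit <- fit_poisson_glmm(null_blocks, "x")
  expect_lt(null_fit$r2_conditional, 0.08)
})

test_that("the parametric bootstrap behaves at its logical extremes", {
  set.seed(47)
  blocks <- make_glmm_blocks(n_sites = 8, beta1 = 0, sigma_site = 0.3)
  fit <- fit_poisson_glmm(blocks, "x")
  same <- parametric_bootstrap_p(fit$model, fit$model, n_boot = 19, seed = 1)
  expect_equal(same$lrt_obs, 0)
  expect_equal(same$p, 1)
  strong <- make_glmm_blocks(n_sites = 10, beta1 = 1, sigma_site = 0.2)
  sfit <- fit_poisson_glmm(strong, "x")
  pb <- parametric_bootstrap_p(sfit, n_boot = 99, seed = 2)
  expect_equal(pb$p, 1 / 100)
})

test_that("predictor ranking orders by |slope| with a stable name
           tie-break", {
  mk <- function(name, slope) {
    structure(list(predictor = name, mean_raw = 1, sd_raw = 1, chisq = 5,
                   p_lrt = 0.01, p_boot = NA_real_, mean_intercept = 0.4,
                   slope = slope, r2_conditional = 0.3),
              class = "glmm_fit")
  }
  tab <- rank_predictors(list(mk("rh", 0.193), mk("sla", 0.283),
                              mk("leaf_cn", -0.260)))
  expect_equal(tab$predictor, c("sla", "leaf_cn", "rh"))
  tie <- rank_predictors(list(mk("b", 0.2), mk("a", -0.2)))
  expect_equal(tie$predictor, c("a", "b"))
})

test_that("Moran screening excludes a gradient site but not iid sites", {
  cfg <- small_sim_config(seed = 15, zero_inflation_pi = 0,
                          site_intercept_sd = 0, beta_trait = 0)
  tc <- simulate_transects(cfg)
  # overwrite counts: iid everywhere except a strong gradient at site 1
  set.seed(48)
  for (s in seq_along(tc$sites)) {
    n <- length(tc$sites[[s]]$plot_positions)
    base <- if (s == 1) round(seq(0, 12, length.out = n)) else rpois(n, 2)
    tc$sites[[s]]$counts <- data.frame(
      plot_index = 1:n, family = "Elateridae", count = base
    )
  }
  res <- exclude_autocorrelated_sites(tc, alpha = 0.01, n_perm = 499)
  expect_true(res$report$excluded[1])
  expect_lte(sum(res$report$excluded), 2)
  expect_equal(length(res$kept$sites),
               length(tc$sites) - sum(res$report$excluded))
})

test_that("backward selection drops inert covariates and keeps a real
           distance effect", {
  set.seed(49)
  n_sites <- 10; n_classes <- 10
  base <- data.frame(
    site_id = rep(sprintf("s%02d", 1:n_sites), each = n_classes),
    lui = rep(runif(n_sites, 0.5, 3.5), each = n_classes),
    whc = rep(runif(n_sites, 30, 90), each = n_classes),
    distance = rep(seq(0.36, 7.86, length.out = n_classes), n_sites)
  )
  null_dat <- transform(base, r = rnorm(nrow(base), 0, 0.1))
  m0 <- fit_mcc_lmm(null_dat, n_boot = 49, seed = 3)
  expect_lte(length(m0$retained), 1)
  eff <- transform(base, r = 0.5 - 0.08 * distance +
                     rnorm(nrow(base), 0, 0.05))
  m1 <- fit_mcc_lmm(eff, n_boot = 49, seed = 4)
  expect_true("distance" %in% m1$retained)
  expect_false(any(c("lui", "whc") %in% m1$retained))
  expect_error(fit_mcc_lmm(null_dat[null_dat$site_id == "s01", ]),
               "fewer than 2")
})

test_that("site-level regressions recover exact and null relationships", {
  sites <- data.frame(lui = seq(0.5, 3.5, length.out = 28))
  sites$resp <- 2 * sites$lui
  exact <- suppressWarnings(fit_site_level_lm(sites, "resp"))
  expect_equal(exact$r2, 1)
  expect_equal(exact$slope, 2)
  # expected R2 under independence is 1/(n-1)
  set.seed(50)
  r2s <- replicate(400, {
    sites$noise <- rnorm(28)
    fit_site_level_lm(sites, "noise")$r2
  })
  expect_lt(abs(mean(r2s) - 1 / 27), 0.012)
  expect_error(fit_site_level_lm(data.frame(lui = rep(1, 5), y = 1:5), "y"),
               "constant")
})
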