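# Independent oracles and small fixture builders used across the suite.

# Poisson GLM by hand-rolled iteratively reweighted least squares; the
# reference for the mixed model at sigma = 0. Deliberately independent of
# both glm() and the package's optimizer.
irls_poisson <- function(x, y, tol = 1e-12, maxit = 100) {
  x <- as.matrix(x)
  beta <- c(log(mean(y) + 0.1), rep(0, ncol(x) - 1))
  for (i in seq_len(maxit)) {
    eta <- as.vector(x %*% beta)
    mu <- exp(eta)
    w <- mu
    z <- eta + (y - mu) / mu
    beta_new <- solve(crossprod(x, w * x), crossprod(x, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- as.vector(beta_new)
      break
    }
    beta <- as.vector(beta_new)
  }
  names(beta) <- colnames(x)
  beta
}

# Pearson correlation from first principles (centred sums, no cor()).
brute_pearson <- function(a, b) {
  da <- a - mean(a)
  db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Small synthetic study: few sites, short transects, quick to simulate.
small_sim_config <- function(seed = 42, ...) {
  sim_config(
    n_regions = 2, sites_per_region = c(3, 3), plots_per_site = 15,
    n_species = 40, n_species_site = 18, region_effects = c(0.1, -0.1),
    seed = seed, ...
  )
}

# Block-level data straight from the mixed model's own assumptions
# (no vegetation layer): the parameter-recovery harness.
make_glmm_blocks <- function(n_sites = 28, n_blocks = 10, beta0 = log(2),
                             beta1 = 0.3, sigma_site = 0.3, n_regions = 3,
                             region_effects = c(0, 0.2, -0.2)) {
  site <- rep(seq_len(n_sites), each = n_blocks)
  region <- ((site - 1) %% n_regions) + 1
  z <- rnorm(n_sites * n_blocks)
  z <- (z - mean(z)) / sd(z)
  b <- rnorm(n_sites, 0, sigma_site)
  lambda <- exp(beta0 + region_effects[region] + b[site] + beta1 * z)
  data.frame(
    site_id = sprintf("S%02d", site), region_id = region,
    block = rep(seq_len(n_blocks), n_sites),
    count = rpois(n_sites * n_blocks, lambda), x = z
  )
}
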