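#' Aggregate a transect into blocks of adjacent cores
#'
#' Zero inflation of the per-core counts is reduced by summing herbivore
#' counts and averaging predictor variables over `block_size` consecutive
#' cores in transect order (non-overlapping), so a 30-core transect yields
#' 10 blocks. Predictor means propagate `NA`: a block containing a plot that
#' is omitted for a community-weighted mean trait is dropped for that trait
#' when the model is fitted. A trailing incomplete block is dropped with a
#' warning. Total counts are conserved across complete blocks.
#'
#' @param metrics Plot-level table ([plot_metrics()] layout): `site_id`,
#'   `region_id`, `plot_index`, `count`, plus numeric predictor columns.
#' @param block_size Cores per block (default 3).
#' @return Data frame, one row per block: `site_id`, `region_id`, `block`,
#'   `count` (sum) and block means of every other numeric column.
#' @export
aggregate_blocks <- function(metrics, block_size = 3) {
  stopifnot(block_size >= 1)
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  count_cols <- grep("^count", num_cols, value = TRUE)
  keep <- setdiff(num_cols, c("plot_index", "region_id", count_cols))
  keep <- grep("^omitted_", keep, value = TRUE, invert = TRUE)
  out <- lapply(split(metrics, metrics$site_id), function(df) {
    df <- df[order(df$plot_index), ]
    n <- nrow(df)
    n_blocks <- n %/% block_size
    if (n %% block_size != 0) {
      warning("site ", df$site_id[1], ": dropping trailing incomplete block ",
              "(", n %% block_size, " cores)")
    }
    idx <- rep(seq_len(n_blocks), each = block_size)
    df <- df[seq_along(idx), ]
    agg <- data.frame(
      site_id = df$site_id[1], region_id = df$region_id[1],
      block = seq_len(n_blocks),
      stringsAsFactors = FALSE
    )
    for (v in count_cols) agg[[v]] <- as.vector(tapply(df[[v]], idx, sum))
    for (v in keep) agg[[v]] <- as.vector(tapply(df[[v]], idx, mean))
    agg
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclude sites whose herbivore counts are spatially autocorrelated
#'
#' Computes global Moran's I (inverse-distance weights, permutation test) on
#' the per-core total counts of each site and removes sites with p below
#' `alpha` from the model input, since spatial structure in the response
#' would bias the mixed models. Sites with constant counts cannot be tested
#' and are retained.
#'
#' @param collection A `transect_collection`.
#' @param alpha Exclusion level (default 0.05).
#' @param n_perm Permutations for the Moran test.
#' @return List with `kept` (filtered collection) and `report` (one row per
#'   site: `site_id`, `i`, `p`, `excluded`).
#' @export
exclude_autocorrelated_sites <- function(collection, alpha = 0.05,
                                         n_perm = 999) {
  sites <- collection$sites
  report <- do.call(rbind, lapply(sites, function(s) {
    counts <- total_counts(s)
    if (stats::sd(counts) == 0) {
      return(data.frame(site_id = s$site_id, i = NA_real_, p = NA_real_,
                        excluded = FALSE, stringsAsFactors = FALSE))
    }
    m <- global_morans_i(counts, s$plot_positions, n_perm = n_perm)
    data.frame(site_id = s$site_id, i = m$i, p = m$p,
               excluded = !is.na(m$p) && m$p < alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  kept <- collection
  kept$sites <- sites[!report$excluded]
  list(kept = kept, report = report)
}

#' Poisson mixed model for one predictor of herbivore counts
#'
#' Fits, via the in-package Laplace engine [pglmm()], a Poisson log-link
#' model of block counts on the z-standardized predictor with region as fixed
#' factor and a site random intercept:
#' `count ~ region + z(predictor) + (1 | site)`. The predictor is
#' z-standardized over the pooled blocks (all sites) so that slopes are
#' comparable across predictors; blocks with a missing predictor value (e.g.
#' coverage-rule omissions) are dropped. The likelihood-ratio chi-square
#' compares against the same model without the predictor; `mean_intercept` is
#' the arithmetic mean of the per-region intercepts on the link scale.
#'
#' @param blocks Aggregated table from [aggregate_blocks()].
#' @param predictor Name of the predictor column.
#' @param log_transform Log-transform (log(x + 1)) before standardizing, used
#'   for bare-soil cover.
#' @param response Count column name (default `"count"`).
#' @param method Integration method passed to [pglmm()].
#' @return Object of class `glmm_fit`.
#' @export
fit_poisson_glmm <- function(blocks, predictor, log_transform = FALSE,
                             response = "count", method = "laplace") {
  if (!predictor %in% names(blocks)) stop("unknown predictor: ", predictor)
  df <- data.frame(
    count = blocks[[response]],
    site = factor(blocks$site_id),
    region = factor(blocks$region_id),
    x = blocks[[predictor]]
  )
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) == 0 || sum(df$count) == 0) {
    stop("degenerate input: no non-missing blocks with positive counts")
  }
  df$site <- droplevels(df$site)
  df$region <- droplevels(df$region)
  if (nlevels(df$site) < 2) stop("need at least 2 sites")
  mean_raw <- mean(df$x)
  sd_raw <- stats::sd(df$x)
  if (log_transform) df$x <- log(df$x + 1)
  df$z <- z_standardize(df$x)
  has_region <- nlevels(df$region) > 1
  x_red <- if (has_region) stats::model.matrix(~region, df)
           else stats::model.matrix(~1, df)
  x_full <- cbind(x_red, z = df$z)
  full <- pglmm(df$count, x_full, df$site, method = method)
  reduced <- pglmm(df$count, x_red, df$site, method = method)
  fe <- full$coefficients
  reg_lev <- levels(df$region)
  region_int <- if (has_region) {
    fe[["(Intercept)"]] + c(0, fe[paste0("region", reg_lev[-1])])
  } else {
    fe[["(Intercept)"]]
  }
  names(region_int) <- reg_lev
  chisq <- max(0, 2 * (full$logLik - reduced$logLik))
  se_z <- sqrt(full$vcov_beta[ncol(x_full), ncol(x_full)])
  fit <- structure(list(
    predictor = predictor, response = response,
    model = full, reduced = reduced, data = df,
    slope = unname(fe[["z"]]),
    slope_se = unname(se_z),
    region_intercepts = region_int,
    mean_intercept = mean(region_int),
    sigma2_site = full$sigma2,
    chisq = chisq, df = 1L,
    p_lrt = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
    p_boot = NA_real_,
    mean_raw = mean_raw, sd_raw = sd_raw,
    n_obs = nrow(df), converged = full$converged && reduced$converged
  ), class = "glmm_fit")
  fit$r2_conditional <- conditional_r2(fit)
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Poisson GLMM: count ~ region + z(", x$predictor, ") + (1 | site)\n",
      sep = "")
  cat(sprintf("  slope %.3f (se %.3f), mean intercept %.3f, sigma2_site %.3f\n",
              x$slope, x$slope_se, x$mean_intercept, x$sigma2_site))
  cat(sprintf("  LRT chisq %.2f, p %.4g%s, conditional R2 %.2f, n = %d\n",
              x$chisq, if (is.na(x$p_boot)) x$p_lrt else x$p_boot,
              if (is.na(x$p_boot)) " (asymptotic)" else " (bootstrap)",
              x$r2_conditional, x$n_obs))
  if (!x$converged) cat("  WARNING: convergence not clean\n")
  invisible(x)
}

#' Conditional R-squared of a Poisson mixed model
#'
#' Variance explained by fixed plus random effects on the latent log scale:
#' (s2_fixed + s2_site) / (s2_fixed + s2_site + s2_resid), where s2_fixed is
#' the variance of the fixed-effect linear predictor, s2_site the
#' random-intercept variance, and s2_resid the observation-level variance of
#' a Poisson response approximated on the log scale — by default the
#' lognormal form ln(1 + 1/lambda_bar) with lambda_bar the mean fitted count;
#' `approx = "trigamma"` uses trigamma(lambda_bar) instead.
#'
#' @param fit A `glmm_fit`, a [pglmm()] fit, or a Poisson `merMod`.
#' @param approx `"lognormal"` (default) or `"trigamma"`.
#' @return Conditional R-squared in \[0, 1\].
#' @export
conditional_r2 <- function(fit, approx = c("lognormal", "trigamma")) {
  approx <- match.arg(approx)
  model <- if (inherits(fit, "glmm_fit")) fit$model else fit
  if (inherits(model, "pglmm")) {
    eta_fix <- model$eta_fixed
    s2s <- model$sigma2
    lambda_bar <- mean(model$fitted)
  } else {
    eta_fix <- as.vector(lme4::getME(model, "X") %*% lme4::fixef(model))
    vc <- lme4::VarCorr(model)
    s2s <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
    lambda_bar <- mean(stats::fitted(model))
  }
  s2f <- stats::var(eta_fix)
  s2e <- if (approx == "lognormal") log(1 + 1 / lambda_bar)
         else trigamma(lambda_bar)
  tot <- s2f + s2s + s2e
  if (tot <= 0) stop("zero total variance: R2 undefined")
  (s2f + s2s) / tot
}

#' Parametric-bootstrap likelihood-ratio test of nested mixed models
#'
#' Simulates `n_boot` response vectors from the reduced model's fitted
#' parameters, refits both models to each, and compares the observed
#' likelihood-ratio statistic with the bootstrap distribution:
#' p = (1 + #\{LRT* >= LRT_obs\}) / (n_ok + 1). Bootstrap samples on which a
#' refit fails are dropped and counted. Gaussian models must be fitted with
#' ML (`REML = FALSE`) for the likelihood ratio to be meaningful.
#'
#' @param full,reduced Nested `merMod` fits (or `glmm_fit`s, whose full and
#'   reduced components are used when `reduced` is missing).
#' @param n_boot Number of bootstrap samples (default 500).
#' @param seed Optional integer seed.
#' @return List with `p`, `lrt_obs`, `n_ok`, `n_failed`.
#' @export
parametric_bootstrap_p <- function(full, reduced = NULL, n_boot = 500,
                                   seed = NULL) {
  if (inherits(full, "glmm_fit")) {
    if (is.null(reduced)) reduced <- full$reduced
    full <- full$model
  }
  if (inherits(reduced, "glmm_fit")) reduced <- reduced$model
  if (!is.null(seed)) set.seed(seed)
  lrt_obs <- max(0, 2 * as.numeric(stats::logLik(full) -
                                     stats::logLik(reduced)))
  own <- inherits(reduced, "pglmm")
  sims <- if (own) simulate.pglmm(reduced, nsim = n_boot)
          else stats::simulate(reduced, nsim = n_boot)
  lrt_star <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    lrt_star[b] <- tryCatch(
      suppressMessages(suppressWarnings({
        if (own) {
          f_b <- refit_pglmm(full, sims[[b]])
          r_b <- refit_pglmm(reduced, sims[[b]])
        } else {
          f_b <- lme4::refit(full, newresp = sims[[b]])
          r_b <- lme4::refit(reduced, newresp = sims[[b]])
        }
        max(0, 2 * as.numeric(stats::logLik(f_b) - stats::logLik(r_b)))
      })),
      error = function(e) NA_real_
    )
  }
  ok <- !is.na(lrt_star)
  p <- (1 + sum(lrt_star[ok] >= lrt_obs - 1e-8)) / (sum(ok) + 1)
  list(p = p, lrt_obs = lrt_obs, n_ok = sum(ok), n_failed = sum(!ok))
}

#' Rank predictors by standardized effect strength
#'
#' Orders a list of single-predictor mixed-model fits by absolute slope
#' (descending; ties broken by predictor name) and assembles the reporting
#' table: raw-scale mean (sd), likelihood-ratio chi-square, p (bootstrap if
#' available, else asymptotic), mean intercept, slope and conditional
#' R-squared.
#'
#' @param fits List of `glmm_fit` objects.
#' @param alpha Significance flag level (default 0.05).
#' @return Data frame, one row per predictor, sorted by |slope|.
#' @export
rank_predictors <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) > 0)
  tab <- do.call(rbind, lapply(fits, function(f) {
    p <- if (!is.na(f$p_boot)) f$p_boot else f$p_lrt
    data.frame(
      predictor = f$predictor,
      mean = f$mean_raw, sd = f$sd_raw,
      chisq = f$chisq, p = p,
      p_source = if (!is.na(f$p_boot)) "bootstrap" else "asymptotic",
      mean_intercept = f$mean_intercept,
      slope = f$slope, r2 = f$r2_conditional,
      significant = p <= alpha,
      stringsAsFactors = FALSE
    )
  }))
  tab <- tab[order(-abs(tab$slope), tab$predictor), ]
  rownames(tab) <- NULL
  tab
}

#' Mixed model of Mantel coefficients on land use and soil
#'
#' Tests whether within-transect spatial pattern depends on land-use
#' intensity and soil water-holding capacity: Gaussian LMM (ML) of per-class
#' Mantel correlation coefficients on LUI, WHC and distance-class midpoint
#' with all pairwise interactions and a site random intercept, simplified
#' backward stepwise. At each step the candidate terms (interactions first; a
#' main effect is only droppable once no retained interaction contains it)
#' are tested by parametric bootstrap against the current model, and the term
#' with the largest p > `alpha` is removed; simplification stops when every
#' remaining term has p <= `alpha`.
#'
#' @param mcc Data frame with columns `site_id`, `r` (Mantel coefficient),
#'   `lui`, `whc`, `distance` (class midpoint, m). Rows with `NA` are
#'   dropped.
#' @param n_boot Bootstrap samples per candidate test (default 200).
#' @param alpha Retention threshold (default 0.05).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `mcc_lmm`: final `model`, `retained` terms,
#'   `history` of tested terms and p-values.
#' @export
fit_mcc_lmm <- function(mcc, n_boot = 200, alpha = 0.05, seed = NULL) {
  mcc <- mcc[stats::complete.cases(mcc[, c("site_id", "r", "lui", "whc",
                                           "distance")]), ]
  if (length(unique(mcc$site_id)) < 2) {
    stop("random site intercept inestimable with fewer than 2 sites")
  }
  if (!is.null(seed)) set.seed(seed)
  terms_now <- c("lui", "whc", "distance",
                 "lui:whc", "lui:distance", "whc:distance")
  fit_with <- function(terms) {
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    f <- stats::as.formula(paste("r ~", rhs, "+ (1 | site_id)"))
    suppressMessages(
      lme4::lmer(f, data = mcc, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )
  }
  current <- fit_with(terms_now)
  history <- data.frame(step = integer(0), term = character(0), p = numeric(0),
                        dropped = logical(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    inter <- grep(":", terms_now, value = TRUE)
    mains <- setdiff(terms_now, inter)
    droppable <- c(inter,
                   mains[!vapply(mains, function(m) {
                     any(vapply(strsplit(inter, ":"), function(p) m %in% p,
                                logical(1)))
                   }, logical(1))])
    if (length(droppable) == 0) break
    ps <- vapply(droppable, function(tm) {
      reduced <- fit_with(setdiff(terms_now, tm))
      parametric_bootstrap_p(current, reduced, n_boot = n_boot)$p
    }, numeric(1))
    worst <- which.max(ps)
    history <- rbind(history, data.frame(
      step = step, term = droppable[worst], p = ps[worst],
      dropped = ps[worst] > alpha, stringsAsFactors = FALSE
    ))
    if (ps[worst] <= alpha) break
    terms_now <- setdiff(terms_now, droppable[worst])
    current <- fit_with(terms_now)
    if (length(terms_now) == 0) break
  }
  structure(list(model = current, retained = terms_now, history = history,
                 n_boot = n_boot, alpha = alpha), class = "mcc_lmm")
}

#' @export
print.mcc_lmm <- function(x, ...) {
  cat("Mantel-coefficient LMM (parametric-bootstrap backward selection)\n")
  cat("  retained fixed terms:",
      if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  if (nrow(x$history)) {
    cat("  drop history:\n")
    print(x$history, row.names = FALSE)
  }
  invisible(x)
}

#' Site-level linear model against land-use intensity
#'
#' Ordinary least-squares regression of a site summary (total herbivore
#' abundance, per-core count variance, or species richness) on the LUI index.
#'
#' @param site_summary Data frame with a `lui` column and the response.
#' @param response Response column name.
#' @return List with `r2`, `p` (F test), `slope`, `model`.
#' @export
fit_site_level_lm <- function(site_summary, response) {
  if (!response %in% names(site_summary)) stop("unknown response: ", response)
  if (nrow(site_summary) < 3) stop("need at least 3 sites")
  if (stats::sd(site_summary$lui) == 0) stop("constant LUI")
  f <- stats::as.formula(paste(response, "~ lui"))
  m <- stats::lm(f, data = site_summary)
  sm <- summary(m)
  fstat <- sm$fstatistic
  list(
    r2 = unname(sm$r.squared),
    p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    slope = unname(stats::coef(m)[["lui"]]),
    model = m
  )
}
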