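#' Configuration for a full pipeline run
#'
#' Bundles every knob of the analysis chain. Input is either a
#' [sim_config()] (synthetic study) or a directory of the four delimited
#' input tables; flags mirror the stage functions' defaults.
#'
#' @param sim A [sim_config()]; ignored when `input_dir` is given.
#' @param input_dir Directory readable by [read_transect_data()], or NULL.
#' @param coverage_threshold CWM coverage rule threshold, in (0, 1).
#' @param alpha Significance level used throughout.
#' @param n_perm Permutations for Mantel correlograms and Moran's I.
#' @param n_boot Parametric-bootstrap samples for model term tests; `0`
#'   reports asymptotic likelihood-ratio p-values instead.
#' @param block_size Cores per aggregation block.
#' @param seed Integer seed covering every stochastic stage.
#' @param out_dir Output directory for result tables, or NULL to skip
#'   writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       coverage_threshold = 0.8, alpha = 0.05,
                       n_perm = 999, n_boot = 500, block_size = 3,
                       seed = 1L, out_dir = NULL) {
  stopifnot(coverage_threshold > 0, coverage_threshold < 1,
            alpha > 0, alpha < 1, n_perm >= 99, n_boot >= 0,
            block_size >= 1)
  structure(as.list(environment()), class = "run_config")
}

# Schema validation with itemized messages, run before any computation.
validate_collection <- function(collection) {
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)
  for (s in collection$sites) {
    id <- s$site_id
    if (any(s$cover < 0)) note(paste(id, "cover matrix has negative entries"))
    if (any(s$counts$count < 0) ||
        any(s$counts$count != round(s$counts$count))) {
      note(paste(id, "counts must be non-negative integers"))
    }
    dp <- diff(s$plot_positions)
    if (any(dp <= 0)) note(paste(id, "plot positions not strictly increasing"))
    if (length(dp) > 1 && max(abs(dp - dp[1])) > 1e-6) {
      note(paste(id, "plot spacing not constant"))
    }
    npl <- length(s$plot_positions)
    if (!setequal(unique(s$counts$plot_index), seq_len(npl))) {
      note(paste(id, "count records do not cover every plot"))
    }
    if (nrow(s$cover) != npl || nrow(s$soil) != npl) {
      note(paste(id, "cover/soil tables not aligned to plots"))
    }
  }
  if (length(errs) > 0) {
    stop("input validation failed:\n  ", paste(errs, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Most abundant herbivore family
#'
#' Totals counts by family and returns the family with the maximum and its
#' percentage share of all individuals. Ties are broken by the
#' lexicographically first family name and flagged.
#'
#' @param core_table Data frame with `family` and `count` columns.
#' @return List with `family`, `share` (percent), `total_individuals`, `tie`.
#' @export
most_abundant_family <- function(core_table) {
  tot <- tapply(core_table$count, core_table$family, sum)
  grand <- sum(tot)
  if (length(tot) == 0 || grand == 0) stop("no herbivores recorded")
  best <- max(tot)
  winners <- sort(names(tot)[tot == best])
  list(family = winners[1], share = unname(best / grand * 100),
       total_individuals = unname(grand), tie = length(winners) > 1)
}

# Per-site summary covariates: LUI (regional-mean standardized), WHC, and
# the site-level responses of the land-use linear models.
site_summary_table <- function(collection) {
  sites <- collection$sites
  meta <- do.call(rbind, lapply(sites, function(s) data.frame(
    site_id = s$site_id, region_id = s$region_id,
    f = s$management$f, m = s$management$m, g = s$management$g,
    whc = water_holding_capacity(s$whc_cores$sat_wt_g, s$whc_cores$dry_wt_g),
    stringsAsFactors = FALSE
  )))
  reg_means <- do.call(rbind, lapply(split(meta, meta$region_id), function(d) {
    data.frame(region_id = d$region_id[1], f_r = mean(d$f), m_r = mean(d$m),
               g_r = mean(d$g))
  }))
  meta <- merge(meta, reg_means, by = "region_id", sort = FALSE)
  meta$lui <- mapply(lui_index, meta$f, meta$m, meta$g,
                     meta$f_r, meta$m_r, meta$g_r)
  extra <- do.call(rbind, lapply(sites, function(s) {
    counts <- total_counts(s)
    data.frame(
      site_id = s$site_id,
      total_abundance = sum(counts),
      count_variance = stats::var(counts),
      species_richness = sum(colSums(s$cover) > 0),
      stringsAsFactors = FALSE
    )
  }))
  out <- merge(meta, extra, by = "site_id", sort = FALSE)
  out[order(out$site_id), ]
}

# Per-site correlograms for one parameter; returns the per-class table rows.
site_correlogram_rows <- function(site, d, n_perm, alpha, parameter) {
  cls <- sturges_classes(site$plot_positions)
  cg <- mantel_correlogram(d, cls, n_perm = n_perm, alpha = alpha)
  cbind(data.frame(site_id = site$site_id, parameter = parameter,
                   stringsAsFactors = FALSE),
        cg$classes, pattern = cg$pattern)
}

#' Run the full analysis chain
#'
#' Sequences every stage: simulate (or read) the transect datasets, validate
#' schemas, compute plot-level metrics, per-site Mantel correlograms (Bray-
#' Curtis on species composition, Euclidean on the scaled community-weighted
#' trait matrix, absolute count differences for total herbivores and the most
#' abundant family) with pattern classification, the Moran's-I site
#' exclusion, block aggregation, per-predictor Poisson mixed-model rankings
#' for total herbivores and the most abundant family, the Mantel-coefficient
#' LMM against LUI and WHC for spatially structured parameters, and
#' site-level linear models against LUI. Deterministic given `config$seed`;
#' when `config$out_dir` is set all result tables are written as CSV with a
#' JSON run manifest.
#'
#' @param config A [run_config()].
#' @return Invisible list bundle: `collection`, `metrics`, `correlograms`,
#'   `patterns`, `moran_report`, `blocks`, `rankings` (per response),
#'   `mcc_lmm`, `site_lms`, `site_summary`, `focal_family`, `manifest`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  warnings_log <- character(0)
  logw <- function(msg) warnings_log <<- c(warnings_log, msg)

  collection <- if (!is.null(config$input_dir)) {
    read_transect_data(config$input_dir)
  } else {
    simulate_transects(config$sim)
  }
  validate_collection(collection)
  sites <- collection$sites
  pool <- collection$pool

  message("stage 1/6: plot-level metrics (", length(sites), " sites)")
  metrics <- do.call(rbind, lapply(sites, plot_metrics, traits = pool,
                                   coverage_threshold = config$coverage_threshold))
  rownames(metrics) <- NULL

  all_cores <- do.call(rbind, lapply(sites, function(s) s$counts))
  focal_family <- most_abundant_family(all_cores)
  if (focal_family$tie) logw("most-abundant-family tie; lexicographic winner")
  metrics$count_focal <- unlist(lapply(sites, function(s) {
    co <- s$counts[s$counts$family == focal_family$family, ]
    as.vector(tapply(co$count, co$plot_index, sum)[
      as.character(seq_along(s$plot_positions))])
  }), use.names = FALSE)

  message("stage 2/6: Mantel correlograms")
  cwm_cols <- grep("^cwm_", names(metrics), value = TRUE)
  correlograms <- do.call(rbind, lapply(sites, function(s) {
    mt <- metrics[metrics$site_id == s$site_id, ]
    rows <- list()
    rows$species <- site_correlogram_rows(
      s, bray_curtis(s$cover), config$n_perm, config$alpha, "species")
    cw <- as.matrix(mt[, cwm_cols, drop = FALSE])
    complete <- stats::complete.cases(cw)
    if (sum(complete) >= 5) {
      cw_s <- scale(cw[complete, , drop = FALSE])
      cw_s <- cw_s[, !apply(cw_s, 2, anyNA), drop = FALSE]
      sub <- s
      sub$plot_positions <- s$plot_positions[complete]
      rows$traits <- site_correlogram_rows(
        sub, euclidean_dist(cw_s), config$n_perm, config$alpha, "traits")
    } else {
      logw(paste(s$site_id, "traits correlogram skipped:",
                 "too many coverage-rule omissions"))
    }
    for (p in c("counts_total", "counts_focal")) {
      v <- if (p == "counts_total") mt$count else mt$count_focal
      if (stats::sd(v) > 0) {
        rows[[p]] <- site_correlogram_rows(
          s, euclidean_dist(v), config$n_perm, config$alpha, p)
      } else {
        logw(paste(s$site_id, p, "correlogram skipped: constant counts"))
      }
    }
    do.call(rbind, rows)
  }))
  rownames(correlograms) <- NULL
  patterns <- unique(correlograms[, c("site_id", "parameter", "pattern")])
  rownames(patterns) <- NULL

  message("stage 3/6: Moran's I site exclusion")
  excl <- exclude_autocorrelated_sites(collection, alpha = config$alpha,
                                       n_perm = config$n_perm)
  if (length(excl$kept$sites) == 0) {
    stop("all sites excluded by the Moran's I screen")
  }
  kept_ids <- names(excl$kept$sites)

  message("stage 4/6: block aggregation + Poisson mixed models")
  blocks <- withCallingHandlers(
    aggregate_blocks(metrics[metrics$site_id %in% kept_ids, ],
                     block_size = config$block_size),
    warning = function(w) {
      logw(conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  predictors <- c(cwm_cols, "water_content", "root_dry_mass", "plant_cover",
                  "bare_soil", "richness", "shannon", "evenness")
  rankings <- list()
  for (resp in c("count", "count_focal")) {
    fits <- lapply(predictors, function(pr) {
      fit <- tryCatch(
        fit_poisson_glmm(blocks, pr, log_transform = (pr == "bare_soil"),
                         response = resp),
        error = function(e) {
          logw(paste("GLMM", resp, pr, "failed:", conditionMessage(e)))
          NULL
        })
      if (!is.null(fit) && config$n_boot > 0) {
        pb <- parametric_bootstrap_p(fit, n_boot = config$n_boot)
        fit$p_boot <- pb$p
        if (pb$n_failed > 0) {
          logw(paste("bootstrap", resp, pr, ":", pb$n_failed,
                     "refits dropped"))
        }
      }
      fit
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0) {
      stop("every mixed-model fit failed for response '", resp, "':\n  ",
           paste(warnings_log, collapse = "\n  "))
    }
    nm <- if (resp == "count") "total" else focal_family$family
    rankings[[nm]] <- rank_predictors(fits, alpha = config$alpha)
  }

  message("stage 5/6: spatial-pattern and site-level land-use models")
  site_sum <- site_summary_table(collection)
  structured <- vapply(split(patterns, patterns$parameter), function(d) {
    mean(d$pattern != "none") >= 0.5
  }, logical(1))
  mcc_fit <- NULL
  mcc_params <- names(structured)[structured &
                                    names(structured) %in% c("species", "traits")]
  if (length(mcc_params) > 0) {
    mcc <- correlograms[correlograms$parameter %in% mcc_params, ]
    mcc <- merge(mcc, site_sum[, c("site_id", "lui", "whc")], by = "site_id")
    mcc$distance <- (mcc$lower + mcc$upper) / 2
    mcc_fit <- fit_mcc_lmm(mcc, n_boot = max(config$n_boot, 99),
                           alpha = config$alpha)
  } else {
    logw("no parameter displayed spatial structure at most sites; MCC-LMM skipped")
  }
  site_lms <- lapply(c(total_abundance = "total_abundance",
                       count_variance = "count_variance",
                       species_richness = "species_richness"),
                     function(v) fit_site_level_lm(site_sum, v))

  message("stage 6/6: reporting")
  manifest <- list(
    package_version = as.character(utils::packageVersion("rootpatch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_sites = length(sites),
    excluded_sites = excl$report$site_id[excl$report$excluded],
    focal_family = focal_family$family,
    focal_family_share = focal_family$share,
    config = list(coverage_threshold = config$coverage_threshold,
                  alpha = config$alpha, n_perm = config$n_perm,
                  n_boot = config$n_boot, block_size = config$block_size,
                  simulated = is.null(config$input_dir)),
    warnings = warnings_log
  )
  bundle <- list(
    collection = collection, metrics = metrics, correlograms = correlograms,
    patterns = patterns, moran_report = excl$report, blocks = blocks,
    rankings = rankings, mcc_lmm = mcc_fit, site_lms = site_lms,
    site_summary = site_sum, focal_family = focal_family, manifest = manifest
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

# Write all result tables of a run bundle as CSV plus the JSON manifest.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE, na = "")
  w(bundle$metrics, "metrics.csv")
  w(bundle$correlograms, "correlograms.csv")
  w(bundle$patterns, "pattern_summary.csv")
  w(bundle$moran_report, "moran_exclusions.csv")
  w(bundle$blocks, "blocks.csv")
  for (nm in names(bundle$rankings)) {
    w(bundle$rankings[[nm]], paste0("ranking_", nm, ".csv"))
  }
  if (!is.null(bundle$mcc_lmm)) {
    w(bundle$mcc_lmm$history, "mcc_lmm_history.csv")
  }
  lm_tab <- do.call(rbind, lapply(names(bundle$site_lms), function(v) {
    f <- bundle$site_lms[[v]]
    data.frame(response = v, r2 = f$r2, p = f$p, slope = f$slope)
  }))
  w(lm_tab, "site_level_lms.csv")
  w(bundle$site_summary, "site_summary.csv")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
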