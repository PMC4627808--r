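#' Write a transect collection to the four delimited input tables
#'
#' Emits, as UTF-8 comma-separated files with header rows:
#' `cover.csv` (one row per plot: `site_id`, `plot_index`, `position_m`,
#' `bare_soil`, `veg_height_m`, then one percent-cover column per species in
#' the union over sites), `traits.csv` (species x traits, empty cell =
#' missing), `cores.csv` (`site_id`, `plot_index`, `family`, `count`,
#' `fresh_wt_g`, `dry_wt_g`, `root_dry_mass_g`), `sites.csv` (`site_id`,
#' `region_id`, `f`, `m`, `g`, spacing and the two water-holding-capacity
#' core weight pairs), plus a `manifest.json` naming the files. Output is
#' byte-identical across runs for the same collection.
#'
#' @param datasets A `transect_collection` (or its `sites` list).
#' @param directory Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
write_fixtures <- function(datasets, directory) {
  if (inherits(datasets, "transect_collection")) {
    sites <- datasets$sites
    pool <- datasets$pool
  } else {
    sites <- datasets
    pool <- attr(datasets, "pool")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_sites = length(sites), files = character(0))
  if (length(sites) == 0) {
    jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  species <- sort(unique(unlist(lapply(sites, function(s) colnames(s$cover)))))
  cover <- do.call(rbind, lapply(sites, function(s) {
    m <- matrix(0, nrow(s$cover), length(species),
                dimnames = list(NULL, species))
    m[, colnames(s$cover)] <- s$cover
    data.frame(site_id = s$site_id, plot_index = seq_len(nrow(s$cover)),
               position_m = s$plot_positions, bare_soil = s$bare_soil,
               veg_height_m = s$veg_height, m, check.names = FALSE,
               stringsAsFactors = FALSE)
  }))
  cores <- do.call(rbind, lapply(sites, function(s) {
    df <- s$counts
    df$site_id <- s$site_id
    df$fresh_wt_g <- s$soil$fresh_wt_g[df$plot_index]
    df$dry_wt_g <- s$soil$dry_wt_g[df$plot_index]
    df$root_dry_mass_g <- s$soil$root_dry_mass_g[df$plot_index]
    df[, c("site_id", "plot_index", "family", "count",
           "fresh_wt_g", "dry_wt_g", "root_dry_mass_g")]
  }))
  site_tab <- do.call(rbind, lapply(sites, function(s) {
    data.frame(
      site_id = s$site_id, region_id = s$region_id,
      spacing_m = diff(s$plot_positions)[1],
      f = s$management$f, m = s$management$m, g = s$management$g,
      whc_sat_wt_g_1 = s$whc_cores$sat_wt_g[1],
      whc_sat_wt_g_2 = s$whc_cores$sat_wt_g[2],
      whc_dry_wt_g_1 = s$whc_cores$dry_wt_g[1],
      whc_dry_wt_g_2 = s$whc_cores$dry_wt_g[2],
      stringsAsFactors = FALSE
    )
  }))
  traits <- if (!is.null(pool)) {
    data.frame(species = rownames(pool), pool, stringsAsFactors = FALSE)
  } else {
    data.frame(species = character(0))
  }
  files <- c(cover = "cover.csv", traits = "traits.csv",
             cores = "cores.csv", sites = "sites.csv")
  utils::write.csv(cover, file.path(directory, files["cover"]),
                   row.names = FALSE, na = "")
  utils::write.csv(traits, file.path(directory, files["traits"]),
                   row.names = FALSE, na = "")
  utils::write.csv(cores, file.path(directory, files["cores"]),
                   row.names = FALSE, na = "")
  utils::write.csv(site_tab, file.path(directory, files["sites"]),
                   row.names = FALSE, na = "")
  manifest$files <- as.list(files)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read the four delimited input tables back into a transect collection
#'
#' Inverse of [write_fixtures()]: reconstructs per-site datasets (cover
#' matrices restricted to species observed at the site, counts by family,
#' soil cores, water-holding-capacity cores, management) and the species
#' trait pool.
#'
#' @param directory Directory holding `cover.csv`, `traits.csv`, `cores.csv`,
#'   `sites.csv`.
#' @return A `transect_collection` (with `config = NULL`).
#' @export
read_transect_data <- function(directory) {
  rd <- function(f) utils::read.csv(file.path(directory, f),
                                    check.names = FALSE,
                                    stringsAsFactors = FALSE)
  cover <- rd("cover.csv")
  traits <- rd("traits.csv")
  cores <- rd("cores.csv")
  site_tab <- rd("sites.csv")
  pool <- traits[, setdiff(names(traits), "species"), drop = FALSE]
  rownames(pool) <- traits$species
  meta_cols <- c("site_id", "plot_index", "position_m", "bare_soil",
                 "veg_height_m")
  spp <- setdiff(names(cover), meta_cols)
  sites <- lapply(seq_len(nrow(site_tab)), function(s) {
    sid <- site_tab$site_id[s]
    cv <- cover[cover$site_id == sid, , drop = FALSE]
    cv <- cv[order(cv$plot_index), , drop = FALSE]
    cm <- as.matrix(cv[, spp, drop = FALSE])
    cm <- cm[, colSums(cm) > 0, drop = FALSE]
    rownames(cm) <- NULL
    co <- cores[cores$site_id == sid, , drop = FALSE]
    soil <- unique(co[, c("plot_index", "fresh_wt_g", "dry_wt_g",
                          "root_dry_mass_g")])
    soil <- soil[order(soil$plot_index), ]
    rownames(soil) <- NULL
    counts <- co[order(co$plot_index),
                 c("plot_index", "family", "count")]
    rownames(counts) <- NULL
    list(
      site_id = sid, region_id = site_tab$region_id[s],
      plot_positions = cv$position_m,
      cover = cm, bare_soil = cv$bare_soil, veg_height = cv$veg_height_m,
      counts = counts, soil = soil,
      whc_cores = data.frame(
        sat_wt_g = c(site_tab$whc_sat_wt_g_1[s], site_tab$whc_sat_wt_g_2[s]),
        dry_wt_g = c(site_tab$whc_dry_wt_g_1[s], site_tab$whc_dry_wt_g_2[s])
      ),
      management = list(f = site_tab$f[s], m = site_tab$m[s],
                        g = site_tab$g[s])
    )
  })
  names(sites) <- site_tab$site_id
  structure(list(pool = pool, sites = sites, config = NULL),
            class = "transect_collection")
}
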