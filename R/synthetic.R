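#' Configuration for the synthetic plot-network generator
#'
#' Defaults emulate the geometry of an Andean plot network: 245 plots from
#' 7.1 deg N to 27.8 deg S, 150-3511 m asl, plot areas 0.25/0.5/1 ha
#' (median 1 ha), mean annual temperature spanning 7.3-23.8 C and
#' decreasing with elevation and absolute latitude, and 6.1% of stems
#' without taxonomic identification.  Species composition is drawn from a
#' simulated two-origin (MZO) scenario tree: the probability that a stem
#' belongs to the temperate-origin clade increases with elevation and
#' absolute latitude, which is the mechanism that produces rising
#' phylogenetic diversity along both gradients.  `slope_lat` and
#' `slope_elev` are the target standardized MPD_ses slopes the mixing
#' strength is calibrated to (see the methods vignette for the
#' calibration constant `gain`).
#'
#' @param n_plots number of plots.
#' @param lat_range signed decimal degrees (south negative).
#' @param elev_range metres above sea level.
#' @param areas,area_prob plot-area choices (ha) and their probabilities.
#' @param mat_range range the generated MAT is scaled to (deg C).
#' @param stems_per_ha expected stem density (DBH >= 10 cm).
#' @param unidentified_fraction fraction of stems without identification.
#' @param slope_lat,slope_elev target standardized slopes of MPD_ses on
#'   absolute latitude and elevation (generator truth).
#' @param gain calibration constant converting target slopes into
#'   mixing-weight coefficients (see the methods vignette).
#' @param base_weight baseline temperate-clade mixing weight at the centre
#'   of the gradients.  Kept well below 0.5 so the implied weights stay in
#'   the monotone regime: a community's MPD rises with clade mixing only
#'   until the two clades contribute equally.
#' @param abundance_sd log-normal SD of per-species abundance weights;
#'   skewed abundances (the default 1) give realistic plot richness well
#'   below the stem count.
#' @param area_effect optional mixing-weight shift per ha of plot area
#'   (negative values emulate a negative plot-size effect on diversity).
#' @param tree_config [scenario_config()] for the underlying scenario tree.
#' @return list of class `network_config`.
#' @export
network_config <- function(n_plots = 245,
                           lat_range = c(-27.8, 7.1),
                           elev_range = c(150, 3511),
                           areas = c(0.25, 0.5, 1),
                           area_prob = c(0.25, 0.25, 0.5),
                           mat_range = c(7.3, 23.8),
                           stems_per_ha = 500,
                           unidentified_fraction = 0.061,
                           slope_lat = 0.24, slope_elev = 0.26,
                           gain = 0.05,
                           base_weight = 0.25,
                           abundance_sd = 2,
                           area_effect = 0,
                           tree_config = scenario_config("MZO",
                                                         n_tips = 1000,
                                                         root_stem_frac = 0.5)) {
  stopifnot(n_plots >= 10, diff(lat_range) > 0, diff(elev_range) > 0,
            diff(mat_range) > 0, length(areas) == length(area_prob),
            unidentified_fraction >= 0, unidentified_fraction < 1,
            base_weight > 0, base_weight < 1,
            inherits(tree_config, "scenario_config"))
  structure(list(n_plots = as.integer(n_plots), lat_range = lat_range,
                 elev_range = elev_range, areas = areas,
                 area_prob = area_prob, mat_range = mat_range,
                 stems_per_ha = stems_per_ha,
                 unidentified_fraction = unidentified_fraction,
                 slope_lat = slope_lat, slope_elev = slope_elev,
                 gain = gain, base_weight = base_weight,
                 abundance_sd = abundance_sd,
                 area_effect = area_effect, tree_config = tree_config),
            class = "network_config")
}

#' Generate a synthetic plot network with known gradient structure
#'
#' Simulates an MZO scenario tree, places plots on the latitude/elevation
#' grid, and fills each plot with stems whose species are drawn from the
#' tropical- or temperate-origin clade with a plot-specific mixing weight
#' `w = base_weight + gain * (slope_elev * z(elev) + slope_lat * z(|lat|))
#' + area_effect * (area - mean(area))`.  An error is raised if any
#' implied weight falls outside [0, 1].  The returned truth record stores
#' the target effect directions and magnitudes so recovery tests never
#' have to re-derive them.
#'
#' @param config a [network_config()].
#' @param seed integer seed.
#' @param out_dir optional directory; when given, writes `stems.csv`,
#'   `meta.csv`, `tree.nwk` and `truth.json` there.
#' @return list of class `synthetic_network`: `stems`, `meta` (data.frames
#'   in the dialect [load_inventory()] reads), `tree` (`phylo`), `truth`
#'   (list), `scenario` (the underlying `mzo_scenario`).
#' @export
generate_network <- function(config = network_config(), seed = 1,
                             out_dir = NULL) {
  stopifnot(inherits(config, "network_config"))
  seeds <- split_seed(seed, 4L)
  sc <- build_scenario(config$tree_config, seed = seeds[1L])
  pool_trop <- names(sc$origin)[sc$origin == "TrL"]
  pool_temp <- names(sc$origin)[sc$origin == "TeL"]
  if (!length(pool_temp))
    stop("scenario tree has no temperate-origin clade; use an MZO tree")

  set.seed(seeds[2L])
  n <- config$n_plots
  plot_id <- sprintf("P%03d", seq_len(n))
  lat <- stats::runif(n, config$lat_range[1L], config$lat_range[2L])
  lon <- stats::runif(n, -80, -63)
  elev <- stats::runif(n, config$elev_range[1L], config$elev_range[2L])
  area <- sample(config$areas, n, replace = TRUE, prob = config$area_prob)
  mat_raw <- -0.005 * elev - 0.15 * abs(lat) + stats::rnorm(n, 0, 0.8)
  mat <- config$mat_range[1L] + (mat_raw - min(mat_raw)) *
    diff(config$mat_range) / diff(range(mat_raw))
  map <- pmin(4313, pmax(608, exp(stats::rnorm(n, log(1300), 0.4))))

  w <- config$base_weight +
    config$gain * (config$slope_elev * zscore(elev) +
                   config$slope_lat * zscore(abs(lat))) +
    config$area_effect * (area - mean(area))
  if (any(w < 0 | w > 1))
    stop("infeasible effect sizes: mixing weight outside [0, 1] (range ",
         sprintf("%.3f to %.3f", min(w), max(w)), ")")

  set.seed(seeds[3L])
  ab_trop <- stats::rlnorm(length(pool_trop), 0, config$abundance_sd)
  ab_temp <- stats::rlnorm(length(pool_temp), 0, config$abundance_sd)
  stem_list <- lapply(seq_len(n), function(i) {
    ns <- max(5L, as.integer(round(config$stems_per_ha * area[i])))
    temp <- stats::runif(ns) < w[i]
    taxon <- character(ns)
    taxon[temp] <- sample(pool_temp, sum(temp), replace = TRUE,
                          prob = ab_temp)
    taxon[!temp] <- sample(pool_trop, sum(!temp), replace = TRUE,
                           prob = ab_trop)
    unid <- stats::runif(ns) < config$unidentified_fraction
    data.frame(plot_id = plot_id[i],
               taxon = ifelse(unid, NA_character_, taxon),
               rank = ifelse(unid, "unidentified", "species"),
               dbh_cm = round(10 + stats::rexp(ns, 0.08), 1),
               stringsAsFactors = FALSE)
  })
  stems <- do.call(rbind, stem_list)
  meta <- data.frame(plot_id = plot_id, lat = round(lat, 4),
                     lon = round(lon, 4), elev_m = round(elev),
                     area_ha = area, mat_c = round(mat, 2),
                     map_mm = round(map), stringsAsFactors = FALSE)
  truth <- list(slope_lat_target = config$slope_lat,
                slope_elev_target = config$slope_elev,
                gain = config$gain, base_weight = config$base_weight,
                area_effect = config$area_effect,
                direction = if (config$gain *
                                (config$slope_lat + config$slope_elev) > 0)
                  "positive" else "none",
                n_plots = n, seed = seed,
                n_species_tree = ape::Ntip(sc$tree),
                weight_range = range(w))
  out <- structure(list(stems = stems, meta = meta, tree = sc$tree,
                        truth = truth, scenario = sc),
                   class = "synthetic_network")
  if (!is.null(out_dir)) write_network(out, out_dir)
  out
}

#' Write a synthetic network to disk
#'
#' @param net a `synthetic_network`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "synthetic_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(net$stems, file.path(dir, "stems.csv"),
                   row.names = FALSE)
  utils::write.csv(net$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  ape::write.tree(net$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(net$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a synthetic height-vessel-diameter table
#'
#' Heights are log-uniform over `height_range`; log10 vessel diameter
#' follows `intercept + slope * log10(height)` plus a shift of
#' `origin_offset_log10` for temperate-origin species and Gaussian noise.
#' A negative offset means temperate species have narrower vessels than
#' tropical species of the same height.
#'
#' @param n_per_group species per biogeographic origin (>= 5).
#' @param origin_offset_log10 log10 shift of the temperate group.
#' @param seed integer seed.
#' @param intercept,slope pooled allometry on the log10-log10 scale.
#' @param noise_sd residual SD in log10 units.
#' @param height_range plant heights (m).
#' @param out_dir optional directory; writes `vessels.csv` and
#'   `vessel_truth.json`.
#' @return list of class `synthetic_vessels`: `records` (data.frame with
#'   `species`, `height_m`, `vessel_um`, `origin`) and `truth`.
#' @export
generate_vessels <- function(n_per_group = 150, origin_offset_log10 = -0.08,
                             seed = 1, intercept = 1.3, slope = 0.4,
                             noise_sd = 0.1, height_range = c(2, 60),
                             out_dir = NULL) {
  stopifnot(n_per_group >= 5, noise_sd > 0, all(height_range > 0))
  set.seed(seed)
  n <- 2L * n_per_group
  origin <- rep(c("tropical", "temperate"), each = n_per_group)
  h <- exp(stats::runif(n, log(height_range[1L]), log(height_range[2L])))
  ld <- intercept + slope * log10(h) +
    origin_offset_log10 * (origin == "temperate") +
    stats::rnorm(n, 0, noise_sd)
  rec <- data.frame(species = sprintf("sp%03d", seq_len(n)),
                    height_m = round(h, 2),
                    vessel_um = round(10^ld, 2),
                    origin = origin, stringsAsFactors = FALSE)
  truth <- list(origin_offset_log10 = origin_offset_log10,
                intercept = intercept, slope = slope, noise_sd = noise_sd,
                n_per_group = n_per_group, seed = seed)
  out <- structure(list(records = rec, truth = truth),
                   class = "synthetic_vessels")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rec, file.path(out_dir, "vessels.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "vessel_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
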