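#' Load a plot inventory and its plot metadata
#'
#' Reads and validates the two CSV tables of a plot network: one stem
#' record per row (`plot_id`, `taxon`, `rank`, `dbh_cm`) and one row of
#' metadata per plot (`plot_id`, `lat`, `lon`, `elev_m`, `area_ha`,
#' `mat_c`, optionally `map_mm`).  Referential integrity is enforced:
#' every stem must belong to a known plot.
#'
#' @param stems_csv path to the stems CSV.
#' @param meta_csv path to the plot-metadata CSV.
#' @return list with data.frames `stems` and `meta`.
#' @export
load_inventory <- function(stems_csv, meta_csv) {
  stems <- utils::read.csv(stems_csv, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_csv, stringsAsFactors = FALSE)
  validate_inventory(stems, meta)
}

#' Validate in-memory inventory tables
#'
#' Same checks as [load_inventory()] for data already in data.frames.
#' @param stems,meta data.frames with the inventory columns.
#' @return list with the validated `stems` and `meta`.
#' @export
validate_inventory <- function(stems, meta) {
  need_s <- c("plot_id", "taxon", "rank", "dbh_cm")
  need_m <- c("plot_id", "lat", "lon", "elev_m", "area_ha", "mat_c")
  miss <- setdiff(need_s, names(stems))
  if (length(miss))
    stop("stems table lacks column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_m, names(meta))
  if (length(miss))
    stop("meta table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$plot_id))
    stop("duplicated plot_id in meta: ",
         paste(unique(meta$plot_id[duplicated(meta$plot_id)]), collapse = ", "))
  for (col in c("lat", "lon", "elev_m", "area_ha", "mat_c")) {
    bad <- which(!is.finite(meta[[col]]))
    if (length(bad))
      stop("non-numeric or missing '", col, "' in meta row(s): ",
           paste(bad, collapse = ", "))
  }
  if (any(meta$elev_m < 0)) stop("negative elevation in meta")
  bad <- which(is.finite(stems$dbh_cm) & stems$dbh_cm <= 0)
  if (length(bad))
    stop("non-positive dbh_cm in stems row(s): ", paste(bad, collapse = ", "))
  orphan <- !(stems$plot_id %in% meta$plot_id)
  if (any(orphan))
    stop("stems reference unknown plot_id(s): ",
         paste(unique(stems$plot_id[orphan]), collapse = ", "),
         " (rows ", paste(utils::head(which(orphan), 10), collapse = ", "), ")")
  ranks <- c("species", "genus", "family", "unidentified")
  bad <- setdiff(unique(stems$rank), ranks)
  if (length(bad))
    stop("unknown rank value(s): ", paste(bad, collapse = ", "))
  list(stems = stems, meta = meta)
}

#' Apply the inventory inclusion filters
#'
#' Drops stems without any taxonomic identification and stems with
#' DBH below the 10 cm census threshold, and reports counts per reason.
#' A stem failing both criteria is counted once, under `unidentified`.
#'
#' @param stems stems data.frame.
#' @param min_dbh inclusion threshold in cm (default 10).
#' @return list with `kept` (filtered data.frame) and `report` (list:
#'   `n_input`, `n_unidentified`, `n_small_dbh`, `n_kept`,
#'   `retained_fraction`).
#' @export
filter_stems <- function(stems, min_dbh = 10) {
  unid <- stems$rank == "unidentified"
  small <- !unid & is.finite(stems$dbh_cm) & stems$dbh_cm < min_dbh
  kept <- stems[!unid & !small, , drop = FALSE]
  report <- list(n_input = nrow(stems),
                 n_unidentified = sum(unid),
                 n_small_dbh = sum(small),
                 n_kept = nrow(kept),
                 retained_fraction = nrow(kept) / max(1L, nrow(stems)))
  stopifnot(report$n_kept + report$n_unidentified + report$n_small_dbh ==
              report$n_input)
  list(kept = kept, report = report)
}

#' Plot-by-taxon incidence matrix
#'
#' Builds the binary community matrix from filtered stems, matching taxa
#' against the tips of the supplied phylogeny.  Taxa identified only to
#' genus or family enter under their own labels and must be present as
#' tips in the tree; unmatched taxa go to a coverage report instead of
#' being silently dropped.  Plots left with fewer than 2 matched taxa are
#' excluded (MPD is undefined there) and listed.
#'
#' @param stems filtered stems data.frame (see [filter_stems()]).
#' @param tree a `phylo` whose tips are the candidate taxon labels.
#' @return list with `comm` (binary matrix, plots x taxa), `unmatched`
#'   (taxa absent from the tree, with stem counts), `excluded_plots`.
#' @export
plot_communities <- function(stems, tree) {
  stopifnot(inherits(tree, "phylo"))
  matched <- stems$taxon %in% tree$tip.label
  unmatched <- sort(table(stems$taxon[!matched]), decreasing = TRUE)
  stems <- stems[matched, , drop = FALSE]
  tab <- unique(stems[, c("plot_id", "taxon")])
  richness <- table(tab$plot_id)
  excluded <- names(richness)[richness < 2]
  tab <- tab[!(tab$plot_id %in% excluded), , drop = FALSE]
  plots <- sort(unique(tab$plot_id))
  taxa <- sort(unique(tab$taxon))
  comm <- matrix(0L, length(plots), length(taxa),
                 dimnames = list(plots, taxa))
  comm[cbind(match(tab$plot_id, plots), match(tab$taxon, taxa))] <- 1L
  list(comm = comm, unmatched = unmatched, excluded_plots = excluded)
}

#' Per-plot MPD and MPD_ses against the network-wide pool
#'
#' Computes the standardized effect size of MPD for every plot, using all
#' matched taxa across the network as the shared null pool so values are
#' comparable among plots.  Polytomies in the supplied tree are randomly
#' resolved with zero-length edges; because zero-length resolution leaves
#' patristic distances unchanged, averaging over `n_resolutions` trees is
#' only informative for user-supplied resolutions with nonzero lengths
#' (the default is therefore 1).
#'
#' @param comm binary plot-by-taxon matrix from [plot_communities()].
#' @param tree a `phylo` containing all matrix taxa as tips.
#' @param n_null null draws per plot (default 999).
#' @param n_resolutions number of random polytomy resolutions to average
#'   over.
#' @param pool species pool for the null draws; defaults to all matrix
#'   taxa (the network-wide pool).  Pass a subset (e.g. one country's
#'   taxa) for a restricted null.
#' @param seed optional integer seed.
#' @return data.frame: `plot_id`, `richness`, `mpd`, `null_mean`,
#'   `null_sd`, `ses`, `rank_p` (values averaged over resolutions).
#' @export
plot_mpd_ses <- function(comm, tree, n_null = 999, n_resolutions = 1,
                         pool = colnames(comm), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- colnames(comm)
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss))
    stop("taxa absent from the tree: ", paste(miss, collapse = ", "))
  if (!all(pool %in% taxa))
    stop("'pool' must be a subset of the community-matrix taxa")
  acc <- NULL
  for (r in seq_len(n_resolutions)) {
    res <- resolve_polytomies(tree)
    sub <- ape::keep.tip(res, taxa)
    dm <- cophenetic_matrix(sub)
    rows <- lapply(rownames(comm), function(p) {
      sp <- taxa[comm[p, ] == 1L]
      s <- mpd_ses(sp, dm, pool = pool, n_null = n_null)
      data.frame(plot_id = p, richness = s$richness, mpd = s$observed_mpd,
                 null_mean = s$null_mean, null_sd = s$null_sd,
                 ses = s$ses, rank_p = s$rank_p, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(acc)) acc <- df
    else for (col in c("mpd", "null_mean", "null_sd", "ses", "rank_p"))
      acc[[col]] <- acc[[col]] + df[[col]]
  }
  for (col in c("mpd", "null_mean", "null_sd", "ses", "rank_p"))
    acc[[col]] <- acc[[col]] / n_resolutions
  acc
}

#' Residualize plot diversity on plot size
#'
#' Plot area has a (negative) effect on MPD-type metrics simply through
#' sampling; downstream gradient models therefore use the residuals of an
#' OLS fit of MPD_ses on plot area.  If area does not vary the values are
#' centred and passed through with a warning.
#'
#' @param ses numeric vector of per-plot MPD_ses.
#' @param area numeric vector of plot areas (ha), same length.
#' @return numeric vector of residuals (mean zero).  Attribute
#'   `area_fit` carries the `ols_fit` (NULL in the pass-through case).
#' @export
residualize <- function(ses, area) {
  stopifnot(length(ses) == length(area))
  if (length(ses) < 3L || stats::var(area) == 0) {
    if (stats::var(area) == 0)
      warning("plot area does not vary; returning centred values")
    out <- ses - mean(ses)
    attr(out, "area_fit") <- NULL
    return(out)
  }
  fit <- ols_fit(ses, area)
  out <- ses - (fit$intercept + fit$slope * area)
  attr(out, "area_fit") <- fit
  out
}

#' Gradient regression of plot diversity on a predictor
#'
#' Simple OLS of (area-residualized) MPD_ses on absolute latitude,
#' elevation, or mean annual temperature.  The slope is reported on the
#' raw predictor scale and as a standardized slope (both variables
#' z-scored), the scale on which effect sizes are comparable across
#' predictors.
#'
#' @param values numeric response per plot (typically [residualize()]
#'   output).
#' @param predictor numeric predictor per plot.
#' @param name optional predictor label carried in the result.
#' @return list of class `gradient_fit`: `predictor`, `n`, `slope_raw`,
#'   `slope_std`, `f`, `r2`, `p`.
#' @export
empirical_gradient <- function(values, predictor, name = "predictor") {
  if (length(values) < 10L) stop("need at least 10 plots")
  fit_raw <- ols_fit(values, predictor)
  fit_std <- ols_fit(zscore(values), zscore(predictor))
  structure(list(predictor = name, n = fit_raw$n,
                 slope_raw = fit_raw$slope, slope_std = fit_std$slope,
                 f = fit_raw$f, r2 = fit_raw$r2, p = fit_raw$p),
            class = "gradient_fit")
}

#' Run the full empirical gradient pipeline
#'
#' Filters stems, builds the community matrix, computes per-plot MPD_ses
#' against the network-wide pool, residualizes on plot area, and fits
#' gradient regressions on absolute latitude (or signed latitude via
#' `abs_latitude = FALSE`), elevation, and mean annual temperature.
#'
#' @param stems,meta validated inventory tables (see [load_inventory()]).
#' @param tree supplied phylogeny (`phylo`).
#' @param n_null null draws per plot.
#' @param n_resolutions random polytomy resolutions to average over.
#' @param abs_latitude use absolute latitude (default) or signed.
#' @param seed optional integer seed.
#' @return list of class `empirical_result`: `plots` (per-plot table with
#'   `ses` and `resid`), `gradients` (list of `gradient_fit` for
#'   `latitude`, `elevation`, `mat`), `filter_report`, `coverage`
#'   (unmatched taxa, excluded plots), `area_fit`.
#' @export
empirical_pipeline <- function(stems, meta, tree, n_null = 999,
                               n_resolutions = 1, abs_latitude = TRUE,
                               seed = NULL) {
  inv <- validate_inventory(stems, meta)
  flt <- filter_stems(inv$stems)
  pc <- plot_communities(flt$kept, tree)
  div <- plot_mpd_ses(pc$comm, tree, n_null = n_null,
                      n_resolutions = n_resolutions, seed = seed)
  m <- inv$meta[match(div$plot_id, inv$meta$plot_id), ]
  div$lat <- m$lat
  div$abs_lat <- abs(m$lat)
  div$elev_m <- m$elev_m
  div$area_ha <- m$area_ha
  div$mat_c <- m$mat_c
  res <- residualize(div$ses, div$area_ha)
  div$resid <- as.numeric(res)
  area_fit <- attr(res, "area_fit")
  latv <- if (abs_latitude) div$abs_lat else div$lat
  gradients <- list(
    latitude = empirical_gradient(div$resid, latv, "latitude"),
    elevation = empirical_gradient(div$resid, div$elev_m, "elevation"),
    mat = empirical_gradient(div$resid, div$mat_c, "mat"))
  structure(list(plots = div, gradients = gradients,
                 filter_report = flt$report,
                 coverage = list(unmatched = pc$unmatched,
                                 excluded_plots = pc$excluded_plots),
                 area_fit = area_fit),
            class = "empirical_result")
}

#' Height-vessel-diameter model with a biogeographic-origin covariate
#'
#' Two complementary views of whether temperate-origin species have
#' narrower vessels than tropical-origin species of the same height:
#' (a) OLS of log10 vessel diameter on log10 plant height plus a 0/1
#' origin indicator (tropical = 0), with the partial F-test for the origin
#' term; (b) residuals of the pooled log-log fit *without* origin,
#' compared between origins with a two-sample pooled-variance t-test.
#'
#' @param records data.frame with columns `species`, `height_m`,
#'   `vessel_um`, `origin` (`"tropical"` / `"temperate"`), at least 10
#'   rows per origin.
#' @return list of class `vessel_fit`: `n`, `slope_logheight`,
#'   `origin_effect` (log10 shift for temperate), `origin_f`, `origin_p`,
#'   `resid_t`, `resid_t_p`, `group_means` (mean pooled-fit residual per
#'   origin).
#' @export
vessel_model <- function(records) {
  need <- c("species", "height_m", "vessel_um", "origin")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("vessel table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(records$height_m <= 0) || any(records$vessel_um <= 0))
    stop("heights and vessel diameters must be positive")
  counts <- table(factor(records$origin,
                         levels = c("tropical", "temperate")))
  if (any(counts == 0))
    stop("both biogeographic origins must be represented")
  if (any(counts < 10))
    stop("need at least 10 records per origin")
  ly <- log10(records$vessel_um)
  lx <- log10(records$height_m)
  temperate <- as.integer(records$origin == "temperate")
  full <- stats::lm(ly ~ lx + temperate)
  an <- stats::anova(full)
  pooled <- stats::lm(ly ~ lx)
  res <- stats::residuals(pooled)
  tt <- stats::t.test(res[temperate == 0], res[temperate == 1],
                      var.equal = TRUE)
  structure(list(n = nrow(records),
                 slope_logheight = unname(stats::coef(full)["lx"]),
                 origin_effect = unname(stats::coef(full)["temperate"]),
                 origin_f = an["temperate", "F value"],
                 origin_p = an["temperate", "Pr(>F)"],
                 resid_t = unname(tt$statistic),
                 resid_t_p = tt$p.value,
                 group_means = c(tropical = mean(res[temperate == 0]),
                                 temperate = mean(res[temperate == 1]))),
            class = "vessel_fit")
}
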