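#' Standardize values to zero mean and unit standard deviation
#'
#' @param x numeric vector, length >= 2, with nonzero variance.
#' @return numeric vector with mean 0 and SD 1 (denominator n - 1).
#' @export
zscore <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop(errorCondition("zero variance; cannot standardize",
                        class = c("mzosim_degenerate", "error", "condition")))
  (x - mean(x)) / s
}

#' Simple ordinary least squares fit
#'
#' Closed-form simple regression of `y` on `x`, reporting the slope F-test
#' (`F = t^2`, p from the F(1, n-2) distribution, equivalent to the
#' two-sided t-test on the slope).
#'
#' @param y response vector.
#' @param x predictor vector, non-constant, same length as `y` (n >= 3).
#' @return list of class `ols_fit`: `slope`, `intercept`, `se_slope`,
#'   `t`, `f`, `r2`, `p`, `n`.
#' @export
ols_fit <- function(y, x) {
  n <- length(y)
  stopifnot(length(x) == n)
  if (n < 3L) stop("need at least 3 observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("constant predictor")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- syy - slope * sxy
  rss <- max(rss, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  fval <- tval^2
  structure(list(slope = slope, intercept = intercept, se_slope = se,
                 t = tval, f = fval,
                 r2 = if (syy > 0) 1 - rss / syy else NA_real_,
                 p = stats::pf(fval, 1, n - 2, lower.tail = FALSE),
                 n = n),
            class = "ols_fit")
}

# Per-replicate RNG discipline: one master seed is split into independent
# stage seeds (tree+states, community sampling, nulls, redraws) so each
# stage is reproducible on its own.
split_seed <- function(seed, n = 4L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run one simulation replicate: scenario, communities, MPD_ses, slopes
#'
#' Executes the full per-replicate pipeline: [build_scenario()], regional
#' pools, [sample_communities()], [mpd_ses()] per community, z-scoring of
#' the community MPD_ses values, and OLS of the standardized values on the
#' binary latitude code (tropical = 0, temperate = 1) and elevation code
#' (lowland = 0, highland = 1).  Replicates whose regional pools fall
#' below 20 species are redrawn with a fresh seed (counted in
#' `n_redraws`).
#'
#' @param config a [scenario_config()].
#' @param seed integer master seed for the replicate.
#' @param max_redraws redraw attempts before giving up.
#' @return list of class `mzo_replicate`: `slope_lat`, `p_lat`,
#'   `slope_elev`, `p_elev`, `community_stats` (data.frame of per-community
#'   region, codes, richness, mpd, ses), `n_redraws`.
#' @export
run_replicate <- function(config, seed, max_redraws = 25) {
  stopifnot(inherits(config, "scenario_config"))
  reg <- region_table()
  for (try in seq_len(max_redraws + 1L)) {
    seeds <- split_seed((seed + try - 1L) %% .Machine$integer.max, 3L)
    sc <- build_scenario(config, seed = seeds[1L])
    pools <- regional_pools(sc$states)
    cs <- tryCatch(
      sample_communities(pools, config$n_per_region, config$fraction,
                         seed = seeds[2L]),
      mzosim_degenerate_pool = function(e) NULL)
    if (!is.null(cs)) break
    if (try > max_redraws)
      stop("regional pools stayed degenerate after ", max_redraws,
           " redraws")
  }
  dm <- cophenetic_matrix(sc$tree)
  meta_pool <- sort(unique(unlist(cs$communities, use.names = FALSE)))
  set.seed(seeds[3L])
  rows <- lapply(names(cs$communities), function(id) {
    comm <- cs$communities[[id]]
    r <- cs$region[[id]]
    pool <- if (config$null_pool == "metacommunity") meta_pool
            else pools[[r]]
    s <- mpd_ses(comm, dm, pool, n_null = config$n_null)
    data.frame(community_id = id, region = r,
               latitude_code = as.integer(reg$latitude_zone[
                 match(r, reg$code)] == "temperate"),
               elevation_code = as.integer(reg$elevation_zone[
                 match(r, reg$code)] == "highland"),
               richness = s$richness, mpd = s$observed_mpd, ses = s$ses,
               rank_p = s$rank_p, stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, rows)
  z <- zscore(stats_df$ses)
  fit_lat <- ols_fit(z, stats_df$latitude_code)
  fit_elev <- ols_fit(z, stats_df$elevation_code)
  structure(list(slope_lat = fit_lat$slope, p_lat = fit_lat$p,
                 slope_elev = fit_elev$slope, p_elev = fit_elev$p,
                 community_stats = stats_df, n_redraws = try - 1L),
            class = "mzo_replicate")
}

#' Run a replicated simulation study and aggregate slope statistics
#'
#' Repeats [run_replicate()] `n_reps` times with independent seeds derived
#' from `seed`, collects the latitude and elevation slopes, and summarizes
#' them: mean slope, one-sample two-sided t-test against zero, the
#' fraction of replicates with a significant slope (two-sided p < 0.05),
#' and the fraction significant *in the scenario-predicted direction*
#' (negative under TNC, positive under MZO).
#'
#' @param config a [scenario_config()].
#' @param n_reps number of replicates (>= 2).
#' @param seed master seed.
#' @param rep_seeds optional explicit vector of per-replicate seeds
#'   (overrides `seed`-based derivation; mainly for reproducing single
#'   replicates).
#' @return list of class `simulation_summary`: `scenario`, `n_reps`,
#'   `replicates` (data.frame with per-replicate slopes and p-values),
#'   and per-gradient summaries `latitude` and `elevation`, each a list
#'   with `mean_slope`, `sd_slope`, `t`, `t_p`, `frac_significant`,
#'   `frac_significant_predicted`, `degenerate`.
#' @export
run_study <- function(config, n_reps = 1000, seed = 1, rep_seeds = NULL) {
  stopifnot(inherits(config, "scenario_config"), n_reps >= 2)
  if (is.null(rep_seeds)) {
    set.seed(seed)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  } else {
    n_reps <- length(rep_seeds)
  }
  reps <- lapply(seq_len(n_reps), function(i) {
    r <- run_replicate(config, seed = rep_seeds[i])
    data.frame(rep = i, seed = rep_seeds[i],
               slope_lat = r$slope_lat, p_lat = r$p_lat,
               slope_elev = r$slope_elev, p_elev = r$p_elev,
               n_redraws = r$n_redraws)
  })
  df <- do.call(rbind, reps)
  pred_sign <- if (config$scenario == "TNC") -1 else 1
  summarize <- function(slopes, pvals) {
    s <- stats::sd(slopes)
    degen <- !is.finite(s) || s == 0
    tt <- if (!degen) stats::t.test(slopes, mu = 0) else NULL
    list(mean_slope = mean(slopes), sd_slope = s,
         t = if (degen) NA_real_ else unname(tt$statistic),
         t_p = if (degen) NA_real_ else tt$p.value,
         frac_significant = mean(pvals < 0.05),
         frac_significant_predicted =
           mean(pvals < 0.05 & sign(slopes) == pred_sign),
         degenerate = degen)
  }
  structure(list(scenario = config$scenario, n_reps = n_reps,
                 config = config, replicates = df,
                 latitude = summarize(df$slope_lat, df$p_lat),
                 elevation = summarize(df$slope_elev, df$p_elev)),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("%s simulation study: %d replicates\n", x$scenario, x$n_reps))
  for (g in c("latitude", "elevation")) {
    s <- x[[g]]
    cat(sprintf(
      "  %-9s mean slope %+.3f (t = %.2f, p = %.2g); %.1f%% significant, %.1f%% in predicted direction\n",
      g, s$mean_slope, s$t, s$t_p, 100 * s$frac_significant,
      100 * s$frac_significant_predicted))
  }
  invisible(x)
}

#' Compare slope distributions of two scenarios
#'
#' Two-sample Kolmogorov-Smirnov test between the replicate slope
#' distributions of two studies.
#'
#' @param slopes_a,slopes_b numeric vectors of slopes (>= 10 each).
#' @return list with `D` (KS statistic) and `p`.
#' @export
compare_scenarios <- function(slopes_a, slopes_b) {
  if (length(slopes_a) < 10 || length(slopes_b) < 10)
    stop("need at least 10 slopes per scenario")
  k <- stats::ks.test(slopes_a, slopes_b)
  list(D = unname(k$statistic), p = k$p.value)
}
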