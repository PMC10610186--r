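#' Regional species pools from tip states
#'
#' Every species whose simulated range is a region belongs to that region's
#' pool; since each species occupies exactly one region, the four pools
#' partition the tip set.
#'
#' @param states named character vector of region codes per tip, as
#'   returned by [simulate_regions()] or found in `build_scenario()$states`.
#' @return named list of four character vectors (TrL, TrH, TeL, TeH), some
#'   possibly empty.
#' @export
regional_pools <- function(states) {
  if (length(states) == 0L) stop("'states' is empty")
  if (is.null(names(states))) stop("'states' must be named by tip label")
  bad <- setdiff(unique(states), region_codes())
  if (length(bad)) stop("unknown region code(s): ", paste(bad, collapse = ", "))
  out <- lapply(region_codes(), function(r) names(states)[states == r])
  stats::setNames(out, region_codes())
}

# Community size rule: round(fraction * pool) with a floor of 2 species
# (MPD needs at least one pair).  Plain base-R round().
community_size <- function(pool_size, fraction) {
  max(2L, as.integer(round(fraction * pool_size)))
}

#' Sample local communities from regional pools
#'
#' Draws `n_per_region` communities per region, each a uniform random
#' subset (without replacement, independent across communities) of
#' `round(fraction * pool size)` species, floored at 2.  A pool smaller
#' than `min_pool` species makes the whole replicate uninformative; a
#' classed error (`mzosim_degenerate_pool`) is raised so study-level code
#' can redraw the replicate.
#'
#' @param pools output of [regional_pools()].
#' @param n_per_region communities per region (default 10).
#' @param fraction fraction of the pool per community (default 0.10).
#' @param seed optional integer seed.
#' @param min_pool smallest workable pool (default 20 species).
#' @return object of class `community_set`: list with `communities` (named
#'   list of species vectors, names like `"TrL_3"`), `region` (named vector
#'   mapping community id to region), `fraction`, `n_per_region`.
#' @export
sample_communities <- function(pools, n_per_region = 10, fraction = 0.10,
                               seed = NULL, min_pool = 20) {
  stopifnot(is.list(pools), all(region_codes() %in% names(pools)))
  if (!is.null(seed)) set.seed(seed)
  small <- region_codes()[vapply(pools[region_codes()], length, 1L) < min_pool]
  if (length(small))
    stop(errorCondition(
      paste0("regional pool(s) below ", min_pool, " species: ",
             paste(small, collapse = ", ")),
      class = c("mzosim_degenerate_pool", "error", "condition")))
  comms <- list(); region <- character(0)
  for (r in region_codes()) {
    pool <- pools[[r]]
    k <- community_size(length(pool), fraction)
    for (i in seq_len(n_per_region)) {
      id <- paste0(r, "_", i)
      comms[[id]] <- sample(pool, k)
      region[id] <- r
    }
  }
  structure(list(communities = comms, region = region,
                 fraction = fraction, n_per_region = n_per_region),
            class = "community_set")
}

#' Long-format table of a community set
#'
#' @param x a `community_set`.
#' @param ... unused.
#' @return data.frame with columns `region`, `community_id`, `species`,
#'   one row per occurrence (the CSV-ready long format).
#' @export
as.data.frame.community_set <- function(x, ...) {
  do.call(rbind, lapply(names(x$communities), function(id) {
    data.frame(region = x$region[[id]], community_id = id,
               species = x$communities[[id]], stringsAsFactors = FALSE)
  }))
}

#' Binary incidence matrix of a community set
#'
#' @param cs a `community_set`.
#' @return integer matrix, communities x species, entries 0/1.
#' @export
community_incidence <- function(cs) {
  stopifnot(inherits(cs, "community_set"))
  sp <- sort(unique(unlist(cs$communities)))
  m <- matrix(0L, length(cs$communities), length(sp),
              dimnames = list(names(cs$communities), sp))
  for (id in names(cs$communities)) m[id, cs$communities[[id]]] <- 1L
  m
}
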