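#' The four biogeographic regions
#'
#' Regions combine a latitude zone and an elevation zone.  The tropical
#' lowlands are warm and wet; the tropical highlands and both temperate
#' regions share a cold/seasonal climate, which is what makes dispersal
#' between them "easy" relative to moves across climate classes.
#'
#' @return a data.frame with columns `code`, `latitude_zone`,
#'   `elevation_zone`, `climate_class`, one row per region, in the fixed
#'   order TrL, TrH, TeL, TeH used by all rate matrices in the package.
#' @export
region_table <- function() {
  data.frame(
    code           = c("TrL", "TrH", "TeL", "TeH"),
    latitude_zone  = c("tropical", "tropical", "temperate", "temperate"),
    elevation_zone = c("lowland", "highland", "lowland", "highland"),
    climate_class  = c("warm_wet", "cold_seasonal", "cold_seasonal",
                       "cold_seasonal"),
    stringsAsFactors = FALSE
  )
}

region_codes <- function() c("TrL", "TrH", "TeL", "TeH")

#' Build the region transition-rate matrix for a scenario
#'
#' Both scenarios (TNC and MZO) share one 4x4 generator `Q`: what differs
#' between them is the root construction handled by [build_scenario()], not
#' the allowed moves.  Moves between regions of the same climate class
#' (TeL-TeH, TrH-TeH) occur at `rate_similar`; moves that cross climate
#' classes (TrL-TrH, TrL-TeL) occur at the lower `rate_dissimilar`.  The
#' TrH-TeL pair, although climatically similar, is disconnected by default
#' (no direct lowland-temperate to highland-tropical corridor); set
#' `rate_trh_tel` to open it.
#'
#' @param scenario `"TNC"` or `"MZO"` (recorded as a tag on the model).
#' @param rate_similar shift rate between climatically similar regions
#'   (per lineage per My).
#' @param rate_dissimilar shift rate between climatically dissimilar
#'   regions; must be strictly less than `rate_similar`.
#' @param rate_trh_tel optional rate for the TrH-TeL pair (default 0).
#' @return an object of class `transition_model`: a list with the generator
#'   `Q` (rows sum to zero), the scenario tag and the two rates.
#' @examples
#' m <- build_transition_model("TNC", 0.1, 0.01)
#' m$Q
#' @export
build_transition_model <- function(scenario = c("TNC", "MZO"),
                                   rate_similar = 0.1,
                                   rate_dissimilar = 0.01,
                                   rate_trh_tel = 0) {
  scenario <- match.arg(scenario)
  if (rate_similar < 0 || rate_dissimilar < 0 || rate_trh_tel < 0)
    stop("transition rates must be non-negative")
  if (rate_similar <= rate_dissimilar)
    stop("'rate_similar' must exceed 'rate_dissimilar'")
  r <- region_codes()
  Q <- matrix(0, 4, 4, dimnames = list(r, r))
  Q["TrL", "TeL"] <- Q["TeL", "TrL"] <- rate_dissimilar
  Q["TrL", "TrH"] <- Q["TrH", "TrL"] <- rate_dissimilar
  Q["TeL", "TeH"] <- Q["TeH", "TeL"] <- rate_similar
  Q["TrH", "TeH"] <- Q["TeH", "TrH"] <- rate_similar
  Q["TrH", "TeL"] <- Q["TeL", "TrH"] <- rate_trh_tel
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, scenario = scenario,
                 rate_similar = rate_similar,
                 rate_dissimilar = rate_dissimilar),
            class = "transition_model")
}

#' Evolve region states along a phylogeny
#'
#' Simulates a continuous-time Markov chain with generator `model$Q`
#' independently along every edge, child nodes inheriting the state their
#' parent edge ends in.  This is the standard stochastic-mapping forward
#' simulation for a discrete trait ("region" treated as a species trait).
#'
#' @param tree an extant-only `phylo`.
#' @param model a [build_transition_model()] object.
#' @param root_state region code at the root.
#' @param seed optional integer seed.
#' @return named character vector of tip region codes.  Attributes:
#'   `n_events` (total number of state shifts on the tree) and
#'   `node_state` (states at all nodes, tips first).
#' @export
simulate_regions <- function(tree, model, root_state = "TrL", seed = NULL) {
  stopifnot(inherits(model, "transition_model"), inherits(tree, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  Q <- model$Q
  codes <- rownames(Q)
  root_state <- match.arg(root_state, codes)
  nt <- ape::Ntip(tree)
  pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  node_state <- integer(nt + tree$Nnode)
  node_state[nt + 1L] <- match(root_state, codes)
  n_events <- 0L
  exit_rate <- -diag(Q)
  jump <- Q; diag(jump) <- 0
  jump <- jump / ifelse(exit_rate > 0, exit_rate, 1)

  for (e in seq_len(nrow(pre$edge))) {
    s <- node_state[pre$edge[e, 1L]]
    len <- pre$edge.length[e]
    t <- 0
    while (exit_rate[s] > 0) {
      t <- t + stats::rexp(1L, exit_rate[s])
      if (t > len) break
      s <- sample.int(4L, 1L, prob = jump[s, ])
      n_events <- n_events + 1L
    }
    node_state[pre$edge[e, 2L]] <- s
  }
  out <- stats::setNames(codes[node_state[seq_len(nt)]], tree$tip.label)
  attr(out, "n_events") <- n_events
  attr(out, "node_state") <- codes[node_state]
  out
}

#' Scenario configuration
#'
#' Bundles every knob of one simulated diversification scenario.  Defaults
#' reproduce the study conditions: speciation 0.5 and extinction 0.05 per
#' lineage per My, a 75/25 tropical/temperate richness split under MZO,
#' and 10 communities per region sampled at 10% of the pool.  The two
#' region-shift rates are not stated by the hypotheses themselves; the
#' defaults (0.5 similar-climate, 0.002 dissimilar-climate shifts per
#' lineage per My) are calibrated so that dissimilar-climate colonization
#' is a rare founder event whose descendants cluster phylogenetically,
#' while climatically similar regions exchange lineages freely -- the
#' regime in which the two hypotheses separate cleanly (see the methods
#' vignette for the calibration).
#'
#' @param scenario `"TNC"` (single TrL origin) or `"MZO"` (two origins).
#' @param n_tips total extant species richness of the clade (>= 8 for MZO).
#' @param lambda,mu birth-death rates (per lineage per My).
#' @param rate_similar,rate_dissimilar region shift rates, see
#'   [build_transition_model()].
#' @param rate_trh_tel rate of the TrH-TeL similar-climate corridor.
#' @param tropical_fraction share of total richness in the TrL-origin clade
#'   under MZO.
#' @param n_per_region local communities sampled per regional pool.
#' @param fraction fraction of each pool sampled into a community.
#' @param root_stem_frac under MZO, length of the stem below the deeper
#'   origin clade as a fraction of its crown age.  0 joins the two crowns
#'   directly at the root; positive values push the common root deeper,
#'   separating the two origin floras by `2 * root_stem_frac * crown age`
#'   of extra path length.
#' @param n_null null draws for the MPD standardized effect size.
#' @param null_pool `"metacommunity"` (all species occurring in any sampled
#'   community, the shared pool that makes values comparable across
#'   regions) or `"regional"` (each community tested against its own
#'   regional pool).
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("TNC", "MZO"), n_tips = 10000,
                            lambda = 0.5, mu = 0.05,
                            rate_similar = 0.5, rate_dissimilar = 0.002,
                            rate_trh_tel = 0,
                            tropical_fraction = 0.75,
                            root_stem_frac = 0.05,
                            n_per_region = 10, fraction = 0.10,
                            n_null = 999,
                            null_pool = c("metacommunity", "regional")) {
  scenario <- match.arg(scenario)
  null_pool <- match.arg(null_pool)
  stopifnot(n_tips >= 2, lambda > 0, mu >= 0, mu < lambda,
            tropical_fraction > 0, tropical_fraction < 1,
            root_stem_frac >= 0,
            n_per_region >= 1, fraction > 0, fraction <= 1)
  if (scenario == "MZO" && n_tips < 8)
    stop("MZO needs n_tips >= 8 so both origin clades have >= 2 tips")
  structure(list(scenario = scenario, n_tips = as.integer(n_tips),
                 lambda = lambda, mu = mu,
                 rate_similar = rate_similar,
                 rate_dissimilar = rate_dissimilar,
                 rate_trh_tel = rate_trh_tel,
                 tropical_fraction = tropical_fraction,
                 root_stem_frac = root_stem_frac,
                 n_per_region = as.integer(n_per_region),
                 fraction = fraction, n_null = as.integer(n_null),
                 null_pool = null_pool),
            class = "scenario_config")
}

#' Build one diversification scenario: tree plus tip regions
#'
#' Under TNC a single birth-death clade of `n_tips` species diversifies
#' from a TrL root.  Under MZO two clades are simulated independently --
#' `round(tropical_fraction * n_tips)` species with a TrL origin and the
#' remainder with a TeL origin -- and joined at a common root: the deeper
#' crown age sets the join depth and the shallower clade's stem is extended
#' so both crowns are contemporaneous (the joined tree is ultrametric).
#' Region evolution runs independently within each clade from its origin
#' state; no state change happens on the artificial stem edges, since the
#' origins are the defining assumption of the scenario.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer seed.
#' @return a list of class `mzo_scenario` with elements `tree` (ultrametric
#'   extant-only `phylo`), `states` (named region codes per tip), `origin`
#'   (named origin-clade root state per tip), `model` (the
#'   `transition_model`) and `config`.
#' @examples
#' sc <- build_scenario(scenario_config("MZO", n_tips = 40), seed = 1)
#' table(sc$states)
#' @export
build_scenario <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  model <- build_transition_model(config$scenario,
                                  config$rate_similar,
                                  config$rate_dissimilar,
                                  config$rate_trh_tel)
  if (config$scenario == "TNC") {
    tr <- prune_extinct(simulate_birth_death(config$lambda, config$mu,
                                             n_tips = config$n_tips))
    st <- simulate_regions(tr, model, root_state = "TrL")
    origin <- stats::setNames(rep("TrL", length(st)), names(st))
  } else {
    n_trop <- as.integer(round(config$tropical_fraction * config$n_tips))
    n_temp <- config$n_tips - n_trop
    if (n_trop < 2L || n_temp < 2L)
      stop("MZO split leaves fewer than 2 tips in one origin clade")
    t_trop <- prune_extinct(simulate_birth_death(config$lambda, config$mu,
                                                 n_tips = n_trop))
    t_temp <- prune_extinct(simulate_birth_death(config$lambda, config$mu,
                                                 n_tips = n_temp))
    t_trop$tip.label <- sprintf("t%d", seq_len(ape::Ntip(t_trop)))
    t_temp$tip.label <- sprintf("u%d", seq_len(ape::Ntip(t_temp)))
    s_trop <- simulate_regions(t_trop, model, root_state = "TrL")
    s_temp <- simulate_regions(t_temp, model, root_state = "TeL")
    tr <- join_clades(t_trop, t_temp, stem_frac = config$root_stem_frac)
    st <- c(s_trop, s_temp)[tr$tip.label]
    origin <- stats::setNames(
      ifelse(startsWith(tr$tip.label, "t"), "TrL", "TeL"), tr$tip.label)
    attr(st, "n_events") <-
      attr(s_trop, "n_events") + attr(s_temp, "n_events")
  }
  structure(list(tree = tr, states = st, origin = origin,
                 model = model, config = config),
            class = "mzo_scenario")
}

# Join two ultrametric clades below a new root.  With stem_frac = 0 the
# deeper crown sets the join depth; stem_frac > 0 pushes the root below it
# by that fraction of the deeper crown age.  The shallower clade's stem is
# extended so all tips stay contemporaneous.  Tip labels must be disjoint.
join_clades <- function(a, b, stem_frac = 0) {
  if (any(a$tip.label %in% b$tip.label))
    stop("tip labels of the two clades must be disjoint")
  ha <- tree_height(a); hb <- tree_height(b)
  h <- max(ha, hb) * (1 + stem_frac)
  na <- ape::Ntip(a); nb <- ape::Ntip(b)
  ia <- a$Nnode; ib <- b$Nnode
  root <- na + nb + 1L
  # renumber: tips of a keep 1..na, tips of b become na+1..na+nb; internal
  # nodes shift to root+1.. (clade a) and root+1+ia.. (clade b)
  map_a <- function(v) ifelse(v <= na, v, v + nb + 1L)
  map_b <- function(v) ifelse(v <= nb, v + na, v + na + ia + 1L)
  edge <- rbind(
    c(root, root + 1L),
    cbind(map_a(a$edge[, 1L]), map_a(a$edge[, 2L])),
    c(root, root + 1L + ia),
    cbind(map_b(b$edge[, 1L]), map_b(b$edge[, 2L])))
  len <- c(h - ha, a$edge.length, h - hb, b$edge.length)
  out <- list(edge = edge, edge.length = len,
              tip.label = c(a$tip.label, b$tip.label),
              Nnode = ia + ib + 1L)
  class(out) <- "phylo"
  out
}
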