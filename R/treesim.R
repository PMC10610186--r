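#' Simulate a birth-death phylogeny
#'
#' Forward (Gillespie) simulation of a constant-rate birth-death process
#' starting from a single lineage.  Each extant lineage waits an exponential
#' time with total rate `lambda + mu`, then either speciates (probability
#' `lambda / (lambda + mu)`) or goes extinct.  The simulation stops either
#' the first time the number of extant lineages reaches `n_tips` (the tree is
#' cut at that instant) or at `max_time`, whichever is requested.  Extinct
#' lineages are retained as non-contemporaneous tips; remove them with
#' [prune_extinct()].
#'
#' Branch lengths are in nominal millions of years, matching the usual
#' reading of a speciation rate of 0.5 as one speciation per lineage per
#' 2 My.  If the whole clade goes extinct before the stopping condition is
#' met the simulation is restarted, drawing further values from the same
#' random stream, up to `retries` times.
#'
#' @param lambda speciation rate (events per lineage per My), > 0.
#' @param mu extinction rate (events per lineage per My), `0 <= mu < lambda`.
#' @param n_tips stop when this many lineages are simultaneously extant
#'   (>= 2).  Exactly one of `n_tips` and `max_time` must be given.
#' @param max_time stop at this time instead of at a fixed tip count.
#' @param retries number of restarts allowed after whole-clade extinction.
#' @param seed optional integer seed (`set.seed` is called when non-NULL).
#' @return an object of class `phylo`.  The stem branch below the first
#'   speciation is kept as `root.edge`.  Attribute `n_extant` gives the
#'   number of extant tips.
#' @seealso [prune_extinct()], [is_extinct_tip()]
#' @examples
#' tr <- simulate_birth_death(0.5, 0.05, n_tips = 50, seed = 1)
#' sum(!is_extinct_tip(tr))
#' @export
simulate_birth_death <- function(lambda, mu, n_tips = NULL, max_time = NULL,
                                 retries = 100, seed = NULL) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0,
            is.numeric(mu), length(mu) == 1L, mu >= 0, mu < lambda)
  if (is.null(n_tips) == is.null(max_time))
    stop("exactly one of 'n_tips' and 'max_time' must be supplied")
  if (!is.null(n_tips) && (n_tips != round(n_tips) || n_tips < 2))
    stop("'n_tips' must be an integer >= 2")
  if (!is.null(max_time) && max_time <= 0) stop("'max_time' must be > 0")
  if (!is.null(seed)) set.seed(seed)

  for (attempt in seq_len(retries + 1L)) {
    tab <- bd_lineage_table(lambda, mu, n_tips = n_tips, max_time = max_time)
    if (!is.null(tab)) {
      tr <- lineage_table_to_phylo(tab)
      attr(tr, "n_extant") <- sum(tab$fate == "extant")
      return(tr)
    }
  }
  stop("clade went extinct in all ", retries + 1L, " attempts")
}

# Core event loop on a flat lineage table.  Returns NULL on whole-clade
# extinction, or (in max_time mode) when fewer than 2 lineages ever existed.
# RNG draws per event, in order: waiting time (rexp), event type (runif),
# lineage choice (sample.int) -- relied upon by matched-stream oracle tests.
bd_lineage_table <- function(lambda, mu, n_tips = NULL, max_time = NULL) {
  cap <- 256L
  start <- numeric(cap); end <- numeric(cap)
  parent <- integer(cap); fate <- character(cap)
  n_lin <- 1L
  start[1L] <- 0; parent[1L] <- 0L
  alive <- integer(cap); alive[1L] <- 1L; n_alive <- 1L
  t <- 0
  total <- lambda + mu
  p_birth <- lambda / total

  repeat {
    if (!is.null(n_tips) && n_alive >= n_tips) break
    dt <- stats::rexp(1L, n_alive * total)
    is_birth <- stats::runif(1L) < p_birth
    idx <- sample.int(n_alive, 1L)
    if (!is.null(max_time) && t + dt > max_time) { t <- max_time; break }
    t <- t + dt
    lin <- alive[idx]
    if (is_birth) {
      if (n_lin + 2L > cap) {
        cap <- cap * 2L
        length(start) <- cap; length(end) <- cap
        length(parent) <- cap; length(fate) <- cap
        length(alive) <- cap
      }
      end[lin] <- t; fate[lin] <- "split"
      c1 <- n_lin + 1L; c2 <- n_lin + 2L
      start[c1] <- t; start[c2] <- t
      parent[c1] <- lin; parent[c2] <- lin
      n_lin <- n_lin + 2L
      alive[idx] <- c1
      n_alive <- n_alive + 1L
      alive[n_alive] <- c2
    } else {
      end[lin] <- t; fate[lin] <- "extinct"
      alive[idx] <- alive[n_alive]
      n_alive <- n_alive - 1L
      if (n_alive == 0L) return(NULL)
    }
  }
  if (n_alive < 2L) return(NULL)
  live <- alive[seq_len(n_alive)]
  end[live] <- t; fate[live] <- "extant"
  keep <- seq_len(n_lin)
  list(start = start[keep], end = end[keep], parent = parent[keep],
       fate = fate[keep], cut_time = t)
}

# Lineage table -> ape phylo.  Internal nodes are numbered in order of
# splitting time, so the first split (the root) gets number Ntip + 1 and
# every parent precedes its descendants, as ape expects.
lineage_table_to_phylo <- function(tab) {
  is_split <- tab$fate == "split"
  tip_lin <- which(!is_split)
  int_lin <- which(is_split)              # already in splitting order
  n_tip <- length(tip_lin)
  node_id <- integer(length(tab$fate))
  node_id[tip_lin] <- seq_len(n_tip)
  node_id[int_lin] <- n_tip + seq_along(int_lin)

  child <- which(tab$parent > 0L)
  edge <- cbind(node_id[tab$parent[child]], node_id[child])
  len <- tab$end[child] - tab$start[child]
  ord <- order(edge[, 1L], edge[, 2L])

  tr <- list(edge = edge[ord, , drop = FALSE],
             edge.length = len[ord],
             tip.label = paste0("t", seq_len(n_tip)),
             Nnode = length(int_lin))
  class(tr) <- "phylo"
  tr$root.edge <- tab$end[1L] - tab$start[1L]
  attr(tr, "tip_fate") <- stats::setNames(tab$fate[tip_lin], tr$tip.label)
  tr
}

#' Flag extinct tips of a non-ultrametric tree
#'
#' A tip is extinct when its depth (root-to-tip path length) falls short of
#' the tree height by more than `tol` times the height.
#'
#' @param tree a `phylo` object.
#' @param tol relative tolerance on tip depth.
#' @return named logical vector over tips.
#' @export
is_extinct_tip <- function(tree, tol = 1e-8) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(ape::node.depth.edgelength(tree))
  stats::setNames(h - depth > tol * h, tree$tip.label)
}

#' Remove extinct lineages from a simulated tree
#'
#' Drops all extinct tips and collapses the resulting unary nodes, summing
#' branch lengths, so the returned tree is ultrametric over the extant tips.
#'
#' @inheritParams is_extinct_tip
#' @return a `phylo` with only extant tips.
#' @examples
#' tr <- simulate_birth_death(0.5, 0.2, n_tips = 20, seed = 3)
#' ex <- prune_extinct(tr)
#' ape::is.ultrametric(ex)
#' @export
prune_extinct <- function(tree, tol = 1e-8) {
  ext <- is_extinct_tip(tree, tol)
  if (sum(!ext) < 2L) stop("fewer than 2 extant tips; nothing to keep")
  if (!any(ext)) return(tree)
  ape::drop.tip(tree, tree$tip.label[ext])
}

#' Height of a tree (maximum root-to-node depth)
#' @param tree a `phylo` object.
#' @return numeric scalar in branch-length units.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}
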