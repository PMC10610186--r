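#' Patristic (cophenetic) distance matrix of a tree
#'
#' Pairwise tip-to-tip distances: the sum of branch lengths along the path
#' between two tips, computed as
#' `depth(i) + depth(j) - 2 * depth(mrca(i, j))`.  Works on binary and
#' multifurcating trees and does not require ultrametricity.
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric numeric matrix with zero diagonal, tip labels as
#'   dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  nt <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  dm <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  post <- ape::reorder.phylo(tree, "postorder")
  children <- split(post$edge[, 2L], post$edge[, 1L])
  tipsets <- vector("list", nt + tree$Nnode)
  tipsets[seq_len(nt)] <- as.list(seq_len(nt))
  # postorder over internal nodes: all pairs of tips whose MRCA is the node
  for (nd in unique(post$edge[, 1L])) {
    sets <- tipsets[children[[as.character(nd)]]]
    k <- length(sets)
    for (a in seq_len(k - 1L)) {
      for (b in seq(a + 1L, k)) {
        A <- sets[[a]]; B <- sets[[b]]
        block <- outer(depth[A], depth[B], `+`) - 2 * depth[nd]
        dm[A, B] <- block
        dm[B, A] <- t(block)
      }
    }
    tipsets[[nd]] <- unlist(sets, use.names = FALSE)
  }
  dm
}

#' Mean pairwise phylogenetic distance of a community
#'
#' The unweighted average of the patristic distance over all unordered
#' pairs of species in the community.
#'
#' @param community character vector of species (>= 2).
#' @param dm distance matrix from [cophenetic_matrix()].
#' @return numeric scalar in branch-length units.
#' @export
mpd <- function(community, dm) {
  if (length(community) < 2L) stop("a community needs at least 2 species")
  missing <- setdiff(community, rownames(dm))
  if (length(missing))
    stop("species absent from the distance matrix: ",
         paste(missing, collapse = ", "))
  k <- length(community)
  sum(dm[community, community]) / (k * (k - 1))
}

#' Standardized effect size of MPD against a richness-controlled null
#'
#' The null distribution is built by drawing `n_null` uniform random
#' subsets of the pool with the same richness as the observed community
#' (for presence-absence data this is the taxa-label shuffle restricted to
#' the pool).  `ses = (observed - null mean) / null SD`; positive values
#' mean the community is phylogenetically overdispersed relative to equally
#' rich random draws, negative values clustered.
#'
#' @param community character vector of species, a subset of `pool`.
#' @param dm distance matrix covering the pool.
#' @param pool character vector: the sampling universe for null draws.
#' @param n_null number of null draws (>= 99; default 999).
#' @param seed optional integer seed.
#' @return a list of class `mpd_ses`: `observed_mpd`, `null_mean`,
#'   `null_sd`, `ses`, `rank_p` (one-sided upper-tail rank p; the lower
#'   tail is `1 + n_null - rank_p * (n_null + 1)` ranks away),
#'   `n_null`, `richness`, `degenerate` (TRUE when the null has zero
#'   spread, in which case `ses` is defined as 0).
#' @export
mpd_ses <- function(community, dm, pool, n_null = 999, seed = NULL) {
  if (n_null < 99) stop("'n_null' must be at least 99")
  if (length(pool) < length(community))
    stop("pool is smaller than the community")
  if (!all(community %in% pool))
    stop("community contains species not in the pool")
  if (!is.null(seed)) set.seed(seed)
  pool_idx <- match(pool, rownames(dm))
  if (anyNA(pool_idx))
    stop("pool species absent from the distance matrix: ",
         paste(pool[is.na(pool_idx)], collapse = ", "))
  k <- length(community)
  obs <- mpd(community, dm)
  denom <- k * (k - 1)
  null <- numeric(n_null)
  for (b in seq_len(n_null)) {
    m <- sample(pool_idx, k)
    null[b] <- sum(dm[m, m]) / denom
  }
  mu <- mean(null); sd0 <- stats::sd(null)
  degenerate <- !is.finite(sd0) || sd0 == 0
  structure(list(observed_mpd = obs, null_mean = mu, null_sd = sd0,
                 ses = if (degenerate) 0 else (obs - mu) / sd0,
                 rank_p = (1 + sum(null >= obs)) / (n_null + 1),
                 n_null = as.integer(n_null), richness = k,
                 degenerate = degenerate),
            class = "mpd_ses")
}

#' Randomly resolve polytomies into a bifurcating tree
#'
#' Each multifurcation is replaced by a randomly chosen sequence of binary
#' splits; the inserted internal edges get zero length, so the tip set and
#' every pairwise patristic distance are preserved exactly.  Repeated calls
#' with different seeds give the pool of alternative resolutions used to
#' propagate polytomy uncertainty.
#'
#' @param tree a `phylo`, possibly with multifurcations.
#' @param seed optional integer seed.
#' @return a strictly bifurcating `phylo`.
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  # rooted-binary check: ape::is.binary() would call a 3-tip star
  # unrooted-binary and skip resolution
  if (tree$Nnode == ape::Ntip(tree) - 1L) return(tree)
  ape::multi2di(tree, random = TRUE)
}
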