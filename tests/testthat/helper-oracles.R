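# Independent brute-force oracles used across the suite.  These deliberately
# share no code with the package implementations they check.

# Patristic distance by walking each tip's path to the root and summing the
# unshared branch lengths.
oracle_cophenetic <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  parent <- integer(nn); elen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- nt + 1L
  path <- function(i) {
    out <- integer(0)
    while (i != root) { out <- c(out, i); i <- parent[i] }
    out
  }
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) {
    pi <- path(i)
    for (j in seq(i + 1, nt)) {
      pj <- path(j)
      shared <- intersect(pi, pj)
      d[i, j] <- d[j, i] <- sum(elen[setdiff(pi, shared)]) +
        sum(elen[setdiff(pj, shared)])
    }
  }
  d
}

# MPD as the literal mean over enumerated unordered pairs.
oracle_mpd <- function(comm, dm) {
  pairs <- utils::combn(comm, 2)
  mean(apply(pairs, 2, function(p) dm[p[1], p[2]]))
}

# Textbook simple-regression formulas from raw sums.
oracle_ols <- function(y, x) {
  n <- length(y)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  b <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  a <- (sy - b * sx) / n
  res <- y - a - b * x
  se <- sqrt(sum(res^2) / (n - 2) / (sxx - sx * sx / n))
  tv <- b / se
  list(slope = b, intercept = a, t = tv, f = tv^2,
       p = 2 * stats::pt(-abs(tv), n - 2))
}

# Pooled-variance two-sample t statistic.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Event-count simulator that mirrors bd_lineage_table's RNG draw order
# (rexp, runif, sample.int per event) but tracks only lineage counts, so a
# matched seed must reproduce the same extinct/extant tip counts.  Restarts
# on whole-clade extinction exactly like simulate_birth_death.
oracle_bd_counts <- function(lambda, mu, n_tips, retries = 100) {
  total <- lambda + mu
  p_birth <- lambda / total
  for (attempt in seq_len(retries + 1)) {
    alive <- 1L; extinct <- 0L
    repeat {
      if (alive >= n_tips)
        return(c(extant = alive, extinct = extinct))
      stats::rexp(1L, alive * total)
      is_birth <- stats::runif(1L) < p_birth
      sample.int(alive, 1L)
      if (is_birth) alive <- alive + 1L
      else { alive <- alive - 1L; extinct <- extinct + 1L }
      if (alive == 0L) break
    }
  }
  stop("oracle: clade extinct in all attempts")
}

# Expected number of CTMC state shifts on a tree: propagate the state
# distribution down the edges with the matrix exponential and integrate the
# exit rate numerically along each edge.
oracle_expected_shifts <- function(tree, Q, root_state, steps = 200) {
  codes <- rownames(Q)
  nt <- ape::Ntip(tree)
  pre <- ape::reorder.phylo(tree, "cladewise")
  p <- matrix(0, nt + tree$Nnode, 4)
  p[nt + 1L, match(root_state, codes)] <- 1
  exit <- -diag(Q)
  total <- 0
  for (e in seq_len(nrow(pre$edge))) {
    from <- pre$edge[e, 1L]; to <- pre$edge[e, 2L]
    len <- pre$edge.length[e]
    if (len > 0) {
      dt <- len / steps
      Pdt <- as.matrix(Matrix::expm(Q * dt))
      v <- p[from, ]
      for (s in seq_len(steps)) {
        total <- total + sum(v * exit) * dt
        v <- as.numeric(v %*% Pdt)
      }
      p[to, ] <- v
    } else {
      p[to, ] <- p[from, ]
    }
  }
  total
}

# Small ultrametric test tree.
balanced8 <- function() {
  ape::read.tree(text = paste0(
    "(((a:1,b:1):1,(c:1,d:1):1):2,((e:1,f:1):1,(g:1,h:1):1):2);"))
}
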