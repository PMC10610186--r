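test_that("cophenetic distances match geometry and two independent oracles", {
  two <- ape::read.tree(text = "(a:5,b:5);")
  expect_equal(cophenetic_matrix(two)["a", "b"], 10)

  bal <- balanced8()
  dm <- cophenetic_matrix(bal)
  h <- tree_height(bal)
  expect_true(all(dm <= 2 * h + 1e-12))
  expect_equal(dm["a", "e"], 2 * h)  # opposite sides of the root

  set.seed(8)
  for (i in 1:5) {
    tr <- ape::rtree(20)
    dm <- cophenetic_matrix(tr)
    expect_equal(dm, oracle_cophenetic(tr), tolerance = 1e-12)
    expect_equal(dm, ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)],
                 tolerance = 1e-12)
  }
  # multifurcations are handled
  poly <- ape::read.tree(text = "((a:1,b:1,c:2):1,(d:1,e:3):2);")
  expect_equal(cophenetic_matrix(poly), oracle_cophenetic(poly),
               tolerance = 1e-12)
  expect_error(cophenetic_matrix(ape::read.tree(text = "(a,b);")),
               "branch lengths")
})

test_that("mpd equals the brute-force pair mean", {
  dm <- matrix(c(0, 7, 7, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mpd(c("a", "b"), dm), 7)

  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3["a", "b"] <- d3["b", "a"] <- 4
  d3["a", "c"] <- d3["c", "a"] <- 6
  d3["b", "c"] <- d3["c", "b"] <- 8
  expect_equal(mpd(letters[1:3], d3), 6)

  expect_error(mpd("a", d3), "at least 2")
  expect_error(mpd(c("a", "zz"), d3), "zz")

  set.seed(99)
  for (i in 1:300) {
    tr <- ape::rtree(sample(5:25, 1))
    dm <- cophenetic_matrix(tr)
    comm <- sample(tr$tip.label, sample(2:ape::Ntip(tr), 1))
    expect_equal(mpd(comm, dm), oracle_mpd(comm, dm), tolerance = 1e-12)
  }
})

test_that("mpd_ses flags the degenerate null and is scale invariant", {
  tr <- ape::rtree(12)
  dm <- cophenetic_matrix(tr)
  pool <- tr$tip.label
  # community == pool: every null draw is the community itself
  s <- mpd_ses(pool, dm, pool, n_null = 99, seed = 1)
  expect_true(s$degenerate)
  expect_equal(s$ses, 0)
  # branch-length scale cancels in the z-score
  comm <- pool[1:5]
  s1 <- mpd_ses(comm, dm, pool, n_null = 199, seed = 7)
  s2 <- mpd_ses(comm, dm * 3.7, pool, n_null = 199, seed = 7)
  expect_equal(s1$ses, s2$ses, tolerance = 1e-10)
  expect_equal(s1$rank_p, s2$rank_p)
  expect_equal(s2$observed_mpd, 3.7 * s1$observed_mpd, tolerance = 1e-10)
  expect_error(mpd_ses(comm, dm, pool, n_null = 50), "99")
  expect_error(mpd_ses(c(comm, "nope"), dm, pool, n_null = 99))
  expect_error(mpd_ses(pool, dm, pool[1:3], n_null = 99), "smaller")
})

test_that("the most distant pair is detected as overdispersed", {
  set.seed(31)
  tr <- ape::rtree(10)
  dm <- cophenetic_matrix(tr)
  pairs <- utils::combn(tr$tip.label, 2)
  pair_mpd <- apply(pairs, 2, function(p) dm[p[1], p[2]])
  stopifnot(sum(pair_mpd == max(pair_mpd)) == 1)  # unique maximum
  best <- pairs[, which.max(pair_mpd)]
  s <- mpd_ses(best, dm, tr$tip.label, n_null = 999, seed = 5)
  expect_gt(s$ses, 0)
  expect_lte(s$rank_p, 0.05)
  # exhaustive enumeration of all 45 pairs gives the same z within MC error
  z_exact <- (max(pair_mpd) - mean(pair_mpd)) / stats::sd(pair_mpd)
  expect_equal(s$ses, z_exact, tolerance = 0.2)
})

test_that("random polytomy resolution preserves distances and is uniform", {
  bal <- balanced8()
  expect_identical(resolve_polytomies(bal, seed = 1), bal)

  poly <- ape::read.tree(text = "((a:1,b:1,c:1):1,d:2);")
  res <- resolve_polytomies(poly, seed = 2)
  expect_true(ape::is.binary(res))
  expect_equal(cophenetic_matrix(res)[rownames(cophenetic_matrix(poly)),
                                      colnames(cophenetic_matrix(poly))],
               cophenetic_matrix(poly), tolerance = 1e-12)

  tri <- ape::read.tree(text = "(a:1,b:1,c:1);")
  set.seed(77)
  picks <- replicate(3000, {
    r <- resolve_polytomies(tri)
    cherry_parent <- max(r$edge[, 1])
    kids <- r$edge[r$edge[, 1] == cherry_parent, 2]
    paste(sort(r$tip.label[kids]), collapse = "")
  })
  tab <- table(picks)
  expect_equal(length(tab), 3L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("observed MPD agrees with picante on shared communities", {
  set.seed(13)
  tr <- ape::rtree(40)
  dm <- cophenetic_matrix(tr)
  comm_mat <- matrix(0L, 5, 40, dimnames = list(paste0("c", 1:5),
                                                tr$tip.label))
  comms <- lapply(1:5, function(i) sample(tr$tip.label, 8))
  for (i in 1:5) comm_mat[i, comms[[i]]] <- 1L
  pic <- picante::mpd(comm_mat, dm)
  mine <- vapply(comms, mpd, numeric(1), dm = dm)
  expect_equal(mine, pic, tolerance = 1e-10)
  # ses against the same pool and null family (taxa shuffle), MC agreement
  pz <- picante::ses.mpd(comm_mat[1:2, ], dm,
                         null.model = "taxa.labels", runs = 999)
  mz <- mpd_ses(comms[[1]], dm, tr$tip.label, n_null = 999, seed = 3)
  expect_lt(abs(mz$ses - pz$mpd.obs.z[1]), 0.5)
})
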