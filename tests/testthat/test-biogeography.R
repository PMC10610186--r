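test_that("transition model encodes the allowed-move set exactly", {
  m <- build_transition_model("TNC", 0.1, 0.01)
  Q <- m$Q
  expect_equal(Q["TrL", "TrH"], 0.01)
  expect_equal(Q["TrL", "TeL"], 0.01)
  expect_equal(Q["TeL", "TeH"], 0.1)
  expect_equal(Q["TeH", "TrH"], 0.1)
  expect_equal(Q["TrH", "TeL"], 0)
  expect_equal(Q["TrL", "TeH"], 0)
  expect_equal(unname(rowSums(Q)), rep(0, 4))
  expect_true(all(Q[upper.tri(Q)] == t(Q)[upper.tri(Q)]))
  # scenarios share Q by construction
  expect_equal(build_transition_model("MZO", 0.1, 0.01)$Q, Q)
  expect_error(build_transition_model("TNC", 0.01, 0.1))
  expect_error(build_transition_model("TNC", -0.1, 0.01))
  # region tags are fixed
  rt <- region_table()
  expect_equal(rt$climate_class[rt$code == "TrL"], "warm_wet")
  expect_equal(sum(rt$climate_class == "cold_seasonal"), 3L)
})

test_that("zero dissimilar-climate rate makes climate classes absorbing", {
  tr <- prune_extinct(simulate_birth_death(0.5, 0.05, n_tips = 80, seed = 3))
  m <- build_transition_model("TNC", 0.1, 0)
  st <- simulate_regions(tr, m, root_state = "TrL", seed = 4)
  expect_true(all(st == "TrL"))
  expect_equal(attr(st, "n_events"), 0L)
  # from a TeL root the warm-wet class is unreachable
  st2 <- simulate_regions(tr, m, root_state = "TeL", seed = 5)
  expect_false(any(st2 == "TrL"))
})

test_that("single-edge state frequencies match the matrix exponential", {
  n <- 20000
  star <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
               edge.length = rep(3, n),
               tip.label = paste0("t", seq_len(n)), Nnode = 1L)
  class(star) <- "phylo"
  m <- build_transition_model("TNC", 0.4, 0.04)
  st <- simulate_regions(star, m, root_state = "TrL", seed = 9)
  p <- as.numeric(Matrix::expm(m$Q * 3)[1, ])
  freq <- as.numeric(table(factor(st, levels = rownames(m$Q)))) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) <= 4 * pmax(se, 1e-12)))
})

test_that("total state-shift count matches the expm-integral oracle", {
  tr <- prune_extinct(simulate_birth_death(0.5, 0.05, n_tips = 80, seed = 21))
  m <- build_transition_model("TNC", 0.3, 0.03)
  expected <- oracle_expected_shifts(tr, m$Q, "TrL")
  set.seed(100)
  obs <- mean(replicate(300,
    attr(simulate_regions(tr, m, root_state = "TrL"), "n_events")))
  expect_lt(abs(obs - expected) / expected, 0.10)
})

test_that("MZO scenarios enforce the richness split and stay ultrametric", {
  sc <- build_scenario(scenario_config("MZO", n_tips = 40,
                                       rate_similar = 0.3,
                                       rate_dissimilar = 0.05), seed = 1)
  expect_equal(sum(sc$origin == "TrL"), 30L)
  expect_equal(sum(sc$origin == "TeL"), 10L)
  expect_equal(ape::Ntip(sc$tree), 40L)
  expect_true(ape::is.ultrametric(sc$tree, tol = 1e-9))
  expect_setequal(names(sc$states), sc$tree$tip.label)

  sc8 <- build_scenario(scenario_config("MZO", n_tips = 8,
                                        rate_similar = 0.3,
                                        rate_dissimilar = 0.05), seed = 2)
  expect_equal(as.integer(table(sc8$origin)[c("TrL", "TeL")]), c(6L, 2L))
  expect_error(scenario_config("MZO", n_tips = 7))

  tnc <- build_scenario(scenario_config("TNC", n_tips = 30,
                                        rate_similar = 0.3,
                                        rate_dissimilar = 0.05), seed = 3)
  expect_true(all(tnc$origin == "TrL"))
  expect_equal(ape::Ntip(tnc$tree), 30L)
})

test_that("MZO origin clades respect reachability under zero dissimilar rate", {
  cfg <- scenario_config("MZO", n_tips = 60, rate_similar = 0.3,
                         rate_dissimilar = 0)
  sc <- build_scenario(cfg, seed = 6)
  temp <- names(sc$origin)[sc$origin == "TeL"]
  trop <- names(sc$origin)[sc$origin == "TrL"]
  expect_false(any(sc$states[temp] == "TrL"))
  expect_true(all(sc$states[trop] == "TrL"))
})

test_that("root stem depth controls the divergence of the origin floras", {
  mk <- function(frac) {
    cfg <- scenario_config("MZO", n_tips = 40, rate_similar = 0.3,
                           rate_dissimilar = 0.05, root_stem_frac = frac)
    build_scenario(cfg, seed = 11)$tree
  }
  t0 <- mk(0); t1 <- mk(0.5)
  expect_true(ape::is.ultrametric(t1, tol = 1e-9))
  expect_equal(tree_height(t1), tree_height(t0) * 1.5, tolerance = 1e-9)
})
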