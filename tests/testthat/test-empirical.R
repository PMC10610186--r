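# Small in-code fixtures ------------------------------------------------------

toy_tree <- function() {
  ape::read.tree(text = paste0(
    "(((SpA:1,SpB:1):1,(SpC:1,SpD:1):1):2,((SpE:1,SpF:1):1,",
    "(GenG:1,FamH:1):1):2);"))
}

toy_inventory <- function() {
  stems <- data.frame(
    plot_id = c("p1", "p1", "p1", "p2", "p2", "p2", "p3", "p3", "p3", "p3"),
    taxon = c("SpA", "SpA", "SpB", "SpC", "SpD", "SpE", "SpF", "GenG",
              NA, "SpA"),
    rank = c(rep("species", 7), "genus", "unidentified", "species"),
    dbh_cm = c(12, 15, 30, 11, 22, 40, 18, 25, 13, 9),
    stringsAsFactors = FALSE)
  meta <- data.frame(
    plot_id = c("p1", "p2", "p3"),
    lat = c(-1.2, -12.5, -26.8), lon = c(-78, -71, -65),
    elev_m = c(300, 1500, 2900), area_ha = c(1, 0.5, 0.25),
    mat_c = c(23, 17, 9), map_mm = c(2400, 1600, 900),
    stringsAsFactors = FALSE)
  list(stems = stems, meta = meta)
}

test_that("inventory loading validates structure and referential integrity", {
  inv <- toy_inventory()
  sf <- tempfile(fileext = ".csv"); mf <- tempfile(fileext = ".csv")
  utils::write.csv(inv$stems, sf, row.names = FALSE)
  utils::write.csv(inv$meta, mf, row.names = FALSE)
  got <- load_inventory(sf, mf)
  expect_equal(nrow(got$stems), nrow(inv$stems))
  expect_equal(nrow(got$meta), 3L)

  bad <- inv$stems
  bad$plot_id[1] <- "p99"
  expect_error(validate_inventory(bad, inv$meta), "p99")
  expect_error(validate_inventory(inv$stems[, -1], inv$meta), "plot_id")
  meta_dup <- rbind(inv$meta, inv$meta[1, ])
  expect_error(validate_inventory(inv$stems, meta_dup), "duplicated")
  meta_na <- inv$meta; meta_na$mat_c[2] <- NA
  expect_error(validate_inventory(inv$stems, meta_na), "mat_c")
  bad_rank <- inv$stems; bad_rank$rank[1] <- "subspecies"
  expect_error(validate_inventory(bad_rank, inv$meta), "rank")
})

test_that("stem filters drop unidentified and small stems with full accounting", {
  inv <- toy_inventory()
  f <- filter_stems(inv$stems)
  expect_equal(f$report$n_input, 10L)
  expect_equal(f$report$n_unidentified, 1L)
  expect_equal(f$report$n_small_dbh, 1L)
  expect_equal(f$report$n_kept, 8L)
  expect_equal(nrow(f$kept), 8L)
  expect_equal(f$report$retained_fraction, 0.8)
  # identity on already-clean data
  clean <- f$kept
  expect_identical(filter_stems(clean)$kept, clean)
})

test_that("plot communities are binary, matched to the tree, and pruned", {
  inv <- toy_inventory()
  kept <- filter_stems(inv$stems)$kept
  kept$taxon[kept$taxon == "SpF"] <- "NotInTree"
  pc <- plot_communities(kept, toy_tree())
  # p1 has SpA (x2) and SpB -> one row with both present once
  expect_equal(unname(pc$comm["p1", c("SpA", "SpB")]), c(1L, 1L))
  expect_equal(sum(pc$comm["p1", ]), 2)
  # p3 retains only SpA after dropping the unmatched stem -> excluded
  expect_true("p3" %in% pc$excluded_plots)
  expect_false("p3" %in% rownames(pc$comm))
  expect_true("NotInTree" %in% names(pc$unmatched))
})

test_that("residualization is orthogonal to area and recovers an area effect", {
  set.seed(4)
  area <- sample(c(0.25, 0.5, 1), 60, replace = TRUE)
  ses <- 2 - 1.5 * area + rnorm(60, 0, 0.1)
  r <- residualize(ses, area)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_equal(sum(r * (area - mean(area))), 0, tolerance = 1e-10)
  fit <- attr(r, "area_fit")
  expect_lt(fit$slope, 0)
  expect_equal(fit$slope, -1.5, tolerance = 0.3)
  expect_warning(r0 <- residualize(ses, rep(1, 60)), "does not vary")
  expect_equal(as.numeric(r0), ses - mean(ses))
})

test_that("gradient fits report raw and standardized slopes consistently", {
  set.seed(6)
  elev <- runif(100, 150, 3500)
  y <- 0.001 * elev + rnorm(100, 0, 0.5)
  g <- empirical_gradient(y, elev, "elevation")
  expect_equal(g$slope_std, stats::cor(y, elev), tolerance = 1e-10)
  expect_equal(g$slope_raw, ols_fit(y, elev)$slope, tolerance = 1e-12)
  expect_lt(g$p, 0.05)
  # shuffling the predictor destroys the association
  g0 <- empirical_gradient(y, sample(elev), "elevation")
  expect_gt(g0$p, 0.05)
  expect_lt(abs(g0$slope_std), 0.15)
  expect_error(empirical_gradient(y[1:5], elev[1:5]), "at least 10")
})

test_that("vessel model matches the pooled-t oracle and recovers offsets", {
  # fixed 12-row table
  tab <- data.frame(
    species = paste0("v", 1:12),
    height_m = c(4, 7, 11, 18, 26, 39, 5, 8, 13, 19, 28, 41),
    vessel_um = c(32, 45, 58, 70, 85, 101, 24, 33, 41, 52, 60, 74),
    origin = rep(c("tropical", "temperate"), each = 6),
    stringsAsFactors = FALSE)
  expect_error(vessel_model(tab), "at least 10")
  tab2 <- rbind(tab, transform(tab, species = paste0("w", 1:12)))
  vm <- vessel_model(tab2)
  pooled <- stats::lm(log10(vessel_um) ~ log10(height_m), tab2)
  res <- stats::residuals(pooled)
  t_oracle <- oracle_pooled_t(res[tab2$origin == "tropical"],
                              res[tab2$origin == "temperate"])
  expect_equal(vm$resid_t, t_oracle, tolerance = 1e-10)
  expect_lt(vm$origin_effect, 0)

  v0 <- generate_vessels(100, origin_offset_log10 = 0, seed = 8)
  vm0 <- vessel_model(v0$records)
  expect_gt(vm0$origin_p, 0.05)
  v1 <- generate_vessels(100, origin_offset_log10 = -0.1, seed = 8)
  vm1 <- vessel_model(v1$records)
  expect_lt(vm1$origin_effect, 0)
  expect_lt(vm1$origin_p, 0.001)
  expect_error(vessel_model(v1$records[v1$records$origin == "tropical", ]),
               "both")
})

test_that("the empirical pipeline is deterministic end to end", {
  cfg <- network_config(n_plots = 25, stems_per_ha = 150,
                        tree_config = scenario_config("MZO", n_tips = 200))
  net <- generate_network(cfg, seed = 3)
  r1 <- empirical_pipeline(net$stems, net$meta, net$tree, n_null = 99,
                           seed = 10)
  r2 <- empirical_pipeline(net$stems, net$meta, net$tree, n_null = 99,
                           seed = 10)
  expect_identical(r1$gradients, r2$gradients)
  expect_equal(nrow(r1$plots), 25L)
  expect_equal(mean(r1$plots$resid), 0, tolerance = 1e-10)
  # MAT decreases with elevation by construction, so the two slopes oppose
  expect_lt(r1$gradients$mat$slope_std * r1$gradients$elevation$slope_std, 0)
})
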