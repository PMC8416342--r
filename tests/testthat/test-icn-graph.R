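test_that("z-scoring standardizes against cohort moments", {
  m <- matrix(c(1, 2, 3, 3, 2, 1, 0, 4, 2), 3, 3)
  colnames(m) <- c("a", "b", "c")
  z <- zscore_items(m)
  expect_equal(unname(z[, "a"]), (m[, 1] - 2) / 1, tolerance = 1e-12)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-8)

  # two-pass oracle agreement
  set.seed(3)
  x <- matrix(rnorm(200), 20, 10)
  z2 <- zscore_items(x)
  for (j in 1:10) {
    mu <- sum(x[, j]) / 20
    s <- sqrt(sum((x[, j] - mu)^2) / 19)
    expect_equal(unname(z2[, j]), (x[, j] - mu) / s, tolerance = 1e-12)
  }

  const <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(zscore_items(const), "b")
})

test_that("ICN weights follow the Gaussian-similarity closed form", {
  expect_equal(icn_weights(c(1.3, 1.3))[1, 2], 1)
  expect_equal(icn_weights(c(0, 1))[1, 2], exp(-1), tolerance = 1e-12)
  w <- icn_weights(c(0, 1, -1))
  expect_equal(w[lower.tri(w)], c(exp(-1), exp(-1), exp(-4)),
               tolerance = 1e-12)
  expect_true(isSymmetric(w))
  expect_true(all(w > 0 & w <= 1))
  # monotone decreasing in |za - zb|; invariant to common shifts
  gaps <- seq(0, 3, by = 0.1)
  vals <- vapply(gaps, function(g) icn_weights(c(0, g))[1, 2], numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(icn_weights(c(0.4, 1.1) + 5)[1, 2],
               icn_weights(c(0.4, 1.1))[1, 2], tolerance = 1e-12)
})

test_that("proportional thresholding retains exactly round(K * pairs) edges", {
  set.seed(9)
  z <- rnorm(43)
  w <- icn_weights(z)
  for (K in c(0.05, 0.1, 0.14, 0.2)) {
    adj <- proportional_threshold(w, K)
    expect_equal(sum(adj) / 2, round(K * 903))
    expect_true(isSymmetric(adj))
    expect_equal(unname(diag(adj)), rep(0L, 43))
  }
  expect_equal(attr(proportional_threshold(w, 0.14), "n_edges"), 126L)
  expect_equal(sum(proportional_threshold(w, 1)) / 2, 903)

  # the retained set is the top-k of a full sort when weights are distinct
  adj <- proportional_threshold(w, 0.1)
  ij <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(w[ij], decreasing = TRUE)
  top <- ij[ord[1:round(0.1 * 903)], ]
  expect_equal(sort(adj[top]), rep(1L, nrow(top)))

  expect_error(proportional_threshold(icn_weights(rnorm(3)), 0.05),
               "zero edges")
})

test_that("betweenness ranks match closed forms and the path-enumeration oracle", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  res <- rank_betweenness(star)
  expect_equal(unname(res$betweenness), c(6, 0, 0, 0, 0))
  expect_equal(unname(res$rank), c(1L, 2L, 2L, 2L, 2L))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(unname(rank_betweenness(path)$betweenness), c(0, 1, 0))
  expect_equal(unname(rank_betweenness(path)$rank)[2], 1L)

  for (s in 1:30) {
    adj <- random_adjacency(sample(6:12, 1), prob = 0.3, seed = 40 + s)
    expect_equal(unname(rank_betweenness(adj)$betweenness),
                 oracle_betweenness(adj), tolerance = 1e-9)
  }
})

test_that("graph screening reports connectedness, small-worldness and modularity", {
  full <- matrix(1, 10, 10) - diag(10)
  scr <- graph_screen(full, n_null = 3, seed = 1)
  expect_equal(scr$connectedness, 1)
  expect_equal(scr$C, 1)

  # two disjoint cliques of 21 and 22 nodes
  adj <- matrix(0, 43, 43)
  adj[1:21, 1:21] <- 1
  adj[22:43, 22:43] <- 1
  diag(adj) <- 0
  scr <- graph_screen(adj, n_null = 3, seed = 2)
  expect_equal(scr$connectedness, 22 / 43, tolerance = 1e-12)
  membership <- rep(1:2, c(21, 22))
  expect_equal(oracle_modularity(adj, membership), scr$Q, tolerance = 0.02)
  expect_gt(scr$Q, 0.3)

  # Watts-Strogatz regime: ring lattice with a few shortcuts is small-world
  g <- igraph::sample_smallworld(1, 40, 3, p = 0.05)
  ws <- as.matrix(igraph::as_adjacency_matrix(g))
  scr <- graph_screen(ws, n_null = 10, seed = 3)
  expect_true(scr$sigma_defined)
  expect_gt(scr$sigma, 1)
})

test_that("sparsity selection returns the sparsest qualifying K", {
  z <- quantile_spread_z(25, seed = 5)
  sel <- select_sparsity(z, k_grid = c(0.14, 0.18),
                         n_null = 5, seed = 1)
  expect_equal(sel$K, 0.14)   # grid minimum when every K qualifies
  expect_true(all(sel$pass_rates$pass_rate > 0.95))

  # constructed cohort whose pass rate first exceeds 95% at K = 0.14:
  # most respondents have screen-stable profiles, two are iid-noise
  # profiles that only connect at denser K
  set.seed(6)
  zc <- rbind(quantile_spread_z(28, seed = 7),
              matrix(rnorm(2 * 43), 2, 43))
  colnames(zc) <- item_schema()$item
  sel2 <- select_sparsity(zc, k_grid = c(0.10, 0.14, 0.18),
                          participant_fraction = 0.9, n_null = 5, seed = 2)
  expect_true(sel2$K >= 0.14)

  expect_error(
    select_sparsity(rbind(quantile_spread_z(5, seed = 8)),
                    k_grid = c(0.1), participant_fraction = 1,
                    n_null = 3, seed = 1),
    "no grid sparsity")
})

test_that("hub identification applies rank and prevalence thresholds", {
  # constructed: item 1 at rank 1 for 60% of respondents
  ranks <- matrix(10L, 20, 43)
  colnames(ranks) <- item_schema()$item
  ranks[1:12, 1] <- 1L
  hubs <- identify_hubs(ranks, hub_criteria("results"))
  expect_true(hubs$hub[hubs$item == "att1"])
  expect_equal(sum(hubs$hub), 1L)
  expect_equal(hubs$prevalence[1], 0.6)

  # presets carry the published thresholds
  expect_equal(hub_criteria("results")$rank_threshold, 4L)
  expect_equal(hub_criteria("results")$prevalence_threshold, 0.40)
  expect_equal(hub_criteria("figure")$rank_threshold, 5L)
  expect_equal(hub_criteria("figure")$prevalence_threshold, 0.25)

  # exchangeable null: no hub in a modest batch of shuffled-rank cohorts
  false_hits <- 0
  for (s in 1:40) {
    z <- null_z_cohort(60, seed = 700 + s)
    pr <- icn_profiles(z, 0.14)
    if (any(identify_hubs(pr$rank)$hub)) false_hits <- false_hits + 1
  }
  expect_equal(false_hits, 0)
})

test_that("a planted hub is recovered as the top-prevalence item", {
  pool <- matrix(0, 8, 43)
  for (s in 1:8) {
    cfg <- plant_hub_item(icn_block_config(seed = 7000 + s), "phq5", 1)
    z <- zscore_items(generate_cohort(cfg))
    pool[s, ] <- colMeans(icn_profiles(z, 0.14)$rank <= 4)
  }
  colnames(pool) <- item_schema()$item
  pooled <- colMeans(pool)
  # enriched well beyond the exchangeable-null expectation of 4/43
  expect_gt(pooled["phq5"], 1.5 * 4 / 43)
  # and among the very top items cohort-over-cohort
  expect_lte(rank(-pooled)[["phq5"]], 4)
})

test_that("two planted hubs both beat random decoy items", {
  decoys <- c("pss2", "phq7", "gad2", "att5", "st_read")
  pool <- matrix(0, 8, 43)
  for (s in 1:8) {
    cfg <- icn_block_config(seed = 8000 + s)
    cfg <- plant_hub_item(cfg, "phq5", 1, c("pss", "phq9"))
    cfg <- plant_hub_item(cfg, "gad4", 1, c("gad7", "attitude"))
    z <- zscore_items(generate_cohort(cfg))
    pool[s, ] <- colMeans(icn_profiles(z, 0.14)$rank <= 4)
  }
  colnames(pool) <- item_schema()$item
  pooled <- colMeans(pool)
  expect_gt(pooled["phq5"], max(pooled[decoys]))
  expect_gt(pooled["gad4"], max(pooled[decoys]))
})

test_that("centrality associations match the rank-correlation oracle", {
  x <- 1:10
  y <- c(2, 4, 6, 7, 9, 11, 12, 15, 17, 20)
  ranks <- cbind(item1 = x)
  totals <- data.frame(pss_total = y)
  res <- centrality_association(ranks, totals)
  expect_equal(res$rho, 1)
  res_rev <- centrality_association(cbind(item1 = rev(x)), totals)
  expect_equal(res_rev$rho, -1)

  set.seed(15)
  xr <- sample(1:43, 10, replace = TRUE)
  yr <- rnorm(10)
  res <- centrality_association(cbind(item1 = xr),
                                data.frame(gad7_total = yr))
  expect_equal(res$rho, oracle_spearman(xr, yr), tolerance = 1e-12)

  res0 <- centrality_association(cbind(item1 = rep(3, 10)),
                                 data.frame(pss_total = yr))
  expect_false(res0$defined)
  expect_true(is.na(res0$rho))
})

test_that("the ICN study front end is deterministic end to end", {
  cohort <- generate_cohort(simulation_config(n_per_grade = rep(12L, 4),
                                              seed = 33))
  fit1 <- icn_study(cohort, K = 0.14, n_null = 3, seed = 4)
  fit2 <- icn_study(cohort, K = 0.14, n_null = 3, seed = 4)
  expect_identical(fit1$hubs, fit2$hubs)
  expect_identical(fit1$associations, fit2$associations)
  expect_equal(fit1$K, 0.14)
  expect_s3_class(fit1, "icn_study")
})
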