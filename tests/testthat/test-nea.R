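test_that("cross-link counting enumerates qualifying edges once, symmetrically", {
  path <- path_net()
  expect_equal(cross_link_count(path, c("A", "C"), c("B", "D")), 3L)
  expect_equal(cross_link_count(path, "A", "D"), 0L)
  expect_equal(cross_link_count(path, character(), c("A", "B")), 0L)

  # edges inside the A/F intersection count once; A = F counts internal edges
  tri <- triangle_net()
  expect_equal(cross_link_count(tri, c("A", "B", "C"), c("A", "B", "C")), 3L)
  expect_equal(cross_link_count(tri, c("A", "B"), c("B", "C")), 3L)

  set.seed(11)
  net <- simulate_network(150, 5, seed = 11)
  for (i in 1:5) {
    a <- sample(net$nodes, 20)
    f <- sample(net$nodes, 25)
    expect_equal(cross_link_count(net, a, f), cross_link_count(net, f, a))
    expect_equal(
      cross_link_count(net, a, f),
      count_cross_oracle(net$edges, match(a, net$nodes), match(f, net$nodes))
    )
  }
})

test_that("null moments match exhaustive enumeration on a small graph", {
  # rigid triangle: rewiring cannot change the edge set
  tri <- triangle_net()
  n_obs <- cross_link_count(tri, c("A", "B"), "C")
  nm <- suppressWarnings(null_moments(tri, c("A", "B"), "C",
                                      n_perm = 20, seed = 1))
  expect_equal(nm$sigma_null, 0)
  expect_equal(nm$mu_null, n_obs)

  # path degree sequence: 7 enumerable realizations; a chain run for a
  # fixed number of successful swaps is a random walk on the swap graph,
  # so exact moments weight each realization by its move count
  start_idx <- cbind(1:4, 2:5)
  nodes <- LETTERS[1:5]
  a_idx <- 1:2
  f_idx <- 3:4
  exact <- exact_null_oracle(start_idx, a_idx, f_idx)
  expect_equal(exact$n_states, 7L)

  start <- gene_network(cbind(nodes[start_idx[, 1L]],
                              nodes[start_idx[, 2L]]))
  nm2 <- null_moments(start, nodes[a_idx], nodes[f_idx],
                      n_perm = 2000, seed = 5, swap_factor = 5)
  expect_lt(abs(nm2$mu_null - exact$mu) / exact$mu, 0.05)
  expect_lt(abs(nm2$sigma_null - exact$sigma) / exact$sigma, 0.05)

  # deterministic given seed
  nm3 <- null_moments(start, nodes[a_idx], nodes[f_idx],
                      n_perm = 50, seed = 9)
  nm4 <- null_moments(start, nodes[a_idx], nodes[f_idx],
                      n_perm = 50, seed = 9)
  expect_identical(nm3$counts, nm4$counts)
})

test_that("z-scores and normal p-values follow their definitions", {
  expect_equal(z_score(10, 10, 2), 0)
  expect_equal(z_score(30, 10, 5), 4)
  expect_equal(z_score(10, 30, 5), -4)
  expect_true(is.na(z_score(5, 3, 0)))
  expect_equal(z_score(3, 3, 0), 0)
  expect_error(z_score(1, 1, -1), class = "crosslink_usage_error")

  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(1.959964), 0.05, tolerance = 1e-6)
  z <- c(-2.3, 0.4, 1.7)
  expect_equal(z_to_p(z), z_to_p(-z))
})

test_that("gene-level NEA requires both the link minimum and significance", {
  net <- gene_network(rbind(c("hub", "m1"), c("hub", "m2"), c("hub", "m3"),
                            c("hub", "m4"), c("m1", "m2"), c("m3", "m5"),
                            c("m5", "m6"), c("m6", "m7")),
                      nodes = "isolated")
  ags <- gene_set("ags", paste0("m", 1:7), source = "ags")

  iso <- suppressWarnings(
    gene_level_nea(net, "isolated", ags, n_perm = 10, seed = 2)
  )
  expect_equal(iso$link_count, 0L)
  expect_false(iso$passes)
  expect_true("small_set" %in% iso$flags)

  hub <- suppressWarnings(gene_level_nea(net, "hub", ags, n_perm = 20, seed = 2))
  expect_equal(hub$link_count, 4L)

  # conjunction: min_links = 0 still requires p < 0.05
  m2 <- suppressWarnings(
    gene_level_nea(net, "m2", ags, min_links = 0, n_perm = 20, seed = 3)
  )
  if (!is.na(m2$p) && m2$p >= 0.05) expect_false(m2$passes)

  expect_error(gene_level_nea(net, "absent", ags),
               class = "crosslink_usage_error")
})

test_that("run_nea covers all pairs with flags, symmetry and reproducible output", {
  net <- simulate_network(300, 6, seed = 21)
  set.seed(22)
  S <- sample(net$nodes, 25)
  fgs <- fgs_catalog(list(
    gene_set("same_as_ags", S),
    gene_set("other", sample(net$nodes, 30)),
    gene_set("tiny", sample(net$nodes, 3)),
    gene_set("outside", c("zz1", "zz2", "zz3", "zz4", "zz5"))
  ))
  cfg <- run_config(seed = 23, n_perm = 20, fdr_mode = "bh")
  res <- run_nea(net, gene_set("ags", S, source = "ags"), fgs, cfg)
  expect_equal(nrow(res), 4L)

  # A = F: observed count is the number of edges within S
  internal <- sum(net$edges[, 1L] %in% match(S, net$nodes) &
                    net$edges[, 2L] %in% match(S, net$nodes))
  expect_equal(res$n_obs[res$fgs_id == "same_as_ags"], internal)

  expect_match(res$flags[res$fgs_id == "tiny"], "small_set")
  out_row <- res[res$fgs_id == "outside", ]
  expect_match(out_row$flags, "no_coverage")
  expect_equal(out_row$n_obs, 0L)

  # direction mirrors the sign of z
  ok <- !is.na(res$z) & res$z != 0
  expect_equal(res$direction[ok], ifelse(res$z[ok] > 0, "enriched", "depleted"))

  # byte-identical output on rerun with the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  res2 <- run_nea(net, gene_set("ags", S, source = "ags"), fgs, cfg)
  write.table(as.data.frame(res), f1); write.table(as.data.frame(res2), f2)
  expect_identical(readLines(f1), readLines(f2))

  # symmetry of the observed count under swapping AGS and FGS roles
  other <- fgs$other$members
  res_fwd <- run_nea(net, gene_set("a", S, source = "ags"),
                     fgs_catalog(list(gene_set("f", other))), cfg)
  res_rev <- run_nea(net, gene_set("a", other, source = "ags"),
                     fgs_catalog(list(gene_set("f", S))), cfg)
  expect_equal(res_fwd$n_obs, res_rev$n_obs)

  expect_error(run_nea(net, list(), fgs, cfg), class = "crosslink_usage_error")
  expect_error(run_nea(net, gene_set("a", S), fgs_catalog(list()), cfg),
               class = "crosslink_usage_error")
})

test_that("adding cross-edges increases the observed count and expected Z", {
  net <- simulate_network(300, 6, seed = 31)
  set.seed(32)
  A <- sample(net$nodes, 25)
  F1 <- sample(net$nodes, 30)
  n0 <- cross_link_count(net, A, F1)
  pl <- plant_enrichment(net, A, F1, 15, seed = 33)
  expect_equal(cross_link_count(pl$network, A, F1), n0 + 15L)

  z_before <- mean(vapply(1:3, function(s) {
    nm <- null_moments(net, A, F1, n_perm = 30, seed = s)
    z_score(n0, nm$mu_null, nm$sigma_null)
  }, 1))
  z_after <- mean(vapply(1:3, function(s) {
    nm <- null_moments(pl$network, A, F1, n_perm = 30, seed = s)
    z_score(n0 + 15L, nm$mu_null, nm$sigma_null)
  }, 1))
  expect_gt(z_after, z_before)
})

test_that("empirical FDR saturates at 1 and matches degree profiles", {
  net <- simulate_network(400, 8, seed = 41)
  set.seed(42)
  ags <- gene_set("ags", sample(net$nodes, 30), source = "ags")
  fgs <- make_catalog(5, 20, 40, net$nodes, seed = 43)
  cfg <- run_config(seed = 44, n_perm = 20)
  ef <- empirical_fdr(net, ags, fgs, z_threshold = 0, n_random = 10,
                      seed = 44, config = cfg)
  expect_equal(ef$fdr, 1)  # every test passes threshold 0 in both arms
  expect_equal(dim(ef$random_z), c(10L, 5L))

  # degree matching: random sets reproduce the AGS's per-bin counts
  deg <- network_degrees(net)
  br <- unique(quantile(deg, probs = seq(0, 1, length.out = 6)))
  bin <- cut(deg, br, include.lowest = TRUE, labels = FALSE)
  ags_bins <- table(bin[match(ags$members, net$nodes)])
  rs <- crosslink:::.sample_degree_matched(net, ags$members, 5, 5L)
  for (r in rs) {
    expect_length(r, length(ags$members))
    expect_equal(table(bin[match(r, net$nodes)]), ags_bins)
  }

  # real count of zero at an unreachable threshold gives NA
  ef_hi <- empirical_fdr(net, ags, fgs, z_threshold = 99, n_random = 10,
                         seed = 45, config = cfg)
  expect_true(is.na(ef_hi$fdr))
})
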