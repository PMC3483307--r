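test_that("signed fold change follows the +r / -1/r convention", {
  expect_equal(signed_fold_change(2, 2), 1)
  expect_equal(signed_fold_change(4, 2), 2)
  expect_equal(signed_fold_change(2, 4), -2)
  expect_error(signed_fold_change(0, 1), class = "crosslink_usage_error")

  # never in (-1, 1); swapping arguments flips the sign (antisymmetry)
  set.seed(1)
  a <- runif(200, 0.1, 10)
  b <- runif(200, 0.1, 10)
  fc <- signed_fold_change(a, b)
  expect_true(all(abs(fc) >= 1))
  rev_fc <- signed_fold_change(b, a)
  nontrivial <- abs(rev_fc) > 1
  expect_equal(fc[nontrivial], -rev_fc[nontrivial])
})

test_that("paired t-test matches the closed form and flags degeneracies", {
  same <- paired_t(c(3, 5, 7), c(3, 5, 7), log2_transform = FALSE)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p, 1)

  # differences (1, 3, 1): t = 2.5 on 2 df
  r <- paired_t(c(1, 3, 1), c(0, 0, 0), log2_transform = FALSE)
  expect_equal(r$t_stat, 2.5)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2.5, df = 2))

  zv <- paired_t(c(2, 2, 2), c(0, 0, 0), log2_transform = FALSE)
  expect_true(zv$zero_variance)
  expect_equal(zv$p, 1e-12)
})

test_that("BH q-values equal an independent step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "crosslink_usage_error")

  set.seed(3)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(bh_fdr(p), bh_oracle(p))
    perm <- sample.int(50)
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  }
})

test_that("the DE table agrees with per-gene t.test and ranks deterministically", {
  sim <- simulate_expression(60, seed = 4)
  tab <- de_table(sim$expr)
  expect_setequal(tab$gene, rownames(sim$expr$values))
  case_idx <- which(sim$expr$condition == "case")
  ctrl_idx <- which(sim$expr$condition == "control")
  for (g in sample(tab$gene, 8)) {
    ref <- paired_t(sim$expr$values[g, case_idx],
                    sim$expr$values[g, ctrl_idx])
    row <- tab[tab$gene == g, ]
    expect_equal(row$t, ref$t_stat, tolerance = 1e-12)
    expect_equal(row$p, ref$p, tolerance = 1e-12)
    expect_equal(row$fc, signed_fold_change(
      mean(sim$expr$values[g, case_idx]),
      mean(sim$expr$values[g, ctrl_idx])
    ))
  }
  expect_equal(tab$q, bh_oracle(tab$p), tolerance = 1e-12)
  # sorted by q, ties by |fc| then symbol
  expect_true(all(diff(tab$q) >= 0))
})

test_that("AGS selection applies top-N tie-breaks and threshold filters", {
  toy <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    fc = c(2, 9, 3, 8, 2), t = 1, p = c(.001, .01, .01, .2, .5),
    q = c(.001, .01, .01, .2, .5), zero_variance = FALSE,
    stringsAsFactors = FALSE
  )
  toy <- toy[order(toy$q, -abs(toy$fc), toy$gene), ]
  class(toy) <- c("de_table", "data.frame")
  top3 <- select_ags(toy, "top_n", n = 3)
  expect_equal(top3$members, c("g1", "g2", "g3"))
  expect_equal(top3$source, "ags")

  expect_warning(all_of <- select_ags(toy, "top_n", n = 10), "exceeds")
  expect_length(all_of$members, 5L)

  thr_tab <- data.frame(
    gene = c("a", "b", "c"), fc = c(1.4, -1.6, 2.0), t = 1,
    p = c(.01, .01, .2), q = c(.01, .01, .2), zero_variance = FALSE,
    stringsAsFactors = FALSE
  )
  class(thr_tab) <- c("de_table", "data.frame")
  sel <- select_ags(thr_tab, "threshold", fc_cut = 1.5, q_cut = 0.05)
  expect_equal(sel$members, "b")
})

test_that("concordance labels split the published 14-gene table 4/2/8", {
  labelled <- classify_concordance(concordant_pairs())
  counts <- table(labelled$concordance)
  expect_equal(unname(counts["tracking"]), 4L)
  expect_equal(unname(counts["anti_tracking"]), 2L)
  expect_equal(unname(counts["same_direction"]), 8L)
  expect_setequal(labelled$gene[labelled$concordance == "tracking"],
                  c("ETS1", "TNFSF18", "CLIP4", "FBLN5"))
  expect_setequal(labelled$gene[labelled$concordance == "anti_tracking"],
                  c("LRRC7", "WDR54"))

  expect_equal(
    as.character(classify_concordance(
      data.frame(gene = "x", fc_over = 2, fc_sil = 2)
    )$concordance), "same_direction")
  expect_equal(
    as.character(classify_concordance(
      data.frame(gene = "ETS1", fc_over = 3.9, fc_sil = -1.5)
    )$concordance), "tracking")
  expect_error(classify_concordance(
    data.frame(gene = "x", fc_over = 0.5, fc_sil = 2)
  ), class = "crosslink_usage_error")
})

test_that("delta-delta-Ct fold changes follow 2^(-ddct) with the signed convention", {
  expect_equal(ddct_fold_change(5, 5, 5, 5), 1)
  expect_equal(ddct_fold_change(5, 6, 5, 5), 2)   # ddct = -1
  expect_equal(ddct_fold_change(6, 5, 5, 5), -2)  # ddct = +1
  expect_error(ddct_fold_change(NA, 1, 1, 1), class = "crosslink_usage_error")
})

test_that("expression matrices and DE tables round-trip through their writers", {
  sim <- simulate_expression(25, seed = 6)
  f <- withr::local_tempfile()
  write_expression(sim$expr, f, header = "roundtrip")
  back <- read_expression(f)
  expect_equal(back$values, sim$expr$values, tolerance = 1e-9)
  expect_equal(back$condition, sim$expr$condition)
  expect_equal(back$pair, sim$expr$pair)

  tab <- de_table(sim$expr)
  g <- withr::local_tempfile()
  write_de_table(tab, g)
  back_tab <- read_de_table(g)
  expect_equal(back_tab$gene, tab$gene)
  expect_equal(back_tab$q, tab$q, tolerance = 1e-9)
})
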