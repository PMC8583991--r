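mk_de <- function(ids, fdr, lfc = -1) {
  n <- length(ids)
  out <- data.frame(feature_id = ids, base_mean = 100,
                    lfc = rep_len(lfc, n), se = 0.1, wald = -5,
                    p_value = rep_len(fdr, n), fdr = rep_len(fdr, n),
                    tested = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

test_that("candidate pairs are restricted to DE features and deduplicated", {
  de_m <- mk_de(c("m1", "m2", "m3", "m4"), fdr = c(0.01, 0.01, 0.01, 0.2))
  de_g <- mk_de(c("g1", "g2", "g3", "g4", "g5"),
                fdr = c(0.01, 0.01, 0.01, 0.01, 0.2))
  db <- target_pair_db(data.frame(
    mirna = c("m1", "m1", "m2", "m2", "m3", "m4"),
    gene = c("g1", "g2", "g2", "g5", "g3", "g4"),
    source = c("pred_db1", "pred_db1", "pred_db1", "pred_db1",
               "val_db1", "pred_db1"),
    evidence = c("predicted", "predicted", "predicted", "predicted",
                 "validated", "predicted")))
  cand <- candidate_pairs(de_m, de_g, db)
  # m2-g5 drops (g5 not DE), m4-g4 drops (m4 not DE)
  expect_equal(nrow(cand), 4)
  expect_true(cand$validated[cand$mirna == "m3"])

  # same pair in a predicted and a validated source merges with union provenance
  db2 <- target_pair_db(data.frame(
    mirna = c("m1", "m1"), gene = c("g1", "g1"),
    source = c("pred_db1", "val_db2"),
    evidence = c("predicted", "validated")))
  cand2 <- candidate_pairs(de_m, de_g, db2)
  expect_equal(nrow(cand2), 1)
  expect_true(cand2$validated)
  expect_equal(cand2$sources, "pred_db1;val_db2")

  expect_warning(out <- candidate_pairs(mk_de("m9", 0.9), de_g, db),
                 "no differentially expressed")
  expect_equal(nrow(out), 0)
})

test_that("edge admission uses strict thresholds on both r and p", {
  # orthonormal construction: sample correlation equals rho exactly
  n <- 12
  set.seed(2)
  x <- scale(rnorm(n))[, 1]
  e <- scale(stats::residuals(lm(rnorm(n) ~ x)))[, 1]
  rho <- -0.8
  y <- rho * x + sqrt(1 - rho^2) * e
  r_obs <- pearson_with_p(x, y)$r
  expect_equal(r_obs, rho, tolerance = 1e-12)

  rl_m <- matrix(x, 1, n, dimnames = list("m1", sprintf("s%02d", 1:n)))
  rl_g <- matrix(y, 1, n, dimnames = list("g1", sprintf("s%02d", 1:n)))
  cand <- data.frame(mirna = "m1", gene = "g1", validated = FALSE,
                     sources = "pred_db1")
  # strictly below its own r: rejected; epsilon above: admitted
  expect_equal(nrow(build_network(cand, rl_m, rl_g,
                                  r_threshold = r_obs)$edges), 0)
  expect_equal(nrow(build_network(cand, rl_m, rl_g,
                                  r_threshold = r_obs + 1e-9)$edges), 1)

  # strong r but p above threshold at n = 4: both conditions required
  x4 <- scale(c(1, 2, 3, 7))[, 1]
  e4 <- scale(stats::residuals(lm(c(2, 1, 4, 3) ~ x4)))[, 1]
  y4 <- -0.9 * x4 + sqrt(1 - 0.81) * e4
  pp <- pearson_with_p(x4, y4)
  expect_equal(pp$r, -0.9, tolerance = 1e-12)
  expect_gt(pp$p, 0.05)
  rl_m4 <- matrix(x4, 1, 4, dimnames = list("m1", paste0("t", 1:4)))
  rl_g4 <- matrix(y4, 1, 4, dimnames = list("g1", paste0("t", 1:4)))
  expect_equal(nrow(build_network(cand, rl_m4, rl_g4)$edges), 0)
  expect_error(build_network(cand, rl_m4[, 1:2, drop = FALSE], rl_g4),
               "3 samples")
})

test_that("admitted edges reproduce their stored statistics from the matrices", {
  cfg <- small_sim_config(n_control = 8, n_case = 8, seed = 31)
  sim <- simulate_dataset(cfg)
  db <- simulate_target_db(sim$truth, cfg)
  de_m <- nb_wald_de(sim$mirna)
  de_g <- nb_wald_de(sim$mrna)
  rl_m <- rlog_like(sim$mirna)
  rl_g <- rlog_like(sim$mrna)
  nw <- build_network(candidate_pairs(de_m, de_g, db), rl_m, rl_g,
                      de_mirna = de_m, de_gene = de_g)
  expect_gt(nrow(nw$edges), 0)
  for (i in seq_len(nrow(nw$edges))) {
    ct <- pearson_with_p(rl_m[nw$edges$mirna[i], ], rl_g[nw$edges$gene[i], ])
    expect_equal(nw$edges$pearson_r[i], ct$r, tolerance = 1e-10)
    expect_equal(nw$edges$p_value[i], ct$p, tolerance = 1e-10)
    expect_lt(nw$edges$pearson_r[i], -0.7)
    expect_lt(nw$edges$p_value[i], 0.05)
  }
  # bipartite with every node in >= 1 edge
  expect_setequal(nw$mirnas$id, unique(nw$edges$mirna))
  expect_setequal(nw$genes$id, unique(nw$edges$gene))
})

test_that("under independence few pairs pass the anticorrelation filter", {
  set.seed(43)
  n <- 12
  xm <- matrix(rnorm(40 * n), 40, n,
               dimnames = list(paste0("m", 1:40), paste0("s", 1:n)))
  xg <- matrix(rnorm(40 * n), 40, n,
               dimnames = list(paste0("g", 1:40), paste0("s", 1:n)))
  pass <- replicate(300, {
    a <- xm[sample(40, 1), ]; b <- xg[sample(40, 1), ]
    ct <- pearson_with_p(a, b)
    ct$r < -0.7 && ct$p < 0.05
  })
  expect_lte(mean(pass), 0.02)
})

test_that("network summary reports targeted-percentage by DE direction", {
  de_g <- mk_de(paste0("g", 1:10),
                fdr = c(rep(0.01, 8), 0.5, 0.5),
                lfc = c(rep(-1, 5), rep(1, 3), -1, 1))
  # targets: 2 of 5 down-DE genes, 1 of 3 up-DE genes
  nw <- toy_network(c("g1", "g2", "g6"), c("m1", "m1", "m2"), r = -0.8)
  s <- network_summary(nw, de_g)
  expect_equal(s$n_edges, 3)
  expect_equal(s$pct_down_de_targeted, 40)
  expect_equal(s$pct_up_de_targeted, 33)
  s0 <- network_summary(mirna_target_network(data.frame()), de_g)
  expect_equal(s0$pct_down_de_targeted, 0)
})

test_that("degree-correlation comparison matches exhaustive rank-sum enumeration", {
  # 6 transcripts: 3 multi-target, 3 single-target, hand-listed correlations
  nw <- toy_network(
    gene = c("g1", "g1", "g2", "g2", "g3", "g3", "g4", "g5", "g6"),
    mirna = c("m1", "m2", "m1", "m3", "m2", "m3", "m1", "m2", "m3"),
    r = c(-0.9, -0.8, -0.85, -0.95, -0.75, -0.85, -0.72, -0.74, -0.78))
  res <- degree_correlation_test(nw)
  expect_equal(res$n_multi, 3)
  expect_equal(res$n_single, 3)
  per_gene <- c(g1 = -0.85, g2 = -0.9, g3 = -0.8)
  singles <- c(g4 = -0.72, g5 = -0.74, g6 = -0.78)
  expect_equal(res$median_multi, median(per_gene))
  expect_equal(res$mwu_p, enum_mwu_p(per_gene, singles), tolerance = 1e-12)

  # identical correlation multisets in both classes -> p = 1
  nw2 <- toy_network(
    gene = c("a", "a", "b", "b", "c", "d"),
    mirna = c("m1", "m2", "m1", "m2", "m3", "m3"),
    r = c(-0.8, -0.8, -0.9, -0.9, -0.8, -0.9))
  res2 <- degree_correlation_test(nw2)
  expect_equal(res2$mwu_p, 1)

  # one class empty -> missing statistics
  nw3 <- toy_network(c("a", "b"), c("m1", "m2"), r = c(-0.8, -0.9))
  res3 <- degree_correlation_test(nw3)
  expect_equal(res3$n_multi, 0)
  expect_true(is.na(res3$mwu_p))
  expect_true(is.na(res3$median_multi))
})

test_that("target prioritization tiers follow degree and validation", {
  nw <- toy_network(
    gene = c("g1", "g1", "g2", "g2", "g3"),
    mirna = c("m1", "m2", "m1", "m3", "m2"),
    r = -0.8, validated = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  res <- prioritize_targets(nw)
  expect_setequal(res$tier_a, c("g1", "g2"))  # degree >= 2
  expect_setequal(res$tier_b, "g1")           # validated evidence
  expect_equal(res$percent_validated, 50)
  # g3: single validated edge -> neither tier
  expect_false("g3" %in% res$tier_a)
})

test_that("prioritized-list overlap induces the right subnetwork", {
  nw <- toy_network(
    gene = c("g1", "g2", "g3", "g3"),
    mirna = c("m1", "m2", "m1", "m3"),
    r = -0.8)
  expressed <- paste0("g", 1:10)
  res <- overlap_prioritized_genes(nw, c("g3", "g8", "zzz"), expressed)
  expect_equal(res$n_list, 3)
  expect_equal(res$n_expressed, 2)
  expect_equal(res$n_in_network, 1)
  expect_equal(nrow(res$subnetwork$edges), 2)
  expect_setequal(res$subnetwork$mirnas$id, c("m1", "m3"))

  res0 <- overlap_prioritized_genes(nw, c("x", "y"), expressed)
  expect_equal(res0$n_in_network, 0)
  expect_equal(nrow(res0$subnetwork$edges), 0)

  res_all <- overlap_prioritized_genes(nw, paste0("g", 1:3), expressed)
  expect_equal(res_all$n_in_network, 3)
})
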