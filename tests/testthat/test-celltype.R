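mk_atlas <- function() {
  set.seed(2)
  mat <- matrix(rnorm(2 * 30, 0, 0.1), 2, 30,
                dimnames = list(c("epithelial", "T_cell"),
                                sprintf("miR-%02d", 1:30)))
  mat[1, 1:10] <- 3 + seq(0.10, 0.01, length.out = 10)
  mat[2, 11:20] <- 3 + seq(0.10, 0.01, length.out = 10)
  cell_type_atlas(mat)
}

test_that("signature extraction takes the top-k with documented tie handling", {
  atlas <- mk_atlas()
  sigs <- extract_signatures(atlas, k = 10)
  expect_setequal(sigs$epithelial, sprintf("miR-%02d", 1:10))
  expect_setequal(sigs$T_cell, sprintf("miR-%02d", 11:20))
  expect_equal(sigs$epithelial[1], "miR-01")  # dominant miRNA ranks first
  expect_error(extract_signatures(atlas, "B_cell"), "unknown cell type")
  expect_warning(all_m <- extract_signatures(atlas, "epithelial", k = 99),
                 "exceeds atlas width")
  expect_length(all_m$epithelial, 30)

  # exact tie at the cut: lexicographic winner kept, message emitted
  tied <- atlas
  tied[1, ] <- 0
  tied[1, c("miR-03", "miR-01", "miR-02")] <- 1
  expect_message(s <- extract_signatures(cell_type_atlas(tied),
                                         "epithelial", k = 2),
                 "tie at rank")
  expect_equal(s$epithelial, c("miR-01", "miR-02"))
})

test_that("running-sum score equals the hand-evaluated maximum deviation", {
  expr <- matrix(c(5, 4, 3, 2, 1), 5, 1,
                 dimnames = list(paste0("f", 1:5), "s1"))
  # set {f1, f3}, tau = 0: deviations 1/2, 1/6, 2/3, 1/3, 0 -> max 2/3
  sc <- ss_enrichment(expr, c("f1", "f3"), tau = 0)
  expect_equal(unname(sc), 2 / 3, tolerance = 1e-12)
  # set {f4, f5} at the very bottom: complete separation, deviation -1
  sc2 <- ss_enrichment(expr, c("f4", "f5"), tau = 0)
  expect_equal(unname(sc2), -1, tolerance = 1e-12)
  expect_error(ss_enrichment(expr, c("x", "y")), "no feature")
  expect_error(ss_enrichment(expr, paste0("f", 1:5)), "full feature set")
})

test_that("scores order samples by signature placement and use ranks only", {
  set.seed(4)
  expr <- matrix(rnorm(100 * 6), 100, 6,
                 dimnames = list(paste0("f", 1:100), paste0("s", 1:6)))
  sig <- paste0("f", 1:10)
  expr[sig, "s1"] <- expr[sig, "s1"] + 10  # signature at the top in s1
  expr[sig, "s2"] <- expr[sig, "s2"] - 10  # and at the bottom in s2
  sc <- ss_enrichment(expr, sig)
  expect_gt(sc["s1"], 0)
  expect_lt(sc["s2"], 0)
  expect_gt(sc["s1"], max(sc[3:6]))
  # invariance to monotone within-sample transforms
  expect_equal(ss_enrichment(exp(expr / 4), sig), sc, tolerance = 1e-12)
  # uniformly increasing in-set expression never decreases the score
  expr2 <- expr
  expr2[sig, "s3"] <- expr2[sig, "s3"] + 1
  sc2 <- ss_enrichment(expr2, sig)
  expect_gte(sc2["s3"], sc["s3"])
})

test_that("signature score matrix keeps sample and signature labels", {
  set.seed(6)
  expr <- matrix(rnorm(50 * 4), 50, 4,
                 dimnames = list(paste0("f", 1:50), paste0("s", 1:4)))
  sigs <- list(a = paste0("f", 1:5), b = paste0("f", 6:12))
  sc <- signature_scores(expr, sigs)
  expect_equal(dim(sc), c(4, 2))
  expect_equal(rownames(sc), colnames(expr))
  expect_equal(sc[, "a"], ss_enrichment(expr, sigs$a))
})

test_that("case/control composition shift moves the signature scores as planted", {
  cfg <- sim_config(n_control = 20, n_case = 20, seed = 1)
  sim <- simulate_dataset(cfg)
  fx <- simulate_fixtures(sim$truth, cfg)
  sigs <- extract_signatures(fx$atlas, c("epithelial", "T_cell"), k = 10)
  sc <- signature_scores(rlog_like(sim$mirna), sigs)
  gt <- score_group_test(sc, sim$mirna$metadata)
  epi <- gt[gt$signature == "epithelial", ]
  tcell <- gt[gt$signature == "T_cell", ]
  expect_lt(epi$median_case, epi$median_control)
  expect_lt(epi$mwu_p, 0.05)
  expect_gt(tcell$median_case, tcell$median_control)
  expect_lt(tcell$mwu_p, 0.05)
})

test_that("group test is symmetric for exchangeable scores", {
  sc <- matrix(rep(c(0.1, 0.4, 0.2, 0.8), 2), 8, 1,
               dimnames = list(paste0("s", 1:8), "sig"))
  meta <- data.frame(status = rep(c("control", "case"), each = 4),
                     row.names = paste0("s", 1:8))
  res <- score_group_test(sc, meta)
  expect_equal(res$mwu_p, 1)
})

test_that("miRNA-score correlations recover planted cell-type specificity", {
  cfg <- sim_config(n_control = 15, n_case = 15, seed = 8)
  sim <- simulate_dataset(cfg)
  fx <- simulate_fixtures(sim$truth, cfg)
  sigs <- extract_signatures(fx$atlas, c("epithelial", "T_cell"), k = 10)
  rl <- rlog_like(sim$mirna)
  sc <- signature_scores(rl, sigs)
  cm <- mirna_score_correlation(rl, sc)
  epi_markers <- sim$truth$markers_mirna$epithelial
  expect_gt(mean(cm[epi_markers, "epithelial"]), 0.3)
  expect_lt(mean(cm[epi_markers, "T_cell"]), 0)
  # constant vector is skipped with a message, not an error
  rl2 <- rbind(rl, const = rep(1, ncol(rl)))
  expect_message(cm2 <- mirna_score_correlation(rl2, sc), "constant")
  expect_true(all(is.na(cm2["const", ])))
})

test_that("LFC-atlas correlation handles identity and degenerate inputs", {
  atlas <- mk_atlas()
  ids <- colnames(atlas)
  de <- data.frame(feature_id = ids, base_mean = 10,
                   lfc = as.numeric(atlas["T_cell", ]), se = 0.1, wald = 1,
                   p_value = 0.5, fdr = 0.5, tested = TRUE)
  class(de) <- c("de_table", "data.frame")
  res <- lfc_atlas_correlation(de, atlas, "T_cell")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$n, 30)
  flat <- atlas
  flat["T_cell", ] <- 5
  expect_error(lfc_atlas_correlation(de, cell_type_atlas(flat), "T_cell"),
               "constant")
  expect_error(lfc_atlas_correlation(de[1:2, ], atlas, "T_cell"),
               "fewer than 3")
})

test_that("composition-driven significance is removed by score correction", {
  lost <- kept <- logical(3)
  for (i in 1:3) {
    cfg <- sim_config(n_control = 20, n_case = 20, n_mirna = 60, n_gene = 60,
                      n_true_pairs = 10, seed = 300 + i)
    sim <- simulate_dataset(cfg)
    fx <- simulate_fixtures(sim$truth, cfg)
    de0 <- nb_wald_de(sim$mirna)
    sigs <- extract_signatures(fx$atlas, c("epithelial", "T_cell"), k = 10)
    sc <- signature_scores(rlog_like(sim$mirna), sigs)
    res <- corrected_de(sim$mirna, sc, baseline = de0)
    markers <- unlist(sim$truth$markers_mirna)
    sig_markers <- intersect(markers, res$previously_significant)
    lost[i] <- length(sig_markers) > 0 && all(sig_markers %in% res$lost)
    direct <- intersect(setdiff(sim$truth$de_mirna$mirna, markers),
                        res$previously_significant)
    kept[i] <- length(direct) > 0 && all(direct %in% res$retained)
  }
  expect_gte(sum(lost), 2)
  expect_gte(sum(kept), 2)
})

test_that("constant or collinear score columns are rejected by name", {
  ds <- raw_nb_dataset(10, 6, seed = 5)
  sc <- matrix(1, ncol(ds$counts), 1,
               dimnames = list(colnames(ds$counts), "flat"))
  expect_error(corrected_de(ds, sc), "collinear score column")
  set.seed(9)
  v <- rnorm(ncol(ds$counts))
  sc2 <- cbind(a = v, b = 2 * v)
  rownames(sc2) <- colnames(ds$counts)
  expect_error(corrected_de(ds, sc2), "collinear")
  expect_error(corrected_de(ds, sc2[1:3, , drop = FALSE]),
               "missing for samples")
})
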