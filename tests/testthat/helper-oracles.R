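# Independent brute-force oracles used across test files. These deliberately
# re-derive each quantity from its definition, not from the package's code
# path.

# BH step-up by the literal definition: q_i = min over j with p_j >= p_i of
# m * p_j / rank_j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[j] / rk[j]))
  }, numeric(1))
}

# Upper-tail hypergeometric p by exhaustive enumeration of all C(N, n) draws.
enum_hyper_p <- function(k, K, n, N) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(N, n)
  overlaps <- colSums(matrix(draws %in% inset, nrow = n))
  mean(overlaps >= k)
}

# Two-sided Mann-Whitney p by an independent enumeration over index subsets
# (works with ties; distinct code path from mwu_test's rank-multiset walk).
enum_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  mu <- n1 * length(y) / 2
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(length(pooled), n1)
  us <- apply(subsets, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Small simulated expression_dataset built directly from NB draws (bypasses
# the package's generator) for DE-level checks.
raw_nb_dataset <- function(n_feat, n_per_group, lfc = 0, dispersion = 0.1,
                           mu_range = c(50, 300), seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  status <- rep(c("control", "case"), each = n_per_group)
  mu0 <- exp(stats::runif(n_feat, log(mu_range[1]), log(mu_range[2])))
  lfc <- rep_len(lfc, n_feat)
  mu <- outer(mu0, rep(1, n))
  mu[, status == "case"] <- mu[, status == "case"] * 2^lfc
  cnts <- matrix(stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu),
                 n_feat, n)
  rownames(cnts) <- sprintf("g%04d", seq_len(n_feat))
  colnames(cnts) <- sprintf("s%03d", seq_len(n))
  meta <- data.frame(status = status,
                     age = round(stats::runif(n, 2, 17), 1),
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     row.names = colnames(cnts))
  expression_dataset(cnts, meta)
}

# Small configuration used where full default sizes are unnecessary.
small_sim_config <- function(...) {
  defaults <- list(n_control = 8, n_case = 8, n_mirna = 30, n_gene = 60,
                   n_true_pairs = 6, n_marker_mirna = 4, n_marker_gene = 4,
                   seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Construct a toy network directly from a minimal edge description. Extra
# arguments (mirnas =, genes =, ...) pass through to mirna_target_network().
toy_network <- function(gene, mirna, r, validated = FALSE, p = 1e-3, ...) {
  edges <- data.frame(mirna = mirna, gene = gene, pearson_r = r,
                      p_value = p, n_samples = 11L,
                      validated = rep_len(validated, length(gene)),
                      sources = "pred_db1", stringsAsFactors = FALSE)
  mirna_target_network(edges, ...)
}
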