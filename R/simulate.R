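#' Configuration for the paired-count simulator
#'
#' Defines the generative model for paired miRNA/mRNA count data with
#' planted structure. Each sample draws cell-type proportions from a
#' status-specific Dirichlet; each feature's latent log2 mean is the
#' composition-weighted mix of its per-cell-type baselines plus a direct
#' status effect (for planted differentially expressed features). For each
#' planted regulatory pair (m, g), gene g's latent log2 mean in sample s is
#' reduced by `repression_slope * (x_ms - mean_s(x_ms))`, where `x_ms` is
#' the miRNA's latent log2 abundance. Counts are negative-binomial draws
#' around `libsize * 2^latent`.
#'
#' Cases draw from a Dirichlet with lower epithelial and higher T-cell
#' concentration than controls by default, so part of the observed
#' differential expression of cell-type marker miRNAs is composition-driven
#' confounding rather than direct regulation.
#'
#' @param n_control,n_case Samples per group.
#' @param n_mirna,n_gene Features per layer.
#' @param n_true_pairs Number of planted repressive (miRNA, gene) pairs;
#'   pair miRNAs ("regulators") carry direct status effects of alternating
#'   sign, target genes carry none (their DE is induced by the repression).
#' @param repression_slope Decrease in target-gene log2 mean per unit of
#'   centered miRNA latent log2 abundance.
#' @param dispersion Negative-binomial overdispersion alpha (> 0);
#'   `Var = mu + alpha * mu^2`.
#' @param libsize_log_sd SD of per-sample log-normal library-size factors.
#' @param cell_types Cell-type names; the first two are treated as the
#'   marker-bearing compartments by default.
#' @param composition_shift Named list with elements `control` and `case`,
#'   each a positive Dirichlet concentration vector named by `cell_types`.
#' @param marker_cell_types Cell types that receive dedicated marker
#'   features.
#' @param n_marker_mirna,n_marker_gene Marker features per marker cell type.
#' @param marker_delta Log2 baseline elevation of a marker feature in its
#'   own cell type.
#' @param profile_sd SD of the small per-cell-type baseline deviations of
#'   non-marker features.
#' @param de_fraction_mirna,de_fraction_gene Fraction of additional
#'   (non-regulator, non-marker) features given a direct status effect.
#' @param effect_size_mirna,effect_size_gene Magnitude (log2) of direct
#'   status effects; signs alternate so both directions are planted.
#' @param predicted_sensitivity,validated_sensitivity Probability that a
#'   true pair is listed in each prediction / validated database.
#' @param decoy_rate Decoy (non-true) pairs added to the database pool per
#'   true pair.
#' @param n_rna Optional named vector `c(control = , case = )` subsampling
#'   the mRNA layer to mimic designs where only a subset of samples has
#'   RNA-seq; `NULL` keeps all samples.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_control = 10, n_case = 10,
                       n_mirna = 100, n_gene = 500,
                       n_true_pairs = 40,
                       repression_slope = 1.5,
                       dispersion = 0.05,
                       libsize_log_sd = 0.2,
                       cell_types = c("epithelial", "T_cell", "other"),
                       composition_shift = list(
                         control = c(epithelial = 6, T_cell = 2, other = 2),
                         case = c(epithelial = 4, T_cell = 4, other = 2)),
                       marker_cell_types = c("epithelial", "T_cell"),
                       n_marker_mirna = 10, n_marker_gene = 10,
                       marker_delta = 3,
                       profile_sd = 0.3,
                       de_fraction_mirna = 0.1, de_fraction_gene = 0.1,
                       effect_size_mirna = 1.5, effect_size_gene = 0.8,
                       predicted_sensitivity = 0.9,
                       validated_sensitivity = 0.5,
                       decoy_rate = 4,
                       n_rna = NULL,
                       seed = 1) {
  cfg <- list(n_control = n_control, n_case = n_case, n_mirna = n_mirna,
              n_gene = n_gene, n_true_pairs = n_true_pairs,
              repression_slope = repression_slope, dispersion = dispersion,
              libsize_log_sd = libsize_log_sd, cell_types = cell_types,
              composition_shift = composition_shift,
              marker_cell_types = marker_cell_types,
              n_marker_mirna = n_marker_mirna, n_marker_gene = n_marker_gene,
              marker_delta = marker_delta, profile_sd = profile_sd,
              de_fraction_mirna = de_fraction_mirna,
              de_fraction_gene = de_fraction_gene,
              effect_size_mirna = effect_size_mirna,
              effect_size_gene = effect_size_gene,
              predicted_sensitivity = predicted_sensitivity,
              validated_sensitivity = validated_sensitivity,
              decoy_rate = decoy_rate, n_rna = n_rna, seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_control, n_case, n_mirna, n_gene) < 1))
      stop("sample and feature counts must be >= 1")
    if (n_true_pairs < 0 || n_true_pairs > n_gene)
      stop("n_true_pairs must be between 0 and n_gene")
    if (dispersion <= 0) stop("dispersion must be > 0")
    if (libsize_log_sd < 0) stop("libsize_log_sd must be >= 0")
    if (!all(c("control", "case") %in% names(composition_shift)))
      stop("composition_shift needs elements 'control' and 'case'")
    for (st in c("control", "case")) {
      conc <- composition_shift[[st]]
      unknown <- setdiff(names(conc), cell_types)
      if (length(unknown))
        stop("unknown cell type in composition_shift: ",
             paste(unknown, collapse = ", "))
      if (!all(cell_types %in% names(conc)) || any(conc <= 0))
        stop("each concentration vector must cover all cell types with ",
             "positive values")
    }
    if (!all(marker_cell_types %in% cell_types))
      stop("marker_cell_types must be a subset of cell_types")
    probs <- c(de_fraction_mirna, de_fraction_gene,
               predicted_sensitivity, validated_sensitivity)
    if (any(probs < 0 | probs > 1))
      stop("fractions and sensitivities must lie in [0, 1]")
    if (decoy_rate < 0) stop("decoy_rate must be >= 0")
  })
  structure(cfg, class = "sim_config")
}

rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc)
  g / sum(g)
}

#' Simulate a paired miRNA/mRNA dataset with planted ground truth
#'
#' Draws sample metadata (status; age ~ Uniform(2, 17) years; sex ~
#' Bernoulli(0.5), emulating a pediatric biopsy cohort), per-sample
#' cell-type compositions, latent feature abundances with planted direct
#' and repressive effects, and negative-binomial counts for both layers.
#' See [sim_config()] for the generative model.
#'
#' @param config A [sim_config()].
#' @return List with elements `mirna` and `mrna` (each an
#'   [expression_dataset()]) and `truth`, a `sim_truth` list containing
#'   `true_pairs` (mirna, gene, slope), `de_mirna` / `de_gene` (features
#'   with *direct* status effects and their directions; repression-induced
#'   gene DE is implied by `true_pairs`), `composition` (sample x cell-type
#'   proportions), marker feature ids per cell type, the latent log2
#'   matrices, and the feature id universes.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_control; nk <- config$n_case
  ns <- nc + nk
  cts <- config$cell_types
  status <- factor(rep(c("control", "case"), c(nc, nk)),
                   levels = c("control", "case"))
  sample_ids <- sprintf("S%03d", seq_len(ns))
  age <- round(stats::runif(ns, 2, 17), 1)
  sex <- factor(sample(c("F", "M"), ns, replace = TRUE), levels = c("F", "M"))

  comp <- t(vapply(seq_len(ns), function(i) {
    conc <- config$composition_shift[[as.character(status[i])]][cts]
    rdirichlet1(conc)
  }, numeric(length(cts))))
  dimnames(comp) <- list(sample_ids, cts)

  mirna_ids <- sprintf("miR-%03d", seq_len(config$n_mirna))
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_gene))

  draw_layer_baselines <- function(ids, lo, hi, n_marker) {
    b0 <- stats::runif(length(ids), lo, hi)
    dev <- matrix(stats::rnorm(length(ids) * length(cts), 0, config$profile_sd),
                  length(ids), length(cts), dimnames = list(ids, cts))
    markers <- list()
    pool <- ids
    for (ct in config$marker_cell_types) {
      k <- min(n_marker, length(pool))
      mk <- sample(pool, k)
      dev[mk, ] <- 0
      dev[mk, ct] <- config$marker_delta
      markers[[ct]] <- mk
      pool <- setdiff(pool, mk)
    }
    list(b0 = stats::setNames(b0, ids), dev = dev, markers = markers)
  }
  bm <- draw_layer_baselines(mirna_ids, 4, 9, config$n_marker_mirna)
  bg <- draw_layer_baselines(gene_ids, 3, 8, config$n_marker_gene)
  marker_m <- unlist(bm$markers, use.names = FALSE)
  marker_g <- unlist(bg$markers, use.names = FALSE)

  # roles: regulators (pair miRNAs, direct effects), extra direct-DE features
  alt_signs <- function(n) rep(c(1, -1), length.out = n)
  pool_m <- setdiff(mirna_ids, marker_m)
  n_reg <- if (config$n_true_pairs > 0)
    min(max(1, ceiling(config$n_true_pairs / 2)), length(pool_m)) else 0
  regulators <- if (n_reg > 0) sample(pool_m, n_reg) else character(0)
  target_pool <- setdiff(gene_ids, marker_g)
  target_genes <- if (config$n_true_pairs > 0)
    sample(target_pool, config$n_true_pairs) else character(0)
  true_pairs <- data.frame(
    mirna = rep(regulators, length.out = config$n_true_pairs),
    gene = target_genes,
    slope = rep(config$repression_slope, config$n_true_pairs),
    stringsAsFactors = FALSE)

  eff_m <- stats::setNames(numeric(config$n_mirna), mirna_ids)
  eff_m[regulators] <- alt_signs(n_reg) * config$effect_size_mirna
  extra_pool_m <- setdiff(pool_m, regulators)
  n_extra_m <- min(round(config$de_fraction_mirna * config$n_mirna),
                   length(extra_pool_m))
  extra_m <- if (n_extra_m > 0) sample(extra_pool_m, n_extra_m) else character(0)
  eff_m[extra_m] <- alt_signs(n_extra_m) * config$effect_size_mirna

  eff_g <- stats::setNames(numeric(config$n_gene), gene_ids)
  pool_g <- setdiff(gene_ids, c(target_genes, marker_g))
  n_de_g <- min(round(config$de_fraction_gene * config$n_gene), length(pool_g))
  de_g <- if (n_de_g > 0) sample(pool_g, n_de_g) else character(0)
  eff_g[de_g] <- alt_signs(n_de_g) * config$effect_size_gene

  case_ind <- as.numeric(status == "case")
  latent_m <- bm$b0 + bm$dev %*% t(comp) + outer(eff_m, case_ind)
  latent_g <- bg$b0 + bg$dev %*% t(comp) + outer(eff_g, case_ind)
  if (nrow(true_pairs)) {
    for (i in seq_len(nrow(true_pairs))) {
      xm <- latent_m[true_pairs$mirna[i], ]
      latent_g[true_pairs$gene[i], ] <-
        latent_g[true_pairs$gene[i], ] - true_pairs$slope[i] * (xm - mean(xm))
    }
  }

  nb_counts <- function(latent, libsize) {
    mu <- sweep(2^latent, 2, libsize, "*")
    cnt <- matrix(stats::rnbinom(length(mu), size = 1 / config$dispersion,
                                 mu = mu),
                  nrow(mu), ncol(mu), dimnames = dimnames(mu))
    cnt
  }
  lib_m <- exp(stats::rnorm(ns, 0, config$libsize_log_sd))
  counts_m <- nb_counts(latent_m, lib_m)
  lib_g <- exp(stats::rnorm(ns, 0, config$libsize_log_sd))
  counts_g <- nb_counts(latent_g, lib_g)

  meta <- data.frame(status = status, age = age, sex = sex,
                     row.names = sample_ids)
  rna_samples <- sample_ids
  if (!is.null(config$n_rna)) {
    nr <- config$n_rna
    if (is.null(names(nr)) || !all(c("control", "case") %in% names(nr)))
      stop("n_rna must be a named vector c(control = , case = )")
    picks <- c(sample(sample_ids[status == "control"], nr[["control"]]),
               sample(sample_ids[status == "case"], nr[["case"]]))
    rna_samples <- sample_ids[sample_ids %in% picks]
  }

  truth <- structure(list(
    true_pairs = true_pairs,
    de_mirna = data.frame(mirna = names(eff_m)[eff_m != 0],
                          direction = ifelse(eff_m[eff_m != 0] > 0,
                                             "up", "down"),
                          effect = eff_m[eff_m != 0],
                          row.names = NULL, stringsAsFactors = FALSE),
    de_gene = data.frame(gene = names(eff_g)[eff_g != 0],
                         direction = ifelse(eff_g[eff_g != 0] > 0,
                                            "up", "down"),
                         effect = eff_g[eff_g != 0],
                         row.names = NULL, stringsAsFactors = FALSE),
    composition = comp,
    markers_mirna = bm$markers,
    markers_gene = bg$markers,
    regulators = regulators,
    latent_mirna = latent_m,
    latent_gene = latent_g,
    mirna_ids = mirna_ids,
    gene_ids = gene_ids,
    config = config), class = "sim_truth")

  list(mirna = expression_dataset(counts_m, meta),
       mrna = expression_dataset(counts_g[, rna_samples, drop = FALSE],
                                 meta[rna_samples, , drop = FALSE]),
       truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("sim_truth: %d planted pairs, %d direct-DE miRNAs, ",
                     "%d direct-DE genes, %d samples\n"),
              nrow(x$true_pairs), nrow(x$de_mirna), nrow(x$de_gene),
              nrow(x$composition)))
  invisible(x)
}

#' Simulate a candidate target-pair database matched to a ground truth
#'
#' Builds a four-source database (two prediction-style sources, two
#' experimentally-validated-style sources). Each true pair enters each
#' prediction source with probability `predicted_sensitivity` and each
#' validated source with probability `validated_sensitivity`. A pool of
#' `round(decoy_rate * n_true_pairs)` unique decoy (non-true) pairs enters
#' each source with the same class-specific probabilities.
#'
#' @param truth `sim_truth` from [simulate_dataset()].
#' @param config The same [sim_config()]; drawing is deterministic given
#'   its seed (a fixed offset of the dataset seed).
#' @return A [target_pair_db()].
#' @export
simulate_target_db <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  sources <- data.frame(
    source = c("pred_db1", "pred_db2", "val_db1", "val_db2"),
    evidence = c("predicted", "predicted", "validated", "validated"),
    sens = c(config$predicted_sensitivity, config$predicted_sensitivity,
             config$validated_sensitivity, config$validated_sensitivity),
    stringsAsFactors = FALSE)
  true_key <- paste(truth$true_pairs$mirna, truth$true_pairs$gene, sep = "\r")
  n_decoy <- round(config$decoy_rate * nrow(truth$true_pairs))
  decoys <- data.frame(mirna = character(0), gene = character(0))
  while (nrow(decoys) < n_decoy) {
    cand <- data.frame(
      mirna = sample(truth$mirna_ids, n_decoy * 2, replace = TRUE),
      gene = sample(truth$gene_ids, n_decoy * 2, replace = TRUE),
      stringsAsFactors = FALSE)
    cand <- cand[!paste(cand$mirna, cand$gene, sep = "\r") %in% true_key, ]
    decoys <- unique(rbind(decoys, cand))
  }
  decoys <- decoys[seq_len(n_decoy), , drop = FALSE]
  pool <- rbind(truth$true_pairs[, c("mirna", "gene")], decoys)
  rows <- lapply(seq_len(nrow(sources)), function(i) {
    keep <- stats::runif(nrow(pool)) < sources$sens[i]
    if (!any(keep)) return(NULL)
    data.frame(mirna = pool$mirna[keep], gene = pool$gene[keep],
               source = sources$source[i], evidence = sources$evidence[i],
               stringsAsFactors = FALSE)
  })
  db <- do.call(rbind, rows)
  if (is.null(db))
    db <- data.frame(mirna = character(0), gene = character(0),
                     source = character(0), evidence = character(0))
  target_pair_db(db)
}

#' Simulate gene sets, a cell-type miRNA atlas, and a prioritized gene list
#'
#' Produces the three annotation fixtures downstream stages consume:
#' a gene-set collection whose leading sets overlap the planted truth (one
#' metabolic-style set drawn from genes repressed in cases, one immune-style
#' set from genes elevated in cases, plus random background sets), a
#' cell-type x miRNA atlas whose enrichment values recover the simulated
#' cell-type baseline deviations (so each marker compartment's top-k list is
#' its planted markers, and marker compartments have disjoint top lists),
#' and a prioritized gene list drawn mostly from case-upregulated genes.
#'
#' @param truth `sim_truth` from [simulate_dataset()].
#' @param config The matching [sim_config()].
#' @param n_random_sets Number of random background gene sets (default 30).
#' @return List with `gene_sets` ([gene_set_collection()]), `atlas`
#'   ([cell_type_atlas()]), and `prioritized_genes` (character vector).
#' @export
simulate_fixtures <- function(truth, config, n_random_sets = 30) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 2000L)
  tp <- truth$true_pairs
  up_m <- truth$de_mirna$mirna[truth$de_mirna$direction == "up"]
  # repression: targets of case-up miRNAs fall in cases and vice versa
  case_down <- unique(c(tp$gene[tp$mirna %in% up_m],
                        truth$de_gene$gene[truth$de_gene$direction == "down"]))
  case_up <- unique(c(tp$gene[!tp$mirna %in% up_m],
                      truth$de_gene$gene[truth$de_gene$direction == "up"]))
  pad <- function(genes, n_min = 10) {
    if (length(genes) >= n_min) return(genes)
    unique(c(genes, sample(truth$gene_ids, n_min)))
  }
  sets <- list(
    fatty_acid_metabolic_process = pad(case_down),
    lymphocyte_activation = pad(case_up))
  for (i in seq_len(n_random_sets)) {
    sz <- sample(15:40, 1)
    sets[[sprintf("random_process_%02d", i)]] <- sample(truth$gene_ids, sz)
  }
  descr <- c("genes repressed in cases (planted)",
             "genes elevated in cases (planted)",
             rep("random background set", n_random_sets))
  gene_sets <- gene_set_collection(sets, descr)

  # atlas enrichment = planted marker elevation + small measurement noise
  atlas_mat <- matrix(0, length(config$cell_types), length(truth$mirna_ids),
                      dimnames = list(config$cell_types, truth$mirna_ids))
  for (ct in config$cell_types) {
    base <- numeric(length(truth$mirna_ids))
    names(base) <- truth$mirna_ids
    mk <- truth$markers_mirna[[ct]]
    if (!is.null(mk)) base[mk] <- config$marker_delta
    atlas_mat[ct, ] <- base + stats::rnorm(length(base), 0, 0.1)
  }
  atlas <- cell_type_atlas(atlas_mat)

  n_prio <- min(15, length(case_up))
  prioritized <- unique(c(sample(case_up, n_prio),
                          sample(truth$gene_ids, 5)))

  list(gene_sets = gene_sets, atlas = atlas,
       prioritized_genes = prioritized)
}

#' Score network edge recovery against planted truth
#'
#' Compares a built network's edge set with the planted (miRNA, gene) pairs.
#'
#' @param network A `mirna_target_network`.
#' @param truth `sim_truth` from [simulate_dataset()].
#' @return List: `precision` (NA when the network is empty), `recall`, `f1`,
#'   `tp`, `fp`, `fn`, and `tp_validated` / `fp_validated` counts of edges
#'   flagged as experimentally validated.
#' @export
evaluate_recovery <- function(network, truth) {
  stopifnot(inherits(network, "mirna_target_network"),
            inherits(truth, "sim_truth"))
  true_key <- paste(truth$true_pairs$mirna, truth$true_pairs$gene, sep = "\r")
  edge_key <- paste(network$edges$mirna, network$edges$gene, sep = "\r")
  tp <- sum(edge_key %in% true_key)
  fp <- length(edge_key) - tp
  fn <- length(true_key) - tp
  precision <- if (length(edge_key) == 0) NA_real_ else tp / (tp + fp)
  recall <- if (length(true_key) == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn,
       tp_validated = sum(network$edges$validated[edge_key %in% true_key]),
       fp_validated = sum(network$edges$validated[!edge_key %in% true_key]))
}
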