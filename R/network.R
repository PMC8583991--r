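#' Candidate miRNA-target pairs restricted to differentially expressed features
#'
#' Filters a target-pair database to pairs whose miRNA and gene are both
#' significant at the given FDR threshold, deduplicating across sources:
#' each (miRNA, gene) pair appears once with the union of contributing
#' sources, and is flagged validated if any contributing source is a
#' validated-class database.
#'
#' @param de_mirna,de_gene `de_table`s for the two layers.
#' @param db A [target_pair_db()].
#' @param alpha FDR threshold for both layers (default 0.05).
#' @return data.frame with columns `mirna`, `gene`, `validated`, `sources`
#'   (semicolon-separated, sorted).
#' @export
candidate_pairs <- function(de_mirna, de_gene, db, alpha = 0.05) {
  sig_m <- significant_features(de_mirna, alpha)
  sig_g <- significant_features(de_gene, alpha)
  empty <- data.frame(mirna = character(0), gene = character(0),
                      validated = logical(0), sources = character(0),
                      stringsAsFactors = FALSE)
  if (length(sig_m) == 0 || length(sig_g) == 0) {
    warning("no differentially expressed features in at least one layer; ",
            "no candidate pairs")
    return(empty)
  }
  sub <- db[db$mirna %in% sig_m & db$gene %in% sig_g, , drop = FALSE]
  if (nrow(sub) == 0) return(empty)
  key <- paste(sub$mirna, sub$gene, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    mirna = sub$mirna[first], gene = sub$gene[first],
    validated = as.logical(tapply(sub$evidence == "validated", key,
                                  any)[key[first]]),
    sources = as.character(tapply(sub$source, key, function(s)
      paste(sort(unique(s)), collapse = ";"))[key[first]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the anticorrelation miRNA-target transcript network
#'
#' For every candidate pair, computes the Pearson correlation between the
#' miRNA's and gene's transformed expression over the samples assayed on
#' both layers, and admits the pair as an edge iff `r < r_threshold` and
#' `p < p_threshold` (both strict). Pairs with a constant expression vector
#' are skipped with a message.
#'
#' @param candidates Output of [candidate_pairs()].
#' @param rlog_mirna,rlog_mrna Transformed feature x sample matrices (see
#'   [rlog_like()]); correlations use the intersection of their samples.
#' @param r_threshold Correlation admission threshold (default -0.7).
#' @param p_threshold p-value admission threshold (default 0.05).
#' @param de_mirna,de_gene Optional `de_table`s used to annotate nodes with
#'   log2 fold changes and up/down directions.
#' @return A [mirna_target_network()].
#' @export
build_network <- function(candidates, rlog_mirna, rlog_mrna,
                          r_threshold = -0.7, p_threshold = 0.05,
                          de_mirna = NULL, de_gene = NULL) {
  shared <- intersect(colnames(rlog_mirna), colnames(rlog_mrna))
  if (length(shared) < 3)
    stop("fewer than 3 samples shared between the two layers")
  xm <- rlog_mirna[, shared, drop = FALSE]
  xg <- rlog_mrna[, shared, drop = FALSE]
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    m <- candidates$mirna[i]; g <- candidates$gene[i]
    if (!m %in% rownames(xm) || !g %in% rownames(xg)) next
    a <- xm[m, ]; b <- xg[g, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      message(sprintf("skipping pair (%s, %s): constant expression vector",
                      m, g))
      next
    }
    ct <- pearson_with_p(a, b)
    if (ct$r < r_threshold && ct$p < p_threshold) {
      rows[[i]] <- data.frame(mirna = m, gene = g, pearson_r = ct$r,
                              p_value = ct$p, n_samples = ct$n,
                              validated = candidates$validated[i],
                              sources = candidates$sources[i],
                              stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    edges <- data.frame(mirna = character(0), gene = character(0),
                        pearson_r = numeric(0), p_value = numeric(0),
                        n_samples = integer(0), validated = logical(0),
                        sources = character(0), stringsAsFactors = FALSE)
  anno <- function(de) {
    if (is.null(de)) return(NULL)
    data.frame(id = de$feature_id, lfc = de$lfc,
               direction = ifelse(is.na(de$lfc), NA_character_,
                                  ifelse(de$lfc > 0, "up", "down")),
               stringsAsFactors = FALSE)
  }
  mirna_target_network(edges, mirnas = anno(de_mirna), genes = anno(de_gene),
                       n_samples = length(shared),
                       thresholds = list(r_threshold = r_threshold,
                                         p_threshold = p_threshold))
}

#' Network summary statistics
#'
#' Edge/node/validated-edge counts plus, when a gene-layer DE table is
#' supplied, the percentage of down- and upregulated DE genes that appear
#' as network targets (whole percents).
#'
#' @param network A `mirna_target_network`.
#' @param de_gene Optional gene-layer `de_table`.
#' @param alpha FDR threshold defining DE genes (default 0.05).
#' @return List of counts and percentages.
#' @export
network_summary <- function(network, de_gene = NULL, alpha = 0.05) {
  out <- list(n_edges = nrow(network$edges),
              n_mirnas = nrow(network$mirnas),
              n_genes = nrow(network$genes),
              n_validated_edges = sum(network$edges$validated),
              n_samples = network$n_samples)
  if (!is.null(de_gene)) {
    targets <- network$genes$id
    for (dir in c("down", "up")) {
      de_ids <- significant_features(de_gene, alpha, direction = dir)
      n_de <- length(de_ids)
      n_hit <- length(intersect(de_ids, targets))
      out[[paste0("n_", dir, "_de_genes")]] <- n_de
      out[[paste0("n_", dir, "_de_targeted")]] <- n_hit
      out[[paste0("pct_", dir, "_de_targeted")]] <-
        if (n_de == 0) 0 else round(100 * n_hit / n_de)
    }
  }
  out
}

#' Compare per-transcript correlation strength by miRNA degree
#'
#' Splits target transcripts into those targeted by more than one miRNA and
#' those targeted by exactly one, summarizes each transcript by the
#' arithmetic mean of its edge correlations (or by pooling the edge
#' correlations directly), and compares the two classes with a two-sided
#' Mann-Whitney U test.
#'
#' @param network A `mirna_target_network`.
#' @param aggregate `"mean"` (default; per-transcript mean edge correlation)
#'   or `"pooled"` (each edge correlation enters its class directly).
#' @return List with `median_multi`, `iqr_multi`, `median_single`,
#'   `iqr_single`, `mwu_p`, `n_multi`, `n_single`. When a degree class is
#'   empty its statistics and the p-value are `NA`.
#' @export
degree_correlation_test <- function(network, aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  e <- network$edges
  deg <- table(e$gene)
  per_gene <- tapply(e$pearson_r, e$gene, mean)
  multi_genes <- names(deg)[deg > 1]
  single_genes <- names(deg)[deg == 1]
  vals <- function(genes) {
    if (aggregate == "mean") as.numeric(per_gene[genes])
    else e$pearson_r[e$gene %in% genes]
  }
  v_multi <- vals(multi_genes)
  v_single <- vals(single_genes)
  iqr_pair <- function(v) {
    if (!length(v)) return(c(NA_real_, NA_real_))
    stats::quantile(v, c(0.25, 0.75), names = FALSE)
  }
  p <- if (length(v_multi) && length(v_single))
    mwu_test(v_multi, v_single)$p else NA_real_
  list(median_multi = if (length(v_multi)) stats::median(v_multi) else NA_real_,
       iqr_multi = iqr_pair(v_multi),
       median_single = if (length(v_single)) stats::median(v_single) else NA_real_,
       iqr_single = iqr_pair(v_single),
       mwu_p = p,
       n_multi = length(multi_genes), n_single = length(single_genes))
}

#' Prioritize network target transcripts
#'
#' Tier A: transcripts targeted by at least two miRNAs. Tier B: tier A
#' transcripts for which at least one incident interaction is
#' experimentally validated.
#'
#' @param network A `mirna_target_network`.
#' @return List: `tier_a`, `tier_b` (gene id vectors), `n_tier_a`,
#'   `n_tier_b`, `percent_validated` (whole percent of tier A in tier B,
#'   `NA` when tier A is empty).
#' @export
prioritize_targets <- function(network) {
  e <- network$edges
  deg <- table(e$gene)
  tier_a <- names(deg)[deg >= 2]
  has_val <- tapply(e$validated, e$gene, any)
  tier_b <- tier_a[as.logical(has_val[tier_a])]
  list(tier_a = tier_a, tier_b = tier_b,
       n_tier_a = length(tier_a), n_tier_b = length(tier_b),
       percent_validated = if (length(tier_a) == 0) NA_real_
       else round(100 * length(tier_b) / length(tier_a)))
}

#' Overlap of the network with an externally prioritized gene list
#'
#' Reports how many genes of a prioritized list (e.g. genes nominated as
#' causal within disease risk loci) are expressed and how many appear as
#' network targets, and returns the induced subnetwork.
#'
#' @param network A `mirna_target_network`.
#' @param gene_list Character vector of prioritized gene ids.
#' @param expressed Character vector of expressed gene ids.
#' @return List: `n_list`, `n_expressed`, `n_in_network`,
#'   `genes_in_network`, `subnetwork` (the network restricted to edges
#'   incident to listed genes).
#' @export
overlap_prioritized_genes <- function(network, gene_list, expressed) {
  gene_list <- unique(as.character(gene_list))
  in_expr <- intersect(gene_list, expressed)
  targets <- network$genes$id
  hit <- intersect(gene_list, targets)
  sub_edges <- network$edges[network$edges$gene %in% hit, , drop = FALSE]
  sub <- mirna_target_network(sub_edges,
                              mirnas = cbind(network$mirnas),
                              genes = cbind(network$genes),
                              n_samples = network$n_samples,
                              thresholds = network$thresholds)
  list(n_list = length(gene_list), n_expressed = length(in_expr),
       n_in_network = length(hit), genes_in_network = hit,
       subnetwork = sub)
}
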