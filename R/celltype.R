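#' Extract top-k cell-type miRNA signatures from an atlas
#'
#' For each requested cell type, takes the `k` miRNAs with the highest
#' atlas enrichment. Ties at the cut are broken lexicographically by miRNA
#' id (and reported with a message).
#'
#' @param atlas A [cell_type_atlas()].
#' @param cell_types Cell types to extract (default: all atlas rows).
#' @param k Signature size (default 10). When `k` exceeds the atlas width
#'   the full miRNA list is returned with a warning.
#' @return Named list of character vectors (class `cell_type_signatures`),
#'   ordered by descending enrichment.
#' @export
extract_signatures <- function(atlas, cell_types = rownames(atlas), k = 10) {
  unknown <- setdiff(cell_types, rownames(atlas))
  if (length(unknown))
    stop("unknown cell type(s): ", paste(unknown, collapse = ", "))
  if (k > ncol(atlas)) {
    warning(sprintf("k = %d exceeds atlas width %d; using all miRNAs",
                    k, ncol(atlas)))
    k <- ncol(atlas)
  }
  sigs <- lapply(cell_types, function(ct) {
    enr <- atlas[ct, ]
    ord <- order(-enr, colnames(atlas))
    if (k < ncol(atlas) && enr[ord[k]] == enr[ord[k + 1]])
      message(sprintf("tie at rank %d for '%s'; lexicographic winner kept",
                      k, ct))
    colnames(atlas)[ord[seq_len(k)]]
  })
  names(sigs) <- cell_types
  structure(sigs, k = k, class = "cell_type_signatures")
}

#' Single-sample signature enrichment score
#'
#' Rank-based running-sum enrichment of a feature set in each sample.
#' Features are ranked by expression (descending; average ranks for ties)
#' and walked from highest to lowest. The in-set cumulative weight uses
#' rank weights `(N - rank + 1)^tau` normalized over the set; the out-set
#' cumulative weight is the uniform step function. The score is the value
#' of `P_in(i) - P_out(i)` at its maximum absolute deviation, so a set
#' concentrated at the top of a sample's ranking scores positive and one
#' at the bottom scores negative. Depends on expression only through
#' within-sample ranks. With `tau = 0` it reduces to the classic
#' unweighted Kolmogorov-Smirnov running sum.
#'
#' @param expr Feature x sample numeric matrix (e.g. [rlog_like()] output).
#' @param signature Character vector of feature ids; its intersection with
#'   the rows of `expr` must be non-empty and a proper subset.
#' @param tau Rank-weight exponent (default 0.25).
#' @return Named numeric vector of per-sample scores.
#' @export
ss_enrichment <- function(expr, signature, tau = 0.25) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 features")
  sig <- intersect(unique(signature), rownames(expr))
  if (length(sig) == 0) stop("signature has no feature in the matrix")
  if (length(sig) == nrow(expr))
    stop("signature covers the full feature set; score undefined")
  n_feat <- nrow(expr)
  in_set <- rownames(expr) %in% sig
  n_out <- n_feat - length(sig)
  scores <- vapply(seq_len(ncol(expr)), function(s) {
    rk <- rank(-expr[, s], ties.method = "average")
    w <- (n_feat - rk + 1)^tau
    ord <- order(rk, rownames(expr))
    win <- ifelse(in_set, w, 0)[ord]
    p_in <- cumsum(win) / sum(w[in_set])
    p_out <- cumsum(!in_set[ord]) / n_out
    dev <- p_in - p_out
    dev[which.max(abs(dev))]
  }, numeric(1))
  names(scores) <- colnames(expr)
  scores
}

#' Sample x signature score matrix
#'
#' Applies [ss_enrichment()] to each signature of a collection.
#'
#' @param expr Feature x sample matrix.
#' @param signatures Named list of feature id vectors (e.g. from
#'   [extract_signatures()]), or a single vector.
#' @param tau Passed to [ss_enrichment()].
#' @return Numeric matrix, samples in rows, signatures in columns.
#' @export
signature_scores <- function(expr, signatures, tau = 0.25) {
  if (!is.list(signatures)) signatures <- list(signature = signatures)
  out <- vapply(signatures, function(s) ss_enrichment(expr, s, tau = tau),
                numeric(ncol(expr)))
  out <- matrix(out, ncol = length(signatures),
                dimnames = list(colnames(expr), names(signatures)))
  out
}

#' Group comparison of signature scores
#'
#' Two-sided Mann-Whitney U test of each signature's per-sample scores
#' between the two levels of a grouping variable, with group medians.
#'
#' @param scores Sample x signature matrix from [signature_scores()].
#' @param metadata Per-sample data.frame containing `group`.
#' @param group Name of the two-level grouping column (default `"status"`).
#' @return data.frame: `signature`, `median_<level1>`, `median_<level2>`,
#'   `mwu_p`.
#' @export
score_group_test <- function(scores, metadata, group = "status") {
  metadata <- metadata[rownames(scores), , drop = FALSE]
  g <- factor(metadata[[group]])
  g <- droplevels(g)
  if (nlevels(g) != 2) stop("grouping variable must have two levels")
  if (min(table(g)) < 1) stop("a group is empty")
  lev <- levels(g)
  rows <- lapply(colnames(scores), function(sg) {
    a <- scores[g == lev[1], sg]
    b <- scores[g == lev[2], sg]
    out <- data.frame(signature = sg, m1 = stats::median(a),
                      m2 = stats::median(b), mwu_p = mwu_test(a, b)$p,
                      stringsAsFactors = FALSE)
    out
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("median_", lev)
  out
}

#' Correlate miRNA expression with signature scores
#'
#' Pearson correlation of each miRNA's transformed expression with each
#' signature's per-sample score, over the shared samples. Scores are used
#' unscaled. Constant vectors are skipped (NA) with a message.
#'
#' @param rlog_mirna Feature x sample matrix.
#' @param scores Sample x signature score matrix.
#' @return miRNA x signature correlation matrix.
#' @export
mirna_score_correlation <- function(rlog_mirna, scores) {
  shared <- intersect(colnames(rlog_mirna), rownames(scores))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  x <- rlog_mirna[, shared, drop = FALSE]
  sc <- scores[shared, , drop = FALSE]
  out <- matrix(NA_real_, nrow(x), ncol(sc),
                dimnames = list(rownames(x), colnames(sc)))
  for (i in seq_len(nrow(x))) {
    if (stats::sd(x[i, ]) == 0) {
      message("skipping constant miRNA vector: ", rownames(x)[i])
      next
    }
    for (j in seq_len(ncol(sc))) {
      if (stats::sd(sc[, j]) == 0) next
      out[i, j] <- stats::cor(x[i, ], sc[, j])
    }
  }
  out
}

#' Correlate DE fold changes with atlas cell-type enrichment
#'
#' Pearson correlation, over the miRNAs shared between a DE table and the
#' atlas, of the log2 fold change with the atlas enrichment for one cell
#' type. A positive correlation means miRNAs elevated in cases tend to be
#' the ones enriched in that cell type.
#'
#' @param de_mirna miRNA-layer `de_table`.
#' @param atlas A [cell_type_atlas()].
#' @param cell_type Atlas row to correlate against.
#' @return List `r`, `p`, `n` (shared miRNA count).
#' @export
lfc_atlas_correlation <- function(de_mirna, atlas, cell_type) {
  if (!cell_type %in% rownames(atlas))
    stop("unknown cell type: ", cell_type)
  ok <- de_mirna$tested & !is.na(de_mirna$lfc)
  shared <- intersect(de_mirna$feature_id[ok], colnames(atlas))
  if (length(shared) < 3) stop("fewer than 3 miRNAs shared with the atlas")
  lfc <- de_mirna$lfc[match(shared, de_mirna$feature_id)]
  enr <- atlas[cell_type, shared]
  res <- pearson_with_p(lfc, enr)
  list(r = res$r, p = res$p, n = res$n)
}

#' Composition-corrected differential expression
#'
#' Reruns the negative-binomial Wald test with the cell-type signature
#' scores appended to the covariates, so status effects that are explained
#' by cell-type composition lose significance while direct effects are
#' retained. Collinear or constant score columns are an error.
#'
#' @param dataset An [expression_dataset()].
#' @param scores Sample x signature score matrix covering the dataset's
#'   samples.
#' @param covariates Additional metadata covariates (default
#'   `c("age", "sex")`).
#' @param test_var Tested factor (default `"status"`).
#' @param baseline Optional uncorrected `de_table` to compare against.
#' @param fdr_threshold FDR cutoff defining significance for the
#'   comparison (default 0.1).
#' @return When `baseline` is `NULL`, the corrected `de_table`. Otherwise a
#'   list: `table`, `previously_significant`, `retained`, `lost`.
#' @export
corrected_de <- function(dataset, scores, covariates = c("age", "sex"),
                         test_var = "status", baseline = NULL,
                         fdr_threshold = 0.1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  samples <- colnames(dataset$counts)
  missing <- setdiff(samples, rownames(scores))
  if (length(missing))
    stop("scores missing for samples: ", paste(missing, collapse = ", "))
  sc <- scores[samples, , drop = FALSE]
  score_names <- make.names(colnames(sc))
  mm <- cbind(`(Intercept)` = 1, sc)
  qd <- qr(mm)
  if (qd$rank < ncol(mm)) {
    bad <- colnames(mm)[qd$pivot[(qd$rank + 1):ncol(mm)]]
    stop("collinear score column(s): ",
         paste(setdiff(bad, "(Intercept)"), collapse = ", "))
  }
  meta2 <- dataset$metadata
  for (j in seq_along(score_names)) meta2[[score_names[j]]] <- sc[, j]
  ds2 <- dataset
  ds2$metadata <- meta2
  tab <- nb_wald_de(ds2, covariates = c(covariates, score_names),
                    test_var = test_var)
  if (is.null(baseline)) return(tab)
  prev <- significant_features(baseline, alpha = fdr_threshold)
  now <- significant_features(tab, alpha = fdr_threshold)
  list(table = tab,
       previously_significant = prev,
       retained = intersect(prev, now),
       lost = setdiff(prev, now))
}
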