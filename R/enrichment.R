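#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query within a
#' background universe. For a set with `K` members in the background, a
#' query of size `n`, and `k` query hits, the p-value is the upper-tail
#' hypergeometric mass `P(X >= k)` out of `N` background genes. Gene sets
#' are intersected with the background first; sets with no background
#' member (or outside the size window) are untested. FDR is
#' Benjamini-Hochberg across the tested sets of this one query.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`; deduplicated).
#' @param sets A [gene_set_collection()] or named list of id vectors.
#' @param background Character vector: the gene universe (typically all
#'   genes expressed in the mRNA dataset).
#' @param min_set_size,max_set_size Size window applied after intersecting
#'   with the background.
#' @return data.frame of class `enrichment_result`, ordered by p-value,
#'   with columns `set_name`, `k`, `K`, `n`, `N`, `p_value`, `fdr`,
#'   `gene_ratio_kn` (k/n), `gene_ratio_kK` (k/K), and list-column
#'   `hit_genes`.
#' @export
ora <- function(query, sets, background, min_set_size = 1,
                max_set_size = Inf) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("empty background")
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside))
    stop("query genes missing from background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), background)
    K <- length(s)
    if (K == 0 || K < min_set_size || K > max_set_size) return(NULL)
    hits <- intersect(s, query)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p_value = p,
               gene_ratio_kn = if (n > 0) k / n else NA_real_,
               gene_ratio_kK = k / K,
               hit_genes = I(list(hits)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_name = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      gene_ratio_kn = numeric(0), gene_ratio_kK = numeric(0),
                      hit_genes = I(list()))
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Direction-split ORA of network target genes
#'
#' Runs one over-representation analysis for the network's downregulated
#' target genes and one for the upregulated targets (direction from the
#' gene-layer DE table), and annotates each tested set with the number of
#' distinct miRNAs targeting at least one of its hit genes — the natural
#' sort key for "how many miRNAs converge on this pathway".
#'
#' @param network A `mirna_target_network`.
#' @param de_gene Gene-layer `de_table`.
#' @param sets A [gene_set_collection()].
#' @param background Gene universe (see [ora()]).
#' @param ... Passed to [ora()].
#' @return List with elements `down` and `up`, each an `enrichment_result`
#'   with an extra `n_mirnas` column.
#' @export
directional_ora <- function(network, de_gene, sets, background, ...) {
  targets <- network$genes$id
  lfc <- de_gene$lfc[match(targets, de_gene$feature_id)]
  res <- list()
  for (dir in c("down", "up")) {
    q <- targets[!is.na(lfc) & (if (dir == "down") lfc < 0 else lfc > 0)]
    q <- intersect(q, background)
    r <- ora(q, sets, background, ...)
    r$n_mirnas <- vapply(r$hit_genes, function(h)
      length(unique(network$edges$mirna[network$edges$gene %in% h])),
      integer(1))
    res[[dir]] <- r
  }
  res
}

#' Per-miRNA ORA of target genes
#'
#' One over-representation analysis per network miRNA, with that miRNA's
#' target genes as the query. miRNAs with no target in the background are
#' absent from the result.
#'
#' @param network A `mirna_target_network`.
#' @param sets A [gene_set_collection()].
#' @param background Gene universe.
#' @param ... Passed to [ora()].
#' @return Named list of `enrichment_result`s, one per miRNA; each carries
#'   an attribute `n_targets`.
#' @export
per_mirna_ora <- function(network, sets, background, ...) {
  by_mirna <- split(network$edges$gene, network$edges$mirna)
  out <- list()
  for (m in names(by_mirna)) {
    q <- intersect(unique(by_mirna[[m]]), background)
    if (length(q) == 0) next
    r <- ora(q, sets, background, ...)
    attr(r, "n_targets") <- length(q)
    out[[m]] <- r
  }
  out
}

#' Collapse redundant enriched sets by Jaccard overlap
#'
#' A simple, clearly approximate substitute for semantic term-redundancy
#' reduction: walks the results from most to least significant and drops
#' any set whose background-restricted membership has Jaccard overlap of
#' at least `threshold` with an already-kept set.
#'
#' @param result An `enrichment_result`.
#' @param sets The [gene_set_collection()] the result was computed from.
#' @param background The background used.
#' @param threshold Jaccard overlap at or above which a set is dropped
#'   (default 0.5).
#' @return The filtered `enrichment_result`.
#' @export
collapse_redundant_sets <- function(result, sets, background,
                                    threshold = 0.5) {
  if (nrow(result) <= 1) return(result)
  members <- lapply(result$set_name, function(nm)
    intersect(unique(sets[[nm]]), background))
  keep <- logical(nrow(result))
  kept_members <- list()
  for (i in seq_len(nrow(result))) {
    s <- members[[i]]
    redundant <- any(vapply(kept_members, function(ks) {
      length(intersect(s, ks)) / length(union(s, ks)) >= threshold
    }, logical(1)))
    if (!redundant) {
      keep[i] <- TRUE
      kept_members[[length(kept_members) + 1]] <- s
    }
  }
  out <- result[keep, ]
  rownames(out) <- NULL
  out
}
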