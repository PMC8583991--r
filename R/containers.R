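#' Paired count matrix with sample metadata
#'
#' The basic container for one omic layer (miRNA or mRNA): a feature x sample
#' matrix of non-negative integer counts plus a per-sample metadata table.
#' Metadata rows are aligned 1:1 with the count columns; a `status` column,
#' when present, is coerced to a factor with `"control"` as the reference
#' level so that positive log2 fold changes always mean "higher in case".
#'
#' @param counts Feature x sample matrix of non-negative integer counts with
#'   unique row and column names.
#' @param metadata data.frame with one row per sample. Sample ids are taken
#'   from the row names, or from a `sample_id` column if present. Typical
#'   columns: `status` (two-level factor), `age` (years), `sex`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `counts` and `metadata` (metadata reordered to match the count columns).
#' @export
expression_dataset <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite and numeric")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count %s at feature '%s', sample '%s'",
                 format(counts[bad[1], bad[2]]),
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  metadata <- as.data.frame(metadata)
  if ("sample_id" %in% names(metadata)) {
    rownames(metadata) <- as.character(metadata$sample_id)
    metadata$sample_id <- NULL
  }
  missing <- setdiff(colnames(counts), rownames(metadata))
  if (length(missing))
    stop("samples present in counts but absent from metadata: ",
         paste(missing, collapse = ", "))
  metadata <- metadata[colnames(counts), , drop = FALSE]
  if ("status" %in% names(metadata)) {
    st <- as.character(metadata$status)
    lev <- unique(st)
    if (all(sort(lev) == sort(c("control", "case"))))
      lev <- c("control", "case")
    metadata$status <- factor(st, levels = lev)
  }
  structure(list(counts = counts, metadata = metadata),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if ("status" %in% names(x$metadata))
    print(table(x$metadata$status))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$counts)

#' miRNA-to-gene candidate target pair table
#'
#' Validates a table of candidate (miRNA, gene) interactions with per-source
#' provenance. Each source is either a prediction database or a database of
#' experimentally validated interactions; the `evidence` column records that
#' class and must be constant within a source.
#'
#' @param pairs data.frame with columns `mirna`, `gene`, `source`,
#'   `evidence` (each entry `"predicted"` or `"validated"`).
#' @return The validated data.frame with class `target_pair_db`.
#' @export
target_pair_db <- function(pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("mirna", "gene", "source", "evidence")
  if (!all(need %in% names(pairs)))
    stop("target pair table must have columns: ", paste(need, collapse = ", "))
  if (!all(pairs$evidence %in% c("predicted", "validated")))
    stop("evidence must be 'predicted' or 'validated'")
  key <- paste(pairs$mirna, pairs$gene, pairs$source, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (mirna, gene, source) rows in target pair table")
  ev_per_source <- tapply(pairs$evidence, pairs$source,
                          function(e) length(unique(e)))
  if (any(ev_per_source > 1))
    stop("source with inconsistent evidence class: ",
         paste(names(ev_per_source)[ev_per_source > 1], collapse = ", "))
  rownames(pairs) <- NULL
  class(pairs) <- c("target_pair_db", "data.frame")
  pairs
}

#' Named gene-set collection
#'
#' @param sets Named list of character vectors of gene ids.
#' @param descriptions Optional character vector of free-text descriptions,
#'   recycled or named like `sets`.
#' @return List of class `gene_set_collection` with a `descriptions`
#'   attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0))
    stop("empty gene sets: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' Cell-type x miRNA atlas enrichment matrix
#'
#' @param mat Numeric matrix, rows = cell types, columns = miRNA ids.
#' @return The matrix with class `cell_type_atlas`.
#' @export
cell_type_atlas <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("atlas must have cell-type row names and miRNA column names")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate cell types in atlas")
  if (any(!is.finite(mat)))
    stop("atlas enrichment values must be finite")
  class(mat) <- c("cell_type_atlas", class(mat))
  mat
}

#' Bipartite miRNA-target transcript network
#'
#' Low-level constructor used by [build_network()] and by readers of exported
#' edge lists. Edges connect a miRNA to a target gene and carry the Pearson
#' correlation, its p-value, the number of samples it was computed on, a flag
#' for experimental validation, and the contributing database sources.
#'
#' @param edges data.frame with columns `mirna`, `gene`, `pearson_r`,
#'   `p_value`, `n_samples`, `validated`, `sources` (semicolon-separated
#'   source names).
#' @param mirnas,genes Optional per-node annotation data.frames with columns
#'   `id`, `lfc`, `direction`; rebuilt from `edges` (with NA annotations)
#'   when omitted.
#' @param n_samples Number of shared samples correlations were computed on.
#' @param thresholds Named list of the admission thresholds used.
#' @return Object of class `mirna_target_network`.
#' @export
mirna_target_network <- function(edges, mirnas = NULL, genes = NULL,
                                 n_samples = NA_integer_, thresholds = list()) {
  edges <- as.data.frame(edges)
  need <- c("mirna", "gene", "pearson_r", "p_value", "n_samples",
            "validated", "sources")
  defaults <- list(mirna = character(0), gene = character(0),
                   pearson_r = numeric(0), p_value = numeric(0),
                   n_samples = integer(0), validated = logical(0),
                   sources = character(0))
  if (nrow(edges) == 0) {
    edges <- as.data.frame(defaults, stringsAsFactors = FALSE)
  } else {
    fill <- list(pearson_r = NA_real_, p_value = NA_real_,
                 n_samples = NA_integer_, validated = FALSE, sources = "")
    miss <- setdiff(need, names(edges))
    if (any(c("mirna", "gene") %in% miss))
      stop("edges must have 'mirna' and 'gene' columns")
    for (col in miss) edges[[col]] <- fill[[col]]
  }
  edges <- edges[, need, drop = FALSE]
  if (nrow(edges) && any(stats::na.omit(edges$pearson_r) >= 0))
    stop("network edges must have negative Pearson correlations")
  node_df <- function(ids, anno) {
    df <- data.frame(id = ids, lfc = rep(NA_real_, length(ids)),
                     direction = rep(NA_character_, length(ids)),
                     stringsAsFactors = FALSE)
    if (!is.null(anno)) {
      anno <- as.data.frame(anno)
      idx <- match(df$id, anno$id)
      df$lfc <- anno$lfc[idx]
      df$direction <- as.character(anno$direction[idx])
    }
    rownames(df) <- NULL
    df
  }
  structure(list(edges = edges,
                 mirnas = node_df(unique(edges$mirna), mirnas),
                 genes = node_df(unique(edges$gene), genes),
                 n_samples = n_samples,
                 thresholds = thresholds),
            class = "mirna_target_network")
}

#' @export
print.mirna_target_network <- function(x, ...) {
  cat(sprintf("mirna_target_network: %d edges, %d miRNAs, %d genes (%d validated edges)\n",
              nrow(x$edges), nrow(x$mirnas), nrow(x$genes),
              sum(x$edges$validated)))
  invisible(x)
}
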