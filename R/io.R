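#' Read a count matrix and its sample metadata
#'
#' Counts are a TSV with feature ids in the first column and a header of
#' sample ids; entries must be non-negative integers (missing values are
#' illegal). Metadata is a TSV keyed by a `sample_id` first column and must
#' cover every count sample.
#'
#' @param path Counts TSV path.
#' @param metadata_path Metadata TSV path.
#' @return An [expression_dataset()].
#' @export
read_counts <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("counts file needs a feature column and samples")
  feats <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat),
                                   dimnames = dimnames(mat)))
    bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric count at feature '%s', sample '%s'",
                   feats[bad[1, 1]], colnames(mat)[bad[1, 2]]))
    mat <- num
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing count at feature '%s', sample '%s'",
                 feats[bad[1]], colnames(mat)[bad[2]]))
  }
  rownames(mat) <- feats
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  names(meta)[1] <- "sample_id"
  expression_dataset(mat, meta)
}

#' Write a count matrix and metadata as TSV
#'
#' @param dataset An [expression_dataset()].
#' @param path Counts TSV path (first column `feature_id`).
#' @param metadata_path Optional metadata TSV path (first column
#'   `sample_id`).
#' @export
write_counts <- function(dataset, path, metadata_path = NULL) {
  tab <- data.frame(feature_id = rownames(dataset$counts),
                    dataset$counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- data.frame(sample_id = rownames(dataset$metadata),
                       dataset$metadata, check.names = FALSE)
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then members, tab-separated.
#' Duplicate members within a set are deduplicated with a warning; duplicate
#' set names or lines with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nms))
    stop("duplicate gene set name: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  descr <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) p[-(1:2)])
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0
  if (any(dup))
    warning("duplicate members deduplicated in set(s): ",
            paste(nms[dup], collapse = ", "))
  names(sets) <- nms
  gene_set_collection(sets, descr)
}

#' Write a gene-set collection as GMT
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  descr <- attr(sets, "descriptions")
  if (is.null(descr)) descr <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descr[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a target-pair database TSV
#'
#' Columns: `mirna`, `gene`, `source`, `evidence`.
#'
#' @param path TSV path.
#' @return A [target_pair_db()].
#' @export
read_target_db <- function(path) {
  target_pair_db(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a target-pair database TSV
#' @param db A [target_pair_db()].
#' @param path Output path.
#' @export
write_target_db <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-type atlas TSV
#'
#' Rows are cell types (first column `cell_type`), columns are miRNAs.
#'
#' @param path TSV path.
#' @return A [cell_type_atlas()].
#' @export
read_atlas <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- as.character(tab[[1]])
  cell_type_atlas(mat)
}

#' Write a cell-type atlas TSV
#' @param atlas A [cell_type_atlas()].
#' @param path Output path.
#' @export
write_atlas <- function(atlas, path) {
  tab <- data.frame(cell_type = rownames(atlas),
                    unclass(atlas), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Export a network as edge TSV or GraphML
#'
#' The edge TSV has columns `mirna`, `gene`, `pearson_r`, `p_value`,
#' `validated`, `sources`, `mirna_direction`, `gene_direction`; numeric
#' attributes are written at full double precision so a round trip through
#' [read_network_edges()] restores the edge set and attributes exactly.
#' GraphML export writes a bipartite graph with a `layer` node attribute
#' (`"mirna"`/`"gene"`) and the same edge attributes.
#'
#' @param network A `mirna_target_network`.
#' @param path Output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  e <- network$edges
  dir_of <- function(ids, nodes) nodes$direction[match(ids, nodes$id)]
  if (format == "edge_tsv") {
    tab <- data.frame(
      mirna = e$mirna, gene = e$gene,
      pearson_r = fmt_full(e$pearson_r), p_value = fmt_full(e$p_value),
      n_samples = e$n_samples,
      validated = e$validated, sources = e$sources,
      mirna_direction = dir_of(e$mirna, network$mirnas),
      gene_direction = dir_of(e$gene, network$genes),
      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    nodes <- data.frame(
      name = c(network$mirnas$id, network$genes$id),
      layer = rep(c("mirna", "gene"),
                  c(nrow(network$mirnas), nrow(network$genes))),
      lfc = c(network$mirnas$lfc, network$genes$lfc),
      stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      d = e[, c("mirna", "gene", "pearson_r", "p_value", "n_samples",
                "validated", "sources")],
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge TSV written by [write_network()]
#'
#' @param path Edge TSV path.
#' @return A `mirna_target_network` (node LFC annotations are not stored in
#'   the edge list; directions are restored).
#' @export
read_network_edges <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  edges <- data.frame(
    mirna = tab$mirna, gene = tab$gene,
    pearson_r = as.numeric(tab$pearson_r),
    p_value = as.numeric(tab$p_value),
    n_samples = tab$n_samples,
    validated = as.logical(tab$validated),
    sources = as.character(tab$sources),
    stringsAsFactors = FALSE)
  dir_anno <- function(ids, dirs)
    data.frame(id = ids, lfc = NA_real_, direction = dirs,
               stringsAsFactors = FALSE)[!duplicated(ids), , drop = FALSE]
  mirna_target_network(
    edges,
    mirnas = dir_anno(tab$mirna, tab$mirna_direction),
    genes = dir_anno(tab$gene, tab$gene_direction),
    n_samples = if (nrow(tab)) tab$n_samples[1] else NA_integer_)
}
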