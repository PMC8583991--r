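#' Configuration for an end-to-end pipeline run
#'
#' Bundles all thresholds (defaults follow the standard workflow: DE FDR
#' 0.05, edge admission r < -0.7 and p < 0.05, composition-corrected FDR
#' 0.1, top-10 signatures), the covariate list, the seed, and either a
#' simulation configuration or paths to externally supplied inputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()] describing the synthetic inputs, or `NULL`
#'   when `inputs` is given.
#' @param inputs Optional named list of paths: `mirna_counts`,
#'   `mirna_metadata`, `mrna_counts`, `mrna_metadata`, `target_db`, `gmt`,
#'   `atlas`, `prioritized_genes` (one id per line).
#' @param alpha DE FDR threshold.
#' @param r_threshold,p_threshold Edge admission thresholds.
#' @param corrected_fdr FDR threshold for the composition-corrected DE
#'   comparison.
#' @param top_k Signature size.
#' @param tau Signature-score rank-weight exponent.
#' @param covariates Metadata covariates for the DE models.
#' @param seed Integer seed (also used for the simulation when `sim` has no
#'   explicit override).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, sim = sim_config(seed = seed),
                       inputs = NULL, alpha = 0.05, r_threshold = -0.7,
                       p_threshold = 0.05, corrected_fdr = 0.1, top_k = 10,
                       tau = 0.25, covariates = c("age", "sex"), seed = 1) {
  if (alpha <= 0 || alpha > 1 || p_threshold <= 0 || p_threshold > 1 ||
      corrected_fdr <= 0 || corrected_fdr > 1)
    stop("significance thresholds must lie in (0, 1]")
  if (r_threshold >= 0 || r_threshold < -1)
    stop("r_threshold must lie in [-1, 0)")
  if (top_k < 1) stop("top_k must be >= 1")
  if (!is.null(inputs)) {
    missing <- !vapply(unlist(inputs), file.exists, logical(1))
    if (any(missing))
      stop("missing input file(s): ",
           paste(unlist(inputs)[missing], collapse = ", "))
  }
  structure(list(out_dir = out_dir, sim = sim, inputs = inputs,
                 alpha = alpha, r_threshold = r_threshold,
                 p_threshold = p_threshold, corrected_fdr = corrected_fdr,
                 top_k = top_k, tau = tau, covariates = covariates,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input simulation (or loading), differential
#' expression on both layers, network construction, over-representation
#' analysis, cell-type signature scoring with composition-corrected DE,
#' and a machine-readable run summary. Every stage writes its outputs
#' under `config$out_dir` and appends a line to `MANIFEST` on completion;
#' a stage failure aborts with the stage name while earlier outputs are
#' retained. Reruns with the same configuration are deterministic.
#'
#' @param config A [run_config()].
#' @return The run summary (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(config$out_dir, "MANIFEST")
  if (file.exists(manifest)) file.remove(manifest)
  done <- function(stage) cat(stage, "\n", file = manifest, append = TRUE,
                              sep = "")
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    done(name)
    res
  }
  opath <- function(...) file.path(config$out_dir, ...)

  inp <- stage("inputs", {
    if (is.null(config$inputs)) {
      sim <- simulate_dataset(config$sim)
      db <- simulate_target_db(sim$truth, config$sim)
      fx <- simulate_fixtures(sim$truth, config$sim)
      write_counts(sim$mirna, opath("mirna_counts.tsv"),
                   opath("mirna_metadata.tsv"))
      write_counts(sim$mrna, opath("mrna_counts.tsv"),
                   opath("mrna_metadata.tsv"))
      write_target_db(db, opath("target_db.tsv"))
      write_gmt(fx$gene_sets, opath("gene_sets.gmt"))
      write_atlas(fx$atlas, opath("atlas.tsv"))
      writeLines(fx$prioritized_genes, opath("prioritized_genes.txt"))
      list(mirna = sim$mirna, mrna = sim$mrna, db = db,
           gene_sets = fx$gene_sets, atlas = fx$atlas,
           prioritized = fx$prioritized_genes, truth = sim$truth)
    } else {
      with(config$inputs, list(
        mirna = read_counts(mirna_counts, mirna_metadata),
        mrna = read_counts(mrna_counts, mrna_metadata),
        db = read_target_db(target_db),
        gene_sets = read_gmt(gmt),
        atlas = read_atlas(atlas),
        prioritized = readLines(prioritized_genes),
        truth = NULL))
    }
  })
  message(sprintf("[inputs] miRNA %d x %d; mRNA %d x %d; db %d rows",
                  nrow(inp$mirna$counts), ncol(inp$mirna$counts),
                  nrow(inp$mrna$counts), ncol(inp$mrna$counts),
                  nrow(inp$db)))

  de <- stage("diffexp", {
    de_m <- nb_wald_de(inp$mirna, covariates = config$covariates)
    de_g <- nb_wald_de(inp$mrna, covariates = config$covariates)
    utils::write.table(de_m, opath("de_mirna.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(de_g, opath("de_mrna.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(mirna = de_m, mrna = de_g)
  })
  message(sprintf("[diffexp] DE miRNAs %d (down %d/up %d); DE genes %d",
                  length(significant_features(de$mirna, config$alpha)),
                  length(significant_features(de$mirna, config$alpha, "down")),
                  length(significant_features(de$mirna, config$alpha, "up")),
                  length(significant_features(de$mrna, config$alpha))))

  net <- stage("network", {
    rl_m <- rlog_like(inp$mirna)
    rl_g <- rlog_like(inp$mrna)
    cand <- candidate_pairs(de$mirna, de$mrna, inp$db, alpha = config$alpha)
    nw <- build_network(cand, rl_m, rl_g,
                        r_threshold = config$r_threshold,
                        p_threshold = config$p_threshold,
                        de_mirna = de$mirna, de_gene = de$mrna)
    write_network(nw, opath("network_edges.tsv"), "edge_tsv")
    write_network(nw, opath("network.graphml"), "graphml")
    list(network = nw, candidates = cand, rlog_mirna = rl_m,
         rlog_mrna = rl_g)
  })
  message(sprintf("[network] %d candidates -> %d edges (%d miRNAs, %d genes)",
                  nrow(net$candidates), nrow(net$network$edges),
                  nrow(net$network$mirnas), nrow(net$network$genes)))

  enr <- stage("enrichment", {
    background <- rownames(inp$mrna$counts)[rowSums(inp$mrna$counts) > 0]
    dor <- directional_ora(net$network, de$mrna, inp$gene_sets, background)
    for (dir in names(dor)) {
      tab <- dor[[dir]]
      tab$hit_genes <- vapply(tab$hit_genes, paste, character(1),
                              collapse = ";")
      utils::write.table(tab, opath(sprintf("ora_%s.tsv", dir)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(directional = dor, background = background)
  })
  message(sprintf("[enrichment] background %d genes; %d/%d sets tested (down/up)",
                  length(enr$background), nrow(enr$directional$down),
                  nrow(enr$directional$up)))

  ct <- stage("celltype", {
    sig_cts <- intersect(c("epithelial", "T_cell"), rownames(inp$atlas))
    if (length(sig_cts) == 0) sig_cts <- rownames(inp$atlas)
    sigs <- extract_signatures(inp$atlas, sig_cts, k = config$top_k)
    scores <- signature_scores(net$rlog_mirna, sigs, tau = config$tau)
    utils::write.table(data.frame(sample_id = rownames(scores), scores,
                                  check.names = FALSE),
                       opath("celltype_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gtest <- score_group_test(scores, inp$mirna$metadata)
    atlas_cor <- lapply(sig_cts, function(ctype)
      lfc_atlas_correlation(de$mirna, inp$atlas, ctype))
    names(atlas_cor) <- sig_cts
    corr <- corrected_de(inp$mirna, scores,
                         covariates = config$covariates,
                         baseline = de$mirna,
                         fdr_threshold = config$corrected_fdr)
    prio_expr <- intersect(inp$prioritized, rownames(net$rlog_mrna))
    prio_scores <- if (length(prio_expr) >= 2 &&
                       length(prio_expr) < nrow(net$rlog_mrna))
      ss_enrichment(net$rlog_mrna, prio_expr, tau = config$tau) else NULL
    overlap <- overlap_prioritized_genes(net$network, inp$prioritized,
                                         enr$background)
    list(signatures = sigs, scores = scores, group_test = gtest,
         atlas_cor = atlas_cor, corrected = corr,
         prioritized_scores = prio_scores, overlap = overlap)
  })
  message(sprintf("[celltype] %d signatures; %d/%d corrected-DE retained",
                  length(ct$signatures), length(ct$corrected$retained),
                  length(ct$corrected$previously_significant)))

  summary <- stage("report", {
    s <- list(
      seed = config$seed,
      thresholds = list(alpha = config$alpha,
                        r_threshold = config$r_threshold,
                        p_threshold = config$p_threshold,
                        corrected_fdr = config$corrected_fdr,
                        top_k = config$top_k, tau = config$tau),
      de = list(
        n_de_mirna = length(significant_features(de$mirna, config$alpha)),
        n_de_mirna_down = length(significant_features(de$mirna, config$alpha,
                                                      "down")),
        n_de_mirna_up = length(significant_features(de$mirna, config$alpha,
                                                    "up")),
        n_de_gene = length(significant_features(de$mrna, config$alpha)),
        n_de_gene_down = length(significant_features(de$mrna, config$alpha,
                                                     "down")),
        n_de_gene_up = length(significant_features(de$mrna, config$alpha,
                                                   "up"))),
      network = network_summary(net$network, de$mrna, config$alpha),
      prioritization = prioritize_targets(net$network)[
        c("n_tier_a", "n_tier_b", "percent_validated")],
      overlap = ct$overlap[c("n_list", "n_expressed", "n_in_network")],
      corrected_de = list(
        n_previously_significant = length(ct$corrected$previously_significant),
        n_retained = length(ct$corrected$retained)))
    if (!is.null(inp$truth)) {
      rec <- evaluate_recovery(net$network, inp$truth)
      s$recovery <- rec[c("precision", "recall", "f1", "tp", "fp", "fn")]
    }
    jsonlite::write_json(s, opath("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    s
  })
  invisible(summary)
}
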