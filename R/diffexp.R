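#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over features
#' with nonzero counts in every sample, of the ratio of each sample's count
#' to the feature's geometric mean. Factors are rescaled to geometric mean 1.
#' If no feature is positive in all samples the function falls back to
#' library-size (column total) ratios with a warning.
#'
#' @param x An [expression_dataset()] or a counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "expression_dataset")) x$counts else as.matrix(x)
  if (all(counts == 0)) stop("all-zero count matrix")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    logc <- log(counts[pos, , drop = FALSE])
    loggeo <- rowMeans(logc)
    sf <- apply(logc, 2, function(lc) exp(stats::median(lc - loggeo)))
  } else {
    warning("no feature has nonzero counts in all samples; ",
            "falling back to library-size factors")
    sf <- colSums(counts)
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Regularized-log-like transform
#'
#' A pseudo-log variance-limiting transform: `log2(count / factor +
#' pseudocount)`. This is a simple normalized shifted log, not a
#' shrinkage-based regularized log; it is monotone in counts and used for
#' all correlation, PCA and signature-scoring steps.
#'
#' @param x An [expression_dataset()] or counts matrix.
#' @param factors Size factors from [size_factors()]; computed when omitted.
#' @param pseudocount Positive value added after normalization (default 1).
#' @return Numeric matrix with the dimensions and dimnames of the counts.
#' @export
rlog_like <- function(x, factors = NULL, pseudocount = 1) {
  counts <- if (inherits(x, "expression_dataset")) x$counts else as.matrix(x)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (is.null(factors)) factors <- size_factors(counts)
  if (length(factors) != ncol(counts))
    stop("need one size factor per sample")
  log2(sweep(counts, 2, factors, "/") + pseudocount)
}

#' Negative-binomial Wald differential expression
#'
#' Per-feature negative-binomial GLM (log link) of counts on a test variable
#' plus covariates, with `log(size factor)` offsets. Dispersion is a
#' per-feature method-of-moments estimate on normalized counts,
#' `alpha = max((var - mean) / mean^2, 1e-8)`, held fixed during the fit
#' (no Cox-Reid adjustment or shrinkage; no LFC shrinkage). The Wald
#' statistic for the test variable's coefficient is referred to the standard
#' normal, and p-values are Benjamini-Hochberg adjusted across tested
#' features. Features that are all zero, fail the optional base-mean filter,
#' or whose fit does not converge are reported untested with missing
#' statistics and are excluded from the BH denominator.
#'
#' @param dataset An [expression_dataset()]; metadata must contain
#'   `test_var` and all `covariates`.
#' @param covariates Character vector of metadata column names to adjust
#'   for (default `c("age", "sex")`). Covariates with no variation are
#'   dropped with a warning.
#' @param test_var Name of the two-level factor to test (default
#'   `"status"`); the reported log2 fold change is second level vs first
#'   (case vs control).
#' @param filter_quantile Features with base mean below this quantile of
#'   base means are untested (independent filtering; default 0 = off).
#' @return data.frame of class `de_table` with columns `feature_id`,
#'   `base_mean`, `lfc`, `se`, `wald`, `p_value`, `fdr`, `tested`.
#' @export
nb_wald_de <- function(dataset, covariates = c("age", "sex"),
                       test_var = "status", filter_quantile = 0) {
  stopifnot(inherits(dataset, "expression_dataset"))
  counts <- dataset$counts
  meta <- dataset$metadata
  if (!test_var %in% names(meta))
    stop("metadata has no column '", test_var, "'")
  tv <- meta[[test_var]]
  if (!is.factor(tv)) tv <- factor(tv)
  if (nlevels(droplevels(tv)) != 2)
    stop("test variable must have exactly two observed levels")
  tv <- droplevels(tv)
  if (min(table(tv)) < 2)
    stop("need at least 2 samples per level of the test variable")
  missing_cov <- setdiff(covariates, names(meta))
  if (length(missing_cov))
    stop("metadata has no covariate column(s): ",
         paste(missing_cov, collapse = ", "))
  keep <- vapply(covariates, function(cv) {
    v <- meta[[cv]]
    length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  if (any(!keep)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[!keep], collapse = ", "))
    covariates <- covariates[keep]
  }
  df <- data.frame(row.names = rownames(meta))
  for (cv in covariates) df[[cv]] <- meta[[cv]]
  df[[test_var]] <- tv
  form <- stats::as.formula(paste("~", paste(c(covariates, test_var),
                                             collapse = " + ")))
  mm <- stats::model.matrix(form, df)
  if (qr(mm)$rank < ncol(mm))
    stop("rank-deficient design matrix")
  coef_name <- paste0(test_var, levels(tv)[2])

  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  tested <- base_mean > 0
  if (filter_quantile > 0) {
    cutoff <- stats::quantile(base_mean, filter_quantile)
    tested <- tested & base_mean >= cutoff
  }

  n_feat <- nrow(counts)
  lfc <- se <- wald <- pval <- rep(NA_real_, n_feat)
  off <- log(sf)
  coef_idx <- match(coef_name, colnames(mm))
  p_cols <- ncol(mm)
  for (i in which(tested)) {
    y <- counts[i, ]
    m <- mean(norm[i, ])
    v <- stats::var(norm[i, ])
    alpha <- max((v - m) / m^2, 1e-8)
    fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(mm, y, family = fam, offset = off,
                                      control = stats::glm.control(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$rank < p_cols ||
        anyNA(fit$coefficients)) {
      tested[i] <- FALSE
      next
    }
    # Wald covariance from the final IRLS weighted least-squares fit
    rmat <- fit$qr$qr[seq_len(p_cols), seq_len(p_cols), drop = FALSE]
    covm <- tryCatch(chol2inv(rmat), error = function(e) NULL)
    if (is.null(covm)) { tested[i] <- FALSE; next }
    se_all <- rep(NA_real_, p_cols)
    se_all[fit$qr$pivot[seq_len(p_cols)]] <- sqrt(diag(covm))
    b <- fit$coefficients[coef_idx]
    s <- se_all[coef_idx]
    if (!is.finite(b) || !is.finite(s) || s <= 0) { tested[i] <- FALSE; next }
    lfc[i] <- b / log(2)
    se[i] <- s / log(2)
    wald[i] <- b / s
    pval[i] <- 2 * stats::pnorm(-abs(wald[i]))
  }
  fdr <- rep(NA_real_, n_feat)
  fdr[tested] <- bh_fdr(pval[tested])
  out <- data.frame(feature_id = rownames(counts), base_mean = base_mean,
                    lfc = lfc, se = se, wald = wald, p_value = pval,
                    fdr = fdr, tested = tested, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Helper: ids of significant features from a DE table
#'
#' @param de A `de_table`.
#' @param alpha FDR threshold.
#' @param direction `"both"`, `"up"` or `"down"` (sign of the log2 fold
#'   change, case vs control).
#' @return Character vector of feature ids.
#' @export
significant_features <- function(de, alpha = 0.05, direction = "both") {
  sig <- de$tested & !is.na(de$fdr) & de$fdr < alpha
  if (direction == "up") sig <- sig & de$lfc > 0
  if (direction == "down") sig <- sig & de$lfc < 0
  de$feature_id[sig]
}

#' Principal-component association with disease status
#'
#' PCA of samples on a transformed expression matrix, followed by, for each
#' of the leading components: a two-sided Mann-Whitney U test of the sample
#' scores between status groups and the partial association of the score
#' with status adjusting for sex and age in a linear model.
#'
#' @param rlog_matrix Feature x sample matrix (e.g. from [rlog_like()]).
#' @param metadata Per-sample data.frame with `status` and, for the partial
#'   test, `sex` and `age`.
#' @param n_components Number of leading components to test (default 2).
#' @param scale. Scale features to unit variance before the decomposition.
#' @return List with `scores` (sample x component), `var_explained`, and
#'   `tests` (data.frame: component, mwu_p, partial_beta, partial_p).
#' @export
pca_status_association <- function(rlog_matrix, metadata, n_components = 2,
                                   scale. = FALSE) {
  if (ncol(rlog_matrix) < 3) stop("need at least 3 samples")
  metadata <- metadata[colnames(rlog_matrix), , drop = FALSE]
  keep <- apply(rlog_matrix, 1, stats::sd) > 0 | !scale.
  pc <- stats::prcomp(t(rlog_matrix[keep, , drop = FALSE]),
                      center = TRUE, scale. = scale.)
  rank <- sum(pc$sdev > 1e-12)
  if (n_components > rank)
    stop(sprintf("requested %d components but rank is %d", n_components, rank))
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  status <- factor(metadata$status)
  adj <- intersect(c("sex", "age"), names(metadata))
  tests <- lapply(seq_len(n_components), function(k) {
    sc <- scores[, k]
    mwu <- mwu_test(sc[status == levels(status)[2]],
                    sc[status == levels(status)[1]])
    fit_df <- data.frame(score = sc, status = status,
                         metadata[, adj, drop = FALSE])
    fit <- stats::lm(score ~ ., data = fit_df)
    cf <- summary(fit)$coefficients
    row <- grep(paste0("^status"), rownames(cf))[1]
    data.frame(component = paste0("PC", k), mwu_p = mwu$p,
               partial_beta = cf[row, "Estimate"],
               partial_p = cf[row, "Pr(>|t|)"])
  })
  list(scores = scores, var_explained = ve[seq_len(n_components)],
       tests = do.call(rbind, tests))
}

#' Sign-and-significance concordance with a reference DE direction list
#'
#' For a reference list of genes with expected directions (e.g. a published
#' consensus of disease-associated genes), reports how many are both
#' significant in a DE table and concordant in fold-change sign.
#'
#' @param de A `de_table`.
#' @param reference data.frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`).
#' @param alpha FDR significance threshold (default 0.05).
#' @return List: `n_reference`, `n_concordant`, `percent` (whole percent of
#'   the reference list).
#' @export
de_concordance <- function(de, reference, alpha = 0.05) {
  stopifnot(all(c("gene", "direction") %in% names(reference)))
  idx <- match(reference$gene, de$feature_id)
  sig <- !is.na(idx) & de$tested[idx] & !is.na(de$fdr[idx]) &
    de$fdr[idx] < alpha
  dir_obs <- ifelse(de$lfc[idx] > 0, "up", "down")
  conc <- sig & dir_obs == reference$direction
  n_ref <- nrow(reference)
  n_conc <- sum(conc, na.rm = TRUE)
  list(n_reference = n_ref, n_concordant = n_conc,
       percent = round(100 * n_conc / n_ref))
}
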