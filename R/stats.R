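#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation with a two-sided p-value from the exact-null
#' t reference: `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. This is the admission statistic for anticorrelation edges.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, finite, neither
#'   constant.
#' @return List with elements `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- as.numeric(stats::cor(x, y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. When both groups have at most
#' `exact_max` observations the two-sided p-value is computed by exhaustive
#' enumeration of all group assignments of the observed (possibly tied) rank
#' multiset: `p = P(|U - n1*n2/2| >= |u - n1*n2/2|)`. Otherwise the normal
#' approximation with tie correction is used, without continuity correction.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_max Largest group size for which the exact enumeration is
#'   used (default 8).
#' @return List with `u` (U statistic of `x`), `p`, and `method`.
#' @export
mwu_test <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    # enumerate all assignments of n1 ranks out of the observed multiset
    combs <- utils::combn(n1 + n2, n1)
    usum <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(usum - mu) >= abs(u - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    nn <- n1 + n2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    p <- min(p, 1)
    method <- "normal approximation with tie correction"
  }
  list(u = u, p = p, method = method)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment. Missing p-values stay missing and are excluded
#' from the number of tests `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, possibly with `NA`s.
#' @return Vector of q-values the same length as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}
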