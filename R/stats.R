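#' Two-sample Welch t-test on log2 intensities
#'
#' The shared test primitive for tissue-enrichment and tumor-vs-normal
#' comparisons.  Uses the unequal-variance (Welch-Satterthwaite) statistic
#' by default; `var_equal = TRUE` selects the pooled-variance Student
#' variant.  The effect size is reported as `log2_fc = mean(a) - mean(b)`,
#' i.e. inputs are expected on the log2 scale.
#'
#' Groups with fewer than two finite values yield an `NA` result (the
#' caller is expected to skip and log such proteins rather than crash).
#' When both groups are constant and equal the statistic is defined as 0
#' with p = 1; constant but unequal groups give p = 0.
#'
#' @param a,b Numeric vectors of log2 intensities.
#' @param var_equal Use pooled-variance Student t instead of Welch.
#' @return List with `log2_fc`, `t_stat`, `p_value`, `df`, `n_a`, `n_b`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  res <- row_welch_t(matrix(a, nrow = 1), matrix(b, nrow = 1),
                     var_equal = var_equal)
  list(log2_fc = res$log2_fc[1], t_stat = res$t_stat[1],
       p_value = res$p_value[1], df = res$df[1],
       n_a = length(a), n_b = length(b))
}

#' Row-wise Welch t-tests over two matrices
#'
#' Vectorized engine behind all per-protein testing: rows are proteins,
#' columns are the samples of each group, `NA`s are ignored per row.  Rows
#' with fewer than two observed values in either group get `NA` statistics.
#'
#' @param A,B Numeric matrices with the same number of rows (log2 scale).
#' @param var_equal Pooled-variance Student variant.
#' @return List of vectors `log2_fc`, `t_stat`, `df`, `p_value`, `n_a`,
#'   `n_b`, each of length `nrow(A)`.
#' @export
row_welch_t <- function(A, B, var_equal = FALSE) {
  if (nrow(A) != nrow(B)) stop("A and B must have the same number of rows")
  na <- rowSums(!is.na(A)); nb <- rowSums(!is.na(B))
  ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
  va <- rowSums((A - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((B - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  ok <- na >= 2 & nb >= 2
  fc <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / pmax(na - 1, 1) +
                   (vb / nb)^2 / pmax(nb - 1, 1))
  }
  t <- fc / sqrt(se2)
  # degenerate zero-variance rows: equal means -> null result, else extreme
  zv <- ok & se2 == 0
  t[zv & fc == 0] <- 0
  df[zv] <- na[zv] + nb[zv] - 2
  p <- 2 * pt(-abs(t), df)
  p[zv & fc == 0] <- 1
  p[zv & fc != 0] <- 0
  t[!ok] <- NA_real_; p[!ok] <- NA_real_; df[!ok] <- NA_real_
  fc[!ok & (na == 0 | nb == 0)] <- NA_real_
  list(log2_fc = fc, t_stat = t, df = df, p_value = p, n_a = na, n_b = nb)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; output order matches input order.  Thin wrapper
#' around `stats::p.adjust(method = "BH")` with input-range validation.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed, propagated).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean` over observed values, computed on the raw intensity
#' scale (the conventional replicate-QC metric).  Returns `NA` with a
#' warning signal if fewer than two observed values or a zero mean.
#'
#' @param x Numeric vector of raw intensities (NA = missing).
#' @return CV as a percentage, or NA if undefined.
#' @export
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * sd(x) / m
}

#' Pearson correlation over pairwise-complete observations
#'
#' @param x,y Paired numeric vectors (NA = missing).
#' @return Correlation in \[-1, 1\], or NA if fewer than two complete pairs.
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}
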