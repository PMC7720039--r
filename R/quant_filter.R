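#' Per-cancer quantifiability filter
#'
#' A protein is retained if it was quantified in at least `min_frac`
#' (default 40%) of the qualified samples of at least one cancer type
#' (tumor and normal pooled per tissue).  The threshold is inclusive
#' ("at least 40%").
#'
#' @param mat Intensity matrix (qualified samples only).
#' @param metadata Sample metadata matching the matrix columns.
#' @param min_frac Minimum observed fraction (default 0.4).
#' @return List with `matrix` (retained proteins only), `decisions`
#'   (data.frame: protein_id, retained, retaining_cancers as a
#'   comma-separated string, max_frac) and `fractions` (protein x cancer
#'   observed-fraction matrix).
#' @export
quantifiability_filter <- function(mat, metadata, min_frac = 0.4) {
  validate_intensity_matrix(mat)
  metadata <- read_metadata(metadata, matrix_samples = colnames(mat))
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0, 1]")
  tissues <- unique(metadata$tissue)
  n_per <- table(metadata$tissue)[tissues]
  if (any(n_per == 0)) stop("empty cancer cohort")
  frac <- sapply(tissues, function(tis) {
    ss <- metadata$sample_id[metadata$tissue == tis]
    rowMeans(!is.na(mat[, ss, drop = FALSE]))
  })
  pass <- frac >= min_frac
  retained <- rowSums(pass) > 0
  decisions <- data.frame(
    protein_id = rownames(mat),
    retained = retained,
    retaining_cancers = apply(pass, 1, function(z)
      paste(tissues[z], collapse = ",")),
    max_frac = apply(frac, 1, max),
    stringsAsFactors = FALSE)
  rownames(decisions) <- NULL
  list(matrix = mat[retained, , drop = FALSE],
       decisions = decisions, fractions = frac)
}

#' Two-branch missing-value imputation
#'
#' Fills every missing cell of a (filtered) intensity matrix by the
#' tissue-conditional rule used for DIA label-free matrices: for a missing
#' cell (protein p, sample s) with tissue t,
#' \itemize{
#'   \item if p is observed in fewer than half of the tissue-t samples
#'     (the protein is mostly absent there, a presence/absence dropout),
#'     fill with 5% of the lowest observed intensity above
#'     `min_intensity` (default 100) in sample s;
#'   \item otherwise (the protein is generally present, a stochastic
#'     dropout), fill with mean - 2*SD of the observed tissue-t values of
#'     p.
#' }
#' Tumor and normal samples of a tissue are pooled, consistent with the
#' tissue-as-single-entity convention.
#'
#' The scale on which the second branch's mean and SD are taken is
#' selectable.  The default, `scale = "log2"`, computes mean - 2*SD on
#' log2 intensities and fills with `2^(mean - 2*sd)` — the standard
#' left-censored down-shift for log-normal label-free abundances, which
#' always yields a positive fill in the low tail of that tissue's
#' distribution.  `scale = "raw"` takes the literal arithmetic on raw
#' intensities; because mean - 2*SD goes negative whenever the pooled CV
#' exceeds 50% (true for any strongly regulated protein), raw-scale fills
#' are floored at `floor_value` and can sit far below the data, which
#' distorts downstream variance estimates — see the vignette.
#'
#' A sample with no observed intensity above `min_intensity` when the
#' first branch fires gets the floor, with a warning.  Observed cells are
#' never altered; the second branch with a single observed value (SD
#' undefined) falls back to the first branch.
#'
#' @param mat Intensity matrix (raw scale), after quantifiability
#'   filtering.
#' @param metadata Sample metadata matching the matrix columns.
#' @param min_intensity Lower bound qualifying the per-sample minimum
#'   (default 100).
#' @param low_frac Branch cutoff: "less than half" (default 0.5).
#' @param scale Scale for the mean - 2*SD branch: "log2" (default) or
#'   "raw".
#' @param floor_value Positivity floor for raw-scale mean - 2*SD fills
#'   (default 1).
#' @return Complete intensity matrix (no missing cells).
#' @export
impute_missing <- function(mat, metadata, min_intensity = 100,
                           low_frac = 0.5, scale = c("log2", "raw"),
                           floor_value = 1) {
  scale <- match.arg(scale)
  validate_intensity_matrix(mat)
  metadata <- read_metadata(metadata, matrix_samples = colnames(mat))
  out <- mat
  # per-sample fill for branch A: 5% of the smallest supra-threshold value
  sample_fill <- apply(mat, 2, function(v) {
    v <- v[!is.na(v) & v > min_intensity]
    if (length(v) == 0) NA_real_ else 0.05 * min(v)
  })
  n_floored <- 0L
  for (tis in unique(metadata$tissue)) {
    ss <- metadata$sample_id[metadata$tissue == tis]
    sub <- mat[, ss, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    frac_obs <- n_obs / length(ss)
    vals <- if (scale == "log2") log2(sub) else sub
    mu <- rowMeans(vals, na.rm = TRUE)
    sdv <- sqrt(rowSums((vals - mu)^2, na.rm = TRUE) / pmax(n_obs - 1, 1))
    branch_b <- frac_obs >= low_frac & n_obs >= 2
    fill_b <- if (scale == "log2") 2^(mu - 2 * sdv) else
      pmax(mu - 2 * sdv, floor_value)
    for (s in ss) {
      mis <- is.na(sub[, s])
      if (!any(mis)) next
      b <- mis & branch_b
      a <- mis & !branch_b
      out[b, s] <- fill_b[b]
      if (any(a)) {
        fa <- sample_fill[s]
        if (is.na(fa)) {
          fa <- floor_value
          n_floored <- n_floored + sum(a)
        }
        out[a, s] <- fa
      }
    }
  }
  if (n_floored > 0)
    warning(n_floored, " cell(s) filled with the floor value: sample(s) ",
            "had no observed intensity above ", min_intensity)
  out
}
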