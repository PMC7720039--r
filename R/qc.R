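#' QC thresholds for sample qualification
#'
#' The five qualification criteria are named in prose in multi-cancer DIA
#' study designs ("at least 50% of proteins quantified", "similar median",
#' "correlation above 0.6", "similar distribution", "grouped in the PCA")
#' and need explicit operationalization; the defaults here are this
#' package's reading, every knob exposed:
#' \enumerate{
#'   \item fraction of the cohort-detected proteins quantified
#'     `>= min_frac_quantified`;
#'   \item sample median log2 intensity within `median_k_mad` MADs of the
#'     median of same-tissue sample medians;
#'   \item mean pairwise Pearson correlation (log2, pairwise-complete)
#'     against same-tissue samples `> min_corr`;
#'   \item two-sample Kolmogorov-Smirnov statistic of the sample's observed
#'     log2 values vs the pooled same-tissue values `<= max_ks_d`;
#'   \item on the first two principal components of the median-normalized
#'     log2 matrix (proteins observed in `>= pca_presence` of all samples,
#'     residual missing values mean-filled), the sample's nearest tissue
#'     centroid is its own tissue.
#' }
#'
#' @param min_frac_quantified Criterion 1 threshold (default 0.5).
#' @param median_k_mad Criterion 2 MAD multiplier (default 3).
#' @param min_corr Criterion 3 threshold (default 0.6).
#' @param max_ks_d Criterion 4 threshold (default 0.3).
#' @param pca_presence Criterion 5 protein-presence filter (default 0.8).
#' @param min_criteria Criteria needed to qualify (default 3 of 5).
#' @return List of class `pcp_qc_config`.
#' @export
qc_config <- function(min_frac_quantified = 0.5, median_k_mad = 3,
                      min_corr = 0.6, max_ks_d = 0.3, pca_presence = 0.8,
                      min_criteria = 3) {
  stopifnot(min_frac_quantified >= 0, min_frac_quantified <= 1,
            median_k_mad > 0, min_corr >= -1, min_corr <= 1,
            max_ks_d > 0, max_ks_d <= 1,
            pca_presence > 0, pca_presence <= 1,
            min_criteria >= 1, min_criteria <= 5)
  structure(list(min_frac_quantified = min_frac_quantified,
                 median_k_mad = median_k_mad, min_corr = min_corr,
                 max_ks_d = max_ks_d, pca_presence = pca_presence,
                 min_criteria = min_criteria),
            class = "pcp_qc_config")
}

#' Replicate-injection quality control
#'
#' Reproducibility metrics for repeated injections of the same sample:
#' per-protein coefficient of variation (raw intensity scale) within each
#' replicate group, the group median CV, and the full pairwise Pearson
#' correlation matrix (log2, pairwise-complete) over all replicate
#' injections.  Proteins observed in fewer than two injections of a group
#' have undefined CV and are excluded from that group's median (their
#' count is reported via `message()`).
#'
#' @param mat Intensity matrix.
#' @param replicate_groups Named list of sample-id character vectors, each
#'   of length >= 2.
#' @return List with `cv` (protein x group matrix of CV percentages),
#'   `median_cv` (named vector, percent), `correlations` (pairwise Pearson
#'   matrix over all listed samples).
#' @export
replicate_qc <- function(mat, replicate_groups) {
  validate_intensity_matrix(mat)
  if (is.null(names(replicate_groups)))
    names(replicate_groups) <- paste0("group", seq_along(replicate_groups))
  sizes <- lengths(replicate_groups)
  if (any(sizes < 2))
    stop("replicate group(s) with fewer than 2 samples: ",
         paste(names(replicate_groups)[sizes < 2], collapse = ", "))
  all_s <- unlist(replicate_groups, use.names = FALSE)
  missing_s <- setdiff(all_s, colnames(mat))
  if (length(missing_s) > 0)
    stop("sample id(s) not in matrix: ", paste(missing_s, collapse = ", "))
  cv <- sapply(replicate_groups, function(ss)
    apply(mat[, ss, drop = FALSE], 1, cv_percent))
  if (!is.matrix(cv)) cv <- matrix(cv, ncol = length(replicate_groups),
                                   dimnames = list(rownames(mat),
                                                   names(replicate_groups)))
  n_undef <- colSums(is.na(cv))
  if (any(n_undef > 0))
    message("proteins with undefined CV excluded from group medians: ",
            paste(sprintf("%s=%d", colnames(cv)[n_undef > 0],
                          n_undef[n_undef > 0]), collapse = ", "))
  med <- apply(cv, 2, median, na.rm = TRUE)
  corr <- cor(log2(mat[, all_s, drop = FALSE]),
              use = "pairwise.complete.obs")
  list(cv = cv, median_cv = med, correlations = corr)
}

#' Assess samples against the five qualification criteria
#'
#' Evaluates every sample within its own cancer-type cohort (tumor and
#' normal pooled per tissue; cohorts are independent of one another) and
#' applies the 3-of-5 qualification rule.  See [qc_config] for the
#' criteria.  A tissue with a single sample leaves criteria 2-4 undefined
#' (the sample then qualifies on criterion 1 alone, with a warning).
#'
#' @param mat Intensity matrix (raw scale, pre-imputation).
#' @param metadata Sample metadata ([read_metadata] contract).
#' @param config A [qc_config] object.
#' @return data.frame, one row per sample: the per-criterion values and
#'   flags, `n_criteria_passed` and `qualified`.
#' @export
assess_samples <- function(mat, metadata, config = qc_config()) {
  validate_intensity_matrix(mat)
  metadata <- read_metadata(metadata, matrix_samples = colnames(mat))
  mat <- mat[, metadata$sample_id, drop = FALSE]
  lm2 <- log2(mat)

  ## criterion 5 once, globally: tissue grouping on PC1/2
  pca_ok_all <- pca_tissue_grouping(mat, metadata, config$pca_presence)

  rep <- data.frame(sample_id = metadata$sample_id,
                    tissue = metadata$tissue, state = metadata$state,
                    frac_quantified = NA_real_, frac_ok = NA,
                    median_log2 = NA_real_, median_ok = NA,
                    mean_within_tissue_corr = NA_real_, corr_ok = NA,
                    ks_d = NA_real_, distribution_ok = NA,
                    pca_ok = pca_ok_all[metadata$sample_id],
                    stringsAsFactors = FALSE)

  for (tis in unique(metadata$tissue)) {
    rows <- which(metadata$tissue == tis)
    sub <- lm2[, rows, drop = FALSE]
    detected <- rowSums(!is.na(sub)) > 0
    n_det <- sum(detected)
    rep$frac_quantified[rows] <-
      colSums(!is.na(sub[detected, , drop = FALSE])) / max(n_det, 1)
    rep$frac_ok[rows] <-
      rep$frac_quantified[rows] >= config$min_frac_quantified
    meds <- apply(sub, 2, median, na.rm = TRUE)
    rep$median_log2[rows] <- meds
    if (length(rows) < 2) {
      warning("tissue '", tis, "' has a single sample; criteria 2-5 ",
              "undefined, sample qualifies on criterion 1 alone")
      rep$pca_ok[rows] <- NA
      next
    }
    ctr <- median(meds)
    tol <- config$median_k_mad * mad(meds) + 1e-8
    rep$median_ok[rows] <- abs(meds - ctr) <= tol
    cc <- cor(sub, use = "pairwise.complete.obs")
    diag(cc) <- NA
    rep$mean_within_tissue_corr[rows] <- rowMeans(cc, na.rm = TRUE)
    rep$corr_ok[rows] <- rep$mean_within_tissue_corr[rows] > config$min_corr
    for (j in seq_along(rows)) {
      xs <- sub[, j]; xs <- xs[!is.na(xs)]
      pooled <- sub[, -j, drop = FALSE]
      pooled <- pooled[!is.na(pooled)]
      rep$ks_d[rows[j]] <- suppressWarnings(
        as.numeric(ks.test(xs, pooled)$statistic))
    }
    rep$distribution_ok[rows] <- rep$ks_d[rows] <= config$max_ks_d
  }

  flags <- cbind(rep$frac_ok, rep$median_ok, rep$corr_ok,
                 rep$distribution_ok, rep$pca_ok)
  rep$n_criteria_passed <- rowSums(flags, na.rm = TRUE)
  singleton <- rowSums(!is.na(flags)) <= 1
  rep$qualified <- rep$n_criteria_passed >= config$min_criteria
  rep$qualified[singleton] <- flags[singleton, 1] %in% TRUE
  rownames(rep) <- NULL
  rep
}

# criterion 5: nearest tissue centroid on the first two PCs
pca_tissue_grouping <- function(mat, metadata, presence = 0.8) {
  keep <- rowMeans(!is.na(mat)) >= presence
  res <- setNames(rep(NA, ncol(mat)), colnames(mat))
  if (sum(keep) < 3 || length(unique(metadata$tissue)) < 2) return(res)
  m <- median_normalize(mat[keep, , drop = FALSE])
  lm2 <- log2(m)
  rm <- rowMeans(lm2, na.rm = TRUE)
  idx <- which(is.na(lm2), arr.ind = TRUE)
  if (nrow(idx) > 0) lm2[idx] <- rm[idx[, 1]]
  sc <- prcomp(t(lm2), center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  cent <- apply(sc, 2, function(v) tapply(v, metadata$tissue, mean))
  d2 <- outer(sc[, 1], cent[, 1], "-")^2 + outer(sc[, 2], cent[, 2], "-")^2
  nearest <- rownames(cent)[max.col(-d2)]
  setNames(nearest == metadata$tissue, colnames(mat))
}

#' Drop disqualified samples
#'
#' @param mat Intensity matrix.
#' @param metadata Sample metadata.
#' @param report Result of [assess_samples].
#' @return List with `matrix` and `metadata` restricted to qualified
#'   samples.
#' @export
filter_qualified <- function(mat, metadata, report) {
  keep <- report$sample_id[report$qualified]
  list(matrix = mat[, colnames(mat) %in% keep, drop = FALSE],
       metadata = metadata[metadata$sample_id %in% keep, , drop = FALSE])
}
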