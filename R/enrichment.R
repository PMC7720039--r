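#' Pairwise tissue comparison statistics
#'
#' For every ordered pair of tissues (t, u), per-protein Welch t-tests on
#' log2 intensities with tumor and normal samples pooled per tissue (the
#' tissue-as-single-entity convention), Benjamini-Hochberg adjusted across
#' proteins within each tissue pair.  Tissues with fewer than two samples
#' are excluded with a warning.
#'
#' @param mat Complete (post-imputation) intensity matrix.
#' @param metadata Sample metadata matching the matrix columns.
#' @param var_equal Use the Student variant instead of Welch.
#' @return Object of class `pcp_pairwise_stats`: list with `log2_fc` and
#'   `adj_p` (protein x tissue x tissue arrays; `log2_fc[p, t, u]` is
#'   mean(t) - mean(u)), `tissues`, `proteins`.
#' @export
pairwise_tissue_stats <- function(mat, metadata, var_equal = FALSE) {
  validate_intensity_matrix(mat)
  metadata <- read_metadata(metadata, matrix_samples = colnames(mat))
  counts <- table(metadata$tissue)
  small <- names(counts)[counts < 2]
  if (length(small) > 0)
    warning("tissue(s) with < 2 samples excluded: ",
            paste(small, collapse = ", "))
  tissues <- setdiff(unique(metadata$tissue), small)
  T <- length(tissues)
  if (T < 2) stop("need at least two tissues with >= 2 samples")
  lm2 <- log2(mat)
  cols <- lapply(tissues, function(tis)
    metadata$sample_id[metadata$tissue == tis])
  names(cols) <- tissues
  n_p <- nrow(mat)
  fc <- array(NA_real_, c(n_p, T, T),
              dimnames = list(rownames(mat), tissues, tissues))
  adj <- fc
  for (i in seq_len(T - 1)) {
    A <- lm2[, cols[[i]], drop = FALSE]
    for (j in seq(i + 1, T)) {
      res <- row_welch_t(A, lm2[, cols[[j]], drop = FALSE],
                         var_equal = var_equal)
      ap <- bh_adjust(res$p_value)
      fc[, i, j] <- res$log2_fc
      fc[, j, i] <- -res$log2_fc
      adj[, i, j] <- ap
      adj[, j, i] <- ap
    }
  }
  structure(list(log2_fc = fc, adj_p = adj, tissues = tissues,
                 proteins = rownames(mat)),
            class = "pcp_pairwise_stats")
}

#' Classify tissue-enriched proteins
#'
#' A protein is enriched in tissue t if its expression exceeds `fc_folds`
#' (default 4-fold, i.e. log2 fold change > log2(4)) with BH-adjusted
#' p < `alpha` against at least `coverage` (default 70%) of the other
#' tissue types.  The coverage count is `ceiling(coverage * (T - 1))`
#' comparisons — with 16 tissues, 11 of 15.
#'
#' @param stats Result of [pairwise_tissue_stats].
#' @param fc_folds Fold-change threshold on the linear scale (default 4).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param coverage Fraction of other tissues to beat, in (0, 1\]
#'   (default 0.7).
#' @return Object of class `pcp_enrichment`: list with `calls` (logical
#'   protein x tissue matrix), `n_pass` (integer matrix of comparisons
#'   won), `required` (comparisons needed), `multiplicity` (named integer
#'   vector: tissues each protein is enriched in) and `category` (named
#'   character, "1"/"2"/"3"/"4+" for enriched proteins).
#' @export
classify_enriched <- function(stats, fc_folds = 4, alpha = 0.05,
                              coverage = 0.7) {
  if (!inherits(stats, "pcp_pairwise_stats"))
    stop("stats must come from pairwise_tissue_stats()")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  T <- length(stats$tissues)
  required <- ceiling(coverage * (T - 1))
  thr <- log2(fc_folds)
  win <- (stats$log2_fc > thr) & (stats$adj_p < alpha)
  n_pass <- apply(win, c(1, 2), sum, na.rm = TRUE)
  calls <- n_pass >= required
  multiplicity <- rowSums(calls)
  category <- ifelse(multiplicity >= 4, "4+", as.character(multiplicity))
  category[multiplicity == 0] <- NA_character_
  structure(list(calls = calls, n_pass = n_pass, required = required,
                 multiplicity = setNames(multiplicity, stats$proteins),
                 category = setNames(category, stats$proteins)),
            class = "pcp_enrichment")
}

#' Multiplicity breakdown of enriched proteins
#'
#' @param enrichment Result of [classify_enriched].
#' @return data.frame: category ("1", "2", "3", "4+"), n, percent
#'   (of all enriched proteins; percentages sum to 100 up to rounding).
#' @export
multiplicity_breakdown <- function(enrichment) {
  cats <- c("1", "2", "3", "4+")
  cc <- enrichment$category[!is.na(enrichment$category)]
  n <- sapply(cats, function(k) sum(cc == k))
  total <- sum(n)
  data.frame(category = cats, n = as.integer(n),
             percent = if (total > 0) 100 * n / total else rep(0, 4),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tissue-group enrichment
#'
#' Applies the tissue-enrichment rule to anatomic groups: each group's
#' pooled samples are treated as the entity and compared against every
#' non-member tissue; a protein is group-enriched if it wins (fold change
#' > `fc_folds`, BH-adjusted p < `alpha`) against at least
#' `ceiling(coverage * n_comparators)` of them.
#'
#' @param mat Complete (post-imputation) intensity matrix.
#' @param metadata Sample metadata matching the matrix columns.
#' @param groups Named list of member-tissue vectors
#'   (default [pcp_tissue_groups]).
#' @param fc_folds,alpha,coverage As in [classify_enriched].
#' @param var_equal Use the Student variant instead of Welch.
#' @return Named list (one element per group) of enriched protein-id
#'   character vectors.
#' @export
group_enrichment <- function(mat, metadata, groups = pcp_tissue_groups(),
                             fc_folds = 4, alpha = 0.05, coverage = 0.7,
                             var_equal = FALSE) {
  validate_intensity_matrix(mat)
  metadata <- read_metadata(metadata, matrix_samples = colnames(mat))
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  bad <- setdiff(unlist(groups), pcp_tissues())
  if (length(bad) > 0)
    stop("unknown tissue(s) in groups: ", paste(bad, collapse = ", "))
  lm2 <- log2(mat)
  thr <- log2(fc_folds)
  tissues <- unique(metadata$tissue)
  out <- list()
  for (g in names(groups)) {
    members <- intersect(groups[[g]], tissues)
    gs <- metadata$sample_id[metadata$tissue %in% members]
    if (length(gs) == 0) stop("group '", g, "' has no samples")
    comparators <- setdiff(tissues, groups[[g]])
    comparators <- comparators[
      sapply(comparators, function(tt)
        sum(metadata$tissue == tt) >= 2)]
    required <- ceiling(coverage * length(comparators))
    A <- lm2[, gs, drop = FALSE]
    wins <- matrix(FALSE, nrow(mat), length(comparators))
    for (k in seq_along(comparators)) {
      us <- metadata$sample_id[metadata$tissue == comparators[k]]
      res <- row_welch_t(A, lm2[, us, drop = FALSE], var_equal = var_equal)
      wins[, k] <- res$log2_fc > thr & bh_adjust(res$p_value) < alpha
    }
    out[[g]] <- rownames(mat)[rowSums(wins, na.rm = TRUE) >= required]
  }
  out
}
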