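#' Tumor-vs-normal differential analysis per cancer type
#'
#' Per-protein Welch t-tests on log2 intensities between the tumor and
#' normal (NAT + normal) samples of each cancer type, BH-adjusted across
#' proteins within the cancer.  A protein is called `up` if
#' `log2_fc > log2(fc_folds)` (default: fold change > 2) with adjusted
#' p < `alpha`, `down` symmetrically, else `none`.  Cancers lacking two
#' tumor or two normal samples (e.g. a brain cohort with tumors only) are
#' skipped with a message; the skipped set is available as
#' `attr(result, "skipped_cancers")` and the analyzed set as
#' `attr(result, "analyzed_cancers")`.
#'
#' @param mat Complete (post-imputation) intensity matrix.
#' @param metadata Sample metadata matching the matrix columns.
#' @param cancers Cancer types (tissues) to analyze; default all present.
#' @param fc_folds Fold-change call threshold, linear scale (default 2).
#' @param alpha Adjusted-p call threshold (default 0.05).
#' @param var_equal Use the Student variant instead of Welch.
#' @return data.frame (long): protein_id, cancer, log2_fc, p, adj_p, call.
#' @export
tumor_vs_normal <- function(mat, metadata,
                            cancers = unique(metadata$tissue),
                            fc_folds = 2, alpha = 0.05,
                            var_equal = FALSE) {
  validate_intensity_matrix(mat)
  metadata <- read_metadata(metadata, matrix_samples = colnames(mat))
  lm2 <- log2(mat)
  thr <- log2(fc_folds)
  out <- list(); skipped <- character(0)
  for (cc in cancers) {
    ts <- metadata$sample_id[metadata$tissue == cc & metadata$group == "tumor"]
    ns <- metadata$sample_id[metadata$tissue == cc & metadata$group == "normal"]
    if (length(ts) < 2 || length(ns) < 2) {
      message("cancer '", cc, "' skipped: needs >= 2 tumor and >= 2 ",
              "normal samples (has ", length(ts), "/", length(ns), ")")
      skipped <- c(skipped, cc)
      next
    }
    res <- row_welch_t(lm2[, ts, drop = FALSE], lm2[, ns, drop = FALSE],
                       var_equal = var_equal)
    adj <- bh_adjust(res$p_value)
    call <- rep("none", nrow(mat))
    call[res$log2_fc > thr & adj < alpha] <- "up"
    call[res$log2_fc < -thr & adj < alpha] <- "down"
    call[is.na(res$p_value)] <- "none"
    out[[cc]] <- data.frame(protein_id = rownames(mat), cancer = cc,
                            log2_fc = res$log2_fc, p = res$p_value,
                            adj_p = adj, call = call,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0) stop("no cancer type had enough samples")
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "analyzed_cancers") <- names(out)
  attr(tab, "skipped_cancers") <- skipped
  tab
}

#' Cross-cancer aggregation of up-regulated proteins
#'
#' Proteins significantly elevated in more than `min_frac` (strictly;
#' default 40%) of the analyzed cancer types.  With 16 analyzed cancers
#' this requires up-calls in at least 7 (7 > 6.4).
#'
#' @param diff Result of [tumor_vs_normal].
#' @param min_frac Strict fraction threshold (default 0.4).
#' @param inclusive Use `>=` instead of the default strict `>`.
#' @return data.frame: protein_id, n_up, n_cancers, frac_up — sorted by
#'   n_up descending, ties by protein id.
#' @export
aggregate_cross_cancer <- function(diff, min_frac = 0.4,
                                   inclusive = FALSE) {
  cancers <- attr(diff, "analyzed_cancers")
  if (is.null(cancers)) cancers <- unique(diff$cancer)
  n_c <- length(cancers)
  if (n_c < 2) stop("need differential tables for at least 2 cancers")
  ups <- diff[diff$call == "up", , drop = FALSE]
  n_up <- table(factor(ups$protein_id))
  cut <- min_frac * n_c
  keep <- if (inclusive) n_up >= cut else n_up > cut
  res <- data.frame(protein_id = names(n_up)[keep],
                    n_up = as.integer(n_up[keep]),
                    n_cancers = rep.int(n_c, sum(keep)),
                    frac_up = as.numeric(n_up[keep]) / n_c,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$n_up, res$protein_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Uniquely overexpressed proteins
#'
#' Proteins called up in exactly one cancer type and nowhere else —
#' candidate cancer-type-discriminating markers.
#'
#' @param diff Result of [tumor_vs_normal].
#' @return data.frame: protein_id, cancer.
#' @export
unique_cancer_proteins <- function(diff) {
  ups <- diff[diff$call == "up", , drop = FALSE]
  n_up <- table(factor(ups$protein_id))
  uniq <- names(n_up)[n_up == 1]
  res <- ups[ups$protein_id %in% uniq, c("protein_id", "cancer")]
  res <- res[order(res$protein_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cancer-associated protein ids
#'
#' Proteins with an up or down call in at least one cancer type.
#'
#' @param diff Result of [tumor_vs_normal].
#' @return Sorted character vector of protein ids.
#' @export
cancer_associated_proteins <- function(diff) {
  sort(unique(diff$protein_id[diff$call != "none"]))
}

#' Cluster cancer-associated proteins into protein groups
#'
#' Per-protein Z-scoring of log2 intensities across all samples, followed
#' by agglomerative hierarchical clustering (Euclidean distance, Ward
#' linkage by default) cut at `k` clusters.  Clusters are labelled PG-1..
#' PG-k in descending order of their mean tumor-minus-normal log2
#' difference (a descriptive direction profile), which makes the labelling
#' deterministic.  Proteins with zero variance across samples cannot be
#' Z-scored and are dropped with a warning.
#'
#' @param mat Complete (post-imputation) intensity matrix.
#' @param metadata Sample metadata matching the matrix columns.
#' @param protein_ids Proteins to cluster (typically
#'   [cancer_associated_proteins]).
#' @param k Number of clusters (default 4).
#' @param method Linkage method for `stats::hclust`
#'   (default `"ward.D2"`).
#' @return data.frame: protein_id, group ("PG-1"..), plus attribute
#'   `"group_direction"` (named mean tumor-minus-normal Z difference per
#'   group).
#' @export
cluster_protein_groups <- function(mat, metadata, protein_ids, k = 4,
                                   method = "ward.D2") {
  validate_intensity_matrix(mat)
  metadata <- read_metadata(metadata, matrix_samples = colnames(mat))
  protein_ids <- intersect(protein_ids, rownames(mat))
  lm2 <- log2(mat[protein_ids, , drop = FALSE])
  sds <- apply(lm2, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance protein(s) dropped before ",
            "clustering")
    lm2 <- lm2[sds > 0, , drop = FALSE]
  }
  if (nrow(lm2) < k)
    stop("fewer proteins (", nrow(lm2), ") than clusters (", k, ")")
  z <- t(scale(t(lm2)))  # per-protein mean 0, SD 1
  cl <- cutree(hclust(dist(z), method = method), k = k)
  tum <- metadata$sample_id[metadata$group == "tumor"]
  nor <- metadata$sample_id[metadata$group == "normal"]
  dirn <- sapply(seq_len(k), function(g) {
    zz <- z[cl == g, , drop = FALSE]
    mean(zz[, tum, drop = FALSE]) - mean(zz[, nor, drop = FALSE])
  })
  ord <- order(-dirn, seq_len(k))  # deterministic tie-break by cluster idx
  lab <- character(k); lab[ord] <- paste0("PG-", seq_len(k))
  res <- data.frame(protein_id = rownames(z), group = lab[cl],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "group_direction") <- setNames(dirn[ord], paste0("PG-", seq_len(k)))
  res
}
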