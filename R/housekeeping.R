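#' Identify universally expressed (housekeeping) proteins
#'
#' A protein is called housekeeping if it was quantified (observed, not
#' imputed) in more than `min_frac` (strictly; default 90%) of the pooled
#' tumor samples *and* more than `min_frac` of the pooled normal samples
#' (NAT and normal combined).  `mode = "per_tissue"` instead requires the
#' presence fraction to exceed `min_frac` within every tissue's tumor
#' (resp. normal) samples — the stricter per-tissue-type reading.
#'
#' @param mat Intensity matrix, pre-imputation (qualified samples).
#' @param metadata Sample metadata matching the matrix columns.
#' @param min_frac Presence threshold, exceeded strictly (default 0.9).
#' @param mode "pooled" (default) or "per_tissue".
#' @return data.frame: protein_id, frac_tumor, frac_normal,
#'   universal_tumor, universal_normal, housekeeping.
#' @export
identify_housekeeping <- function(mat, metadata, min_frac = 0.9,
                                  mode = c("pooled", "per_tissue")) {
  mode <- match.arg(mode)
  validate_intensity_matrix(mat)
  metadata <- read_metadata(metadata, matrix_samples = colnames(mat))
  ts <- metadata$sample_id[metadata$group == "tumor"]
  ns <- metadata$sample_id[metadata$group == "normal"]
  if (length(ts) == 0 || length(ns) == 0)
    stop("need at least one tumor and one normal sample")
  frac_tumor <- rowMeans(!is.na(mat[, ts, drop = FALSE]))
  frac_normal <- rowMeans(!is.na(mat[, ns, drop = FALSE]))
  if (mode == "pooled") {
    ut <- frac_tumor > min_frac
    un <- frac_normal > min_frac
  } else {
    per_frac <- function(group) {
      md <- metadata[metadata$group == group, , drop = FALSE]
      tis_ok <- sapply(unique(md$tissue), function(tt) {
        ss <- md$sample_id[md$tissue == tt]
        rowMeans(!is.na(mat[, ss, drop = FALSE])) > min_frac
      })
      rowSums(tis_ok) == ncol(tis_ok)
    }
    ut <- per_frac("tumor"); un <- per_frac("normal")
  }
  data.frame(protein_id = rownames(mat),
             frac_tumor = frac_tumor, frac_normal = frac_normal,
             universal_tumor = ut, universal_normal = un,
             housekeeping = ut & un,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare a detected housekeeping set against a reference list
#'
#' @param summary Result of [identify_housekeeping].
#' @param reference_ids Character vector of reference housekeeping protein
#'   ids (e.g. an HPA-style housekeeping-gene list).
#' @return List: `n_detected`, `n_reference`, `n_overlap`,
#'   `frac_of_detected`, `frac_of_reference`, `overlap_ids`.
#' @export
compare_reference <- function(summary, reference_ids) {
  if (length(reference_ids) == 0) stop("empty reference list")
  det <- summary$protein_id[summary$housekeeping]
  ov <- intersect(det, reference_ids)
  list(n_detected = length(det), n_reference = length(reference_ids),
       n_overlap = length(ov),
       frac_of_detected = if (length(det) > 0)
         length(ov) / length(det) else NA_real_,
       frac_of_reference = length(ov) / length(reference_ids),
       overlap_ids = sort(ov))
}

#' Across-tissue expression stability
#'
#' Dispersion score separating constitutively flat proteins from
#' fluctuating ones: the coefficient of variation (percent) of the
#' per-tissue mean log2 intensities.  Low values indicate similar levels
#' across all tissues (the expected housekeeping behavior); high values
#' flag proteins whose abundance swings between tissues.
#'
#' @param mat Complete (post-imputation) intensity matrix.
#' @param metadata Sample metadata matching the matrix columns.
#' @param protein_ids Proteins to score (default: all rows).
#' @return Named numeric vector of dispersion scores (NA when fewer than
#'   two tissues are present).
#' @export
expression_stability <- function(mat, metadata, protein_ids = rownames(mat)) {
  validate_intensity_matrix(mat)
  metadata <- read_metadata(metadata, matrix_samples = colnames(mat))
  missing_p <- setdiff(protein_ids, rownames(mat))
  if (length(missing_p) > 0)
    stop("protein id(s) not in matrix: ",
         paste(head(missing_p, 5), collapse = ", "))
  lm2 <- log2(mat[protein_ids, , drop = FALSE])
  tissues <- unique(metadata$tissue)
  if (length(tissues) < 2)
    return(setNames(rep(NA_real_, length(protein_ids)), protein_ids))
  tm <- sapply(tissues, function(tis) {
    ss <- metadata$sample_id[metadata$tissue == tis]
    rowMeans(lm2[, ss, drop = FALSE], na.rm = TRUE)
  })
  if (!is.matrix(tm)) tm <- matrix(tm, nrow = 1,
                                   dimnames = list(protein_ids, tissues))
  setNames(apply(tm, 1, function(v) {
    m <- mean(v)
    if (m == 0) NA_real_ else 100 * sd(v) / abs(m)
  }), protein_ids)
}
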