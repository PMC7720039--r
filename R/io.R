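#' The 16-tissue closed vocabulary
#'
#' Tissue labels used throughout the package.  Each cancer-type cohort in a
#' pan-cancer DIA study corresponds to one tissue of origin, so "tissue" and
#' "cancer type" are used interchangeably.  The lung cohorts
#' (adenocarcinoma, squamous, small-cell) are kept as separate tissue types.
#'
#' @return Character vector of the 16 tissue labels.
#' @export
pcp_tissues <- function() {
  c("brain", "head_and_neck", "lung_adeno", "lung_squamous",
    "lung_small_cell", "esophagus", "stomach", "pancreas", "colon",
    "liver", "kidney", "bladder", "prostate", "breast", "ovary", "uterus")
}

#' Anatomic tissue groups
#'
#' The digestive, urinary and gynecologic tissue groups used for
#' group-level enrichment analysis.
#'
#' @return Named list of character vectors (group name -> member tissues).
#' @export
pcp_tissue_groups <- function() {
  list(
    digestive  = c("colon", "stomach", "esophagus", "pancreas", "liver"),
    urinary    = c("bladder", "prostate", "kidney"),
    gynecologic = c("breast", "uterus", "ovary")
  )
}

pcp_states <- function() c("tumor", "NAT", "normal")

#' Collapse disease states to the tumor/normal dichotomy
#'
#' NAT (tumor-matched normal adjacent tissue) and true normal tissue are
#' pooled as "normal" in every downstream analysis.
#'
#' @param state Character vector of states ("tumor", "NAT", "normal").
#' @return Character vector with values in c("tumor", "normal").
#' @export
sample_group <- function(state) {
  bad <- setdiff(unique(state), pcp_states())
  if (length(bad) > 0)
    stop("unknown disease state(s): ", paste(bad, collapse = ", "))
  ifelse(state == "tumor", "tumor", "normal")
}

## ---- intensity matrix ------------------------------------------------------

validate_intensity_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("intensity matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("intensity matrix must have protein row names and sample col names")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate protein ids in intensity matrix")
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample ids in intensity matrix")
  obs <- mat[!is.na(mat)]
  if (any(obs <= 0))
    stop("observed intensities must be strictly positive")
  invisible(mat)
}

#' Read a protein intensity matrix
#'
#' Reads a tab-delimited protein quantification table in either wide layout
#' (first column `protein_id`, one column per sample, empty cells missing)
#' or long "report" layout (columns `protein_id`, `sample_id`, `intensity`).
#' Cells that are blank, `NA` or `<= 0` are parsed as missing: a zero in a
#' label-free quantification export means "not quantified", and the
#' downstream imputation rules presuppose positive observed intensities.
#' The number of non-positive cells coerced to missing is reported via
#' `message()`.
#'
#' @param path Path to a TSV file.
#' @param layout `"wide"` (default) or `"long"`.
#' @return Numeric matrix, proteins x samples, `NA` = missing.
#' @export
read_intensity_matrix <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (layout == "wide") {
    if (ncol(df) < 2) stop("wide layout needs protein_id plus sample columns")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop("duplicate protein ids in ", path)
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- ids
  } else {
    need <- c("protein_id", "sample_id", "intensity")
    if (!all(need %in% names(df)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    key <- paste(df$protein_id, df$sample_id, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (protein, sample) pairs in long table")
    pids <- unique(as.character(df$protein_id))
    sids <- unique(as.character(df$sample_id))
    mat <- matrix(NA_real_, length(pids), length(sids),
                  dimnames = list(pids, sids))
    mat[cbind(match(df$protein_id, pids), match(df$sample_id, sids))] <-
      as.numeric(df$intensity)
  }
  if (any(mat < 0, na.rm = TRUE))
    stop("negative intensities in ", path)
  nz <- sum(mat <= 0, na.rm = TRUE)
  if (nz > 0) {
    message(nz, " non-positive intensity cells coerced to missing")
    mat[!is.na(mat) & mat <= 0] <- NA_real_
  }
  validate_intensity_matrix(mat)
  mat
}

#' Write a protein intensity matrix as wide TSV
#'
#' Missing values are written as empty cells; [read_intensity_matrix]
#' round-trips the result exactly (up to numeric printing precision of 15
#' significant digits).
#'
#' @param mat Intensity matrix.
#' @param path Output path.
#' @export
write_intensity_matrix <- function(mat, path) {
  validate_intensity_matrix(mat)
  df <- data.frame(protein_id = rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1][is.na(mat)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- metadata and annotation ----------------------------------------------

#' Read and validate a sample metadata table
#'
#' Requires columns `sample_id`, `patient_id`, `tissue`, `state`.  Tissue
#' labels must come from [pcp_tissues] and states from tumor/NAT/normal.  A
#' `group` column (tumor/normal dichotomy, see [sample_group]) is added.
#'
#' @param path TSV path, or a data.frame to validate in place.
#' @param matrix_samples Optional character vector of sample ids expected to
#'   match (the intensity matrix columns); mismatches raise an error naming
#'   the offending ids.
#' @return data.frame with columns sample_id, patient_id, tissue, state,
#'   group.
#' @export
read_metadata <- function(path, matrix_samples = NULL) {
  md <- if (is.data.frame(path)) path else
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue", "state")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  bad_t <- setdiff(unique(md$tissue), pcp_tissues())
  if (length(bad_t) > 0)
    stop("unknown tissue label(s): ", paste(bad_t, collapse = ", "))
  bad_s <- setdiff(unique(md$state), pcp_states())
  if (length(bad_s) > 0)
    stop("unknown disease state(s): ", paste(bad_s, collapse = ", "))
  if (!is.null(matrix_samples)) {
    only_md <- setdiff(md$sample_id, matrix_samples)
    only_mx <- setdiff(matrix_samples, md$sample_id)
    if (length(only_md) + length(only_mx) > 0)
      stop("sample id mismatch; metadata-only: {",
           paste(only_md, collapse = ", "), "}; matrix-only: {",
           paste(only_mx, collapse = ", "), "}")
  }
  md$group <- sample_group(md$state)
  md
}

#' Read a protein annotation flag table
#'
#' Column contract: `protein_id` plus any of the boolean flag columns
#' `is_drug_target`, `is_fda_approved_target`, `is_ct_antigen`,
#' `is_driver_gene`, `is_hpa_housekeeping`, and an optional free-text
#' `drugs` column.  Missing flag columns are filled with `FALSE`.
#'
#' @param path TSV path, or a data.frame to validate in place.
#' @return data.frame with protein_id, the five logical flags and drugs.
#' @export
read_annotation <- function(path) {
  ann <- if (is.data.frame(path)) path else
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(ann))
    stop("annotation table needs a protein_id column")
  ann$protein_id <- as.character(ann$protein_id)
  if (anyDuplicated(ann$protein_id))
    stop("duplicate protein ids in annotation table")
  flags <- c("is_drug_target", "is_fda_approved_target", "is_ct_antigen",
             "is_driver_gene", "is_hpa_housekeeping")
  for (f in flags) {
    if (!f %in% names(ann)) ann[[f]] <- FALSE
    ann[[f]] <- as.logical(ann[[f]])
    if (anyNA(ann[[f]])) stop("non-boolean values in flag column ", f)
  }
  if (!"drugs" %in% names(ann)) ann$drugs <- ""
  ann[, c("protein_id", flags, "drugs")]
}

## ---- normalization ---------------------------------------------------------

#' Median normalization across samples
#'
#' Reproduces the "cross run normalization using the sample median" setting
#' of DIA quantification software as an optional in-package step: every
#' sample's observed log2 intensities are shifted so that its median equals
#' the global median of the pre-normalization sample medians.  The
#' missingness pattern is untouched.
#'
#' @param mat Intensity matrix (raw scale).
#' @return Normalized intensity matrix, same dimensions and missingness.
#' @export
median_normalize <- function(mat) {
  validate_intensity_matrix(mat)
  nobs <- colSums(!is.na(mat))
  if (any(nobs == 0))
    stop("sample(s) with no observed values: ",
         paste(colnames(mat)[nobs == 0], collapse = ", "))
  lm2 <- log2(mat)
  med <- apply(lm2, 2, median, na.rm = TRUE)
  target <- median(med)
  out <- 2^sweep(lm2, 2, med - target, "-")
  dimnames(out) <- dimnames(mat)
  out
}
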