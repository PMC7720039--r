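#' Druggable candidate proteins
#'
#' The two-criterion filter for therapeutically targetable candidates:
#' (1) the protein is a target of an FDA-approved drug, and (2) it is
#' overexpressed (call `up`: fold change > 2, BH-adjusted p < 0.05 as set
#' in the differential stage) in at least one cancer type.  Sorted by
#' maximum log2 fold change descending, ties by protein id.
#'
#' @param diff Result of [tumor_vs_normal].
#' @param annotation Annotation table ([read_annotation] contract).
#' @return data.frame: protein_id, fda_approved, cancers_up
#'   (comma-separated), n_cancers_up, max_log2_fc, drugs.
#' @export
druggable_candidates <- function(diff, annotation) {
  annotation <- read_annotation(annotation)
  if (length(intersect(diff$protein_id, annotation$protein_id)) == 0)
    stop("no overlap between differential and annotation protein ids; ",
         "supply a protein_id mapping table")
  fda <- annotation$protein_id[annotation$is_fda_approved_target]
  ups <- diff[diff$call == "up" & diff$protein_id %in% fda, , drop = FALSE]
  if (nrow(ups) == 0)
    return(data.frame(protein_id = character(0), fda_approved = logical(0),
                      cancers_up = character(0), n_cancers_up = integer(0),
                      max_log2_fc = numeric(0), drugs = character(0),
                      stringsAsFactors = FALSE))
  sp <- split(ups, ups$protein_id)
  res <- data.frame(
    protein_id = names(sp),
    fda_approved = TRUE,
    cancers_up = vapply(sp, function(d)
      paste(sort(d$cancer), collapse = ","), character(1)),
    n_cancers_up = vapply(sp, nrow, integer(1)),
    max_log2_fc = vapply(sp, function(d) max(d$log2_fc), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  res$drugs <- annotation$drugs[match(res$protein_id,
                                      annotation$protein_id)]
  res <- res[order(-res$max_log2_fc, res$protein_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cancer/testis antigen calls
#'
#' CT antigens among the quantifiable proteins, and which of them are
#' elevated (call `up`) in at least one cancer type.
#'
#' @param diff Result of [tumor_vs_normal].
#' @param annotation Annotation table with `is_ct_antigen` flags.
#' @param quantified_ids Protein ids of the quantifiable set (post
#'   quantifiability filter).
#' @return data.frame: protein_id, detected, elevated, elevated_cancers
#'   (comma-separated) — one row per annotated CT antigen.
#' @export
ct_antigen_calls <- function(diff, annotation, quantified_ids) {
  annotation <- read_annotation(annotation)
  ct <- annotation$protein_id[annotation$is_ct_antigen]
  detected <- ct %in% quantified_ids
  ups <- diff[diff$call == "up" & diff$protein_id %in% ct, , drop = FALSE]
  elev <- vapply(ct, function(p)
    paste(sort(ups$cancer[ups$protein_id == p]), collapse = ","),
    character(1))
  data.frame(protein_id = ct, detected = detected,
             elevated = detected & nzchar(elev),
             elevated_cancers = ifelse(detected, elev, ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap of cancer-associated proteins with driver genes
#'
#' Joins the differential calls against driver-gene flags and reports, for
#' each cancer-associated driver product, the per-cancer direction profile
#' — supporting observations such as an oncogene product being *down* at
#' the protein level despite genomic activation.
#'
#' @param diff Result of [tumor_vs_normal].
#' @param annotation Annotation table with `is_driver_gene` flags.
#' @return data.frame: protein_id, n_up, n_down, cancers_up, cancers_down
#'   (comma-separated), direction ("up", "down" or "mixed").
#' @export
driver_overlap <- function(diff, annotation) {
  annotation <- read_annotation(annotation)
  drv <- annotation$protein_id[annotation$is_driver_gene]
  assoc <- intersect(cancer_associated_proteins(diff), drv)
  if (length(assoc) == 0)
    return(data.frame(protein_id = character(0), n_up = integer(0),
                      n_down = integer(0), cancers_up = character(0),
                      cancers_down = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  sub <- diff[diff$protein_id %in% assoc & diff$call != "none", ,
              drop = FALSE]
  sp <- split(sub, sub$protein_id)
  res <- data.frame(
    protein_id = names(sp),
    n_up = vapply(sp, function(d) sum(d$call == "up"), integer(1)),
    n_down = vapply(sp, function(d) sum(d$call == "down"), integer(1)),
    cancers_up = vapply(sp, function(d)
      paste(sort(d$cancer[d$call == "up"]), collapse = ","), character(1)),
    cancers_down = vapply(sp, function(d)
      paste(sort(d$cancer[d$call == "down"]), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  res$direction <- ifelse(res$n_up > 0 & res$n_down > 0, "mixed",
                          ifelse(res$n_up > 0, "up", "down"))
  res[order(res$protein_id), , drop = FALSE]
}
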