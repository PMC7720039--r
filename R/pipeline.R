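#' Pipeline configuration
#'
#' All stage thresholds of the full synthetic-cohort pipeline, validated
#' up front, plus the simulation configuration.  Every default mirrors the
#' analysis conventions of the individual stages: 40% quantifiability,
#' >90% presence for housekeeping, 4-fold / 70%-coverage enrichment,
#' 2-fold differential calls at BH-adjusted p < 0.05, strict >40%
#' cross-cancer aggregation, four protein groups.
#'
#' @param sim A [sim_config] object (the cohort to generate).
#' @param qc A [qc_config] object.
#' @param min_frac_quant Quantifiability threshold (default 0.4).
#' @param presence Housekeeping presence threshold (default 0.9).
#' @param fc_enrich,fc_diff Fold-change thresholds, linear scale.
#' @param alpha Adjusted-p threshold for both analyses (default 0.05).
#' @param coverage Enrichment coverage fraction (default 0.7).
#' @param cross_cancer_frac Cross-cancer aggregation fraction (default 0.4).
#' @param k_clusters Number of protein groups (default 4).
#' @param normalize Apply [median_normalize] before QC (default FALSE; the
#'   generator emulates data already median-normalized upstream).
#' @param var_equal Student instead of Welch t everywhere.
#' @return List of class `pcp_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_config(),
                            min_frac_quant = 0.4, presence = 0.9,
                            fc_enrich = 4, fc_diff = 2, alpha = 0.05,
                            coverage = 0.7, cross_cancer_frac = 0.4,
                            k_clusters = 4, normalize = FALSE,
                            var_equal = FALSE) {
  validate_sim_config(sim)
  stopifnot(inherits(qc, "pcp_qc_config"))
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!in01(min_frac_quant)) stop("min_frac_quant must be in [0, 1]")
  if (!in01(presence)) stop("presence must be in [0, 1]")
  if (!in01(alpha)) stop("alpha must be in [0, 1]")
  if (!in01(cross_cancer_frac)) stop("cross_cancer_frac must be in [0, 1]")
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1)
    stop("coverage must be in (0, 1]")
  if (fc_enrich <= 1 || fc_diff <= 1)
    stop("fold-change thresholds must exceed 1")
  if (k_clusters < 1) stop("k_clusters must be >= 1")
  structure(list(sim = sim, qc = qc, min_frac_quant = min_frac_quant,
                 presence = presence, fc_enrich = fc_enrich,
                 fc_diff = fc_diff, alpha = alpha, coverage = coverage,
                 cross_cancer_frac = cross_cancer_frac,
                 k_clusters = k_clusters, normalize = normalize,
                 var_equal = var_equal),
            class = "pcp_pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates simulate -> sample QC -> quantifiability filter ->
#' housekeeping detection -> imputation -> tissue enrichment ->
#' differential analysis -> cross-cancer aggregation, unique-protein and
#' protein-group clustering -> annotation joins, writing every stage's
#' output table plus a machine-readable run summary
#' (`summary.json`) into `out_dir`.  Fully deterministic given the
#' simulation seed.  A stage failure aborts with the failing stage named;
#' tables written before the failure are preserved.
#'
#' @param config A [pipeline_config] object.
#' @param out_dir Output directory (created if absent).
#' @return The run summary, invisibly (a named list; also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pcp_pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("simulate", generate_cohort(config$sim))
  annotation <- stage("simulate", simulate_annotation(cohort))
  stage("simulate", write_cohort(cohort, out_dir))
  write_tsv(annotation, file.path(out_dir, "annotation.tsv"))
  mat <- cohort$matrix; md <- cohort$metadata
  if (config$normalize) mat <- stage("normalize", median_normalize(mat))

  qc_rep <- stage("qc", assess_samples(mat, md, config$qc))
  write_tsv(qc_rep, file.path(out_dir, "qc_report.tsv"))
  fq <- filter_qualified(mat, md, qc_rep)

  qf <- stage("quantifiability_filter",
              quantifiability_filter(fq$matrix, fq$metadata,
                                     config$min_frac_quant))
  write_tsv(qf$decisions, file.path(out_dir, "quantifiability.tsv"))

  hk <- stage("housekeeping",
              identify_housekeeping(qf$matrix, fq$metadata,
                                    config$presence))
  write_tsv(hk, file.path(out_dir, "housekeeping.tsv"))
  hk_ref <- annotation$protein_id[annotation$is_hpa_housekeeping]
  hk_cmp <- stage("housekeeping", compare_reference(hk, hk_ref))

  imp <- stage("impute", impute_missing(qf$matrix, fq$metadata))
  stage("impute", write_intensity_matrix(
    imp, file.path(out_dir, "imputed_matrix.tsv")))

  pstats <- stage("enrichment",
                  pairwise_tissue_stats(imp, fq$metadata,
                                        var_equal = config$var_equal))
  enr <- stage("enrichment",
               classify_enriched(pstats, config$fc_enrich, config$alpha,
                                 config$coverage))
  mb <- multiplicity_breakdown(enr)
  enr_tab <- data.frame(protein_id = names(enr$multiplicity),
                        multiplicity = as.integer(enr$multiplicity),
                        category = as.character(enr$category),
                        tissues = apply(enr$calls, 1, function(z)
                          paste(colnames(enr$calls)[z], collapse = ",")),
                        stringsAsFactors = FALSE)
  write_tsv(enr_tab[enr_tab$multiplicity > 0, , drop = FALSE],
            file.path(out_dir, "enrichment.tsv"))
  groups_present <- Filter(function(m) any(m %in% fq$metadata$tissue),
                           pcp_tissue_groups())
  grp <- stage("enrichment",
               group_enrichment(imp, fq$metadata, groups = groups_present,
                                fc_folds = config$fc_enrich,
                                alpha = config$alpha,
                                coverage = config$coverage,
                                var_equal = config$var_equal))

  diff <- stage("differential",
                tumor_vs_normal(imp, fq$metadata,
                                fc_folds = config$fc_diff,
                                alpha = config$alpha,
                                var_equal = config$var_equal))
  write_tsv(diff, file.path(out_dir, "differential.tsv"))
  common <- stage("aggregate",
                  aggregate_cross_cancer(diff, config$cross_cancer_frac))
  write_tsv(common, file.path(out_dir, "common_up.tsv"))
  uniq <- unique_cancer_proteins(diff)
  write_tsv(uniq, file.path(out_dir, "unique_proteins.tsv"))
  assoc <- cancer_associated_proteins(diff)
  clusters <- NULL
  if (length(assoc) >= config$k_clusters) {
    clusters <- stage("cluster",
                      cluster_protein_groups(imp, fq$metadata, assoc,
                                             k = config$k_clusters))
    write_tsv(clusters, file.path(out_dir, "protein_groups.tsv"))
  }

  cand <- stage("annotate", druggable_candidates(diff, annotation))
  write_tsv(cand, file.path(out_dir, "druggable_candidates.tsv"))
  ct <- stage("annotate",
              ct_antigen_calls(diff, annotation, rownames(qf$matrix)))
  write_tsv(ct, file.path(out_dir, "ct_antigens.tsv"))
  drv <- stage("annotate", driver_overlap(diff, annotation))
  write_tsv(drv, file.path(out_dir, "driver_overlap.tsv"))

  per_cancer <- do.call(rbind, lapply(
    split(diff, diff$cancer), function(d)
      data.frame(cancer = d$cancer[1],
                 n_up = sum(d$call == "up"),
                 n_down = sum(d$call == "down"))))
  per_cancer <- per_cancer[order(per_cancer$cancer), , drop = FALSE]

  summary <- list(
    seed = config$sim$rng_seed,
    n_samples = ncol(cohort$matrix),
    n_qualified = sum(qc_rep$qualified),
    n_disqualified = sum(!qc_rep$qualified),
    n_proteins_total = nrow(cohort$matrix),
    n_proteins_retained = nrow(qf$matrix),
    n_housekeeping = sum(hk$housekeeping),
    housekeeping_reference_overlap = hk_cmp$n_overlap,
    n_enriched = sum(enr$multiplicity > 0),
    multiplicity_breakdown = setNames(as.list(mb$n), mb$category),
    group_enriched = lapply(grp, length),
    analyzed_cancers = attr(diff, "analyzed_cancers"),
    skipped_cancers = attr(diff, "skipped_cancers"),
    per_cancer_calls = setNames(
      lapply(seq_len(nrow(per_cancer)), function(i)
        list(up = per_cancer$n_up[i], down = per_cancer$n_down[i])),
      per_cancer$cancer),
    n_cancer_associated = length(assoc),
    n_common_up = nrow(common),
    n_unique = nrow(uniq),
    protein_group_sizes = if (!is.null(clusters))
      as.list(table(clusters$group)) else NULL,
    n_druggable_candidates = nrow(cand),
    n_ct_detected = sum(ct$detected),
    n_ct_elevated = sum(ct$elevated),
    n_driver_overlap = nrow(drv),
    config = list(min_frac_quant = config$min_frac_quant,
                  presence = config$presence,
                  fc_enrich = config$fc_enrich,
                  fc_diff = config$fc_diff, alpha = config$alpha,
                  coverage = config$coverage,
                  cross_cancer_frac = config$cross_cancer_frac,
                  k_clusters = config$k_clusters,
                  normalize = config$normalize,
                  var_equal = config$var_equal,
                  qc = unclass(config$qc),
                  sim = unclass(config$sim)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
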