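#' Default per-tissue cohort sizes
#'
#' Tumor / normal sample counts per tissue for the default simulated
#' cohort, mirroring a 16-cancer-type pan-cancer design (246 samples:
#' 129 tumors, 117 NAT/normal; brain has tumors only).
#'
#' @return data.frame with columns tissue, n_tumor, n_normal.
#' @export
default_cohort_sizes <- function() {
  data.frame(
    tissue = pcp_tissues(),
    n_tumor  = c(12L, 6L, 10L, 8L, 6L, 7L, 9L, 8L, 11L, 8L, 10L, 11L, 7L, 5L, 7L, 4L),
    n_normal = c(0L,  6L, 10L, 8L, 6L, 7L, 9L, 8L, 11L, 8L, 10L, 11L, 7L, 5L, 7L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_cohort].  The
#' intensity model is log-normal: per-protein baseline log2 abundances are
#' drawn from `N(baseline_log2_mean, baseline_log2_sd)`, planted effects
#' are added on the log2 scale (so they are exact fold changes in
#' expectation), residual within-tissue noise has SD `noise_log2_sd`, and
#' intensities are `2^x`.  Missingness is intensity-dependent: a logistic
#' dropout curve in latent log2 intensity with slope
#' `missing_intensity_slope`, centered so the marginal missing fraction
#' equals `missing_rate` (slope 0 gives uniform missingness).
#'
#' Planted structure, all recorded in the returned ground truth:
#' \itemize{
#'   \item housekeeping proteins: high, tight baselines
#'     (`+hk_log2_boost`, SD/4) so intensity-dependent dropout rarely
#'     touches them — emulating ribosomal/cytoskeletal proteins;
#'   \item tissue-enriched proteins: `+enrichment_log2_effect` in 1, 2, 3
#'     or 4 tissues (counts per multiplicity via `n_tissue_enriched`);
#'   \item per-cancer up/down regulated proteins:
#'     `+/- cancer_log2_effect` in that cancer's tumor samples only;
#'   \item outlier samples: missingness raised to
#'     `outlier_missing_rate`, a global `+/- outlier_log2_shift` median
#'     shift, and half of the values replaced by independent draws
#'     (decorrelation) — built to fail at least three of the five sample
#'     qualification criteria.
#' }
#'
#' @param samples_per_tissue data.frame(tissue, n_tumor, n_normal);
#'   defaults to [default_cohort_sizes].
#' @param n_proteins Number of proteins.
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 abundance
#'   distribution across proteins.
#' @param noise_log2_sd Residual within-tissue SD (log2 units).
#' @param n_housekeeping Number of planted housekeeping proteins.
#' @param hk_log2_boost Log2 abundance boost for housekeeping proteins.
#' @param n_tissue_enriched Named counts per multiplicity category
#'   `c("1"=,"2"=,"3"=,"4+"=)`; "4+" proteins are enriched in 4 tissues.
#' @param enrichment_log2_effect Planted enrichment effect (log2; >= 2
#'   means > 4-fold).
#' @param n_cancer_up,n_cancer_down Planted up-/down-regulated proteins
#'   per cancer type.
#' @param cancer_log2_effect Planted tumor-vs-normal effect (log2).
#' @param missing_rate Marginal missing fraction in \[0, 1\].
#' @param missing_intensity_slope Logistic dropout slope per log2 unit
#'   (0 = intensity-independent).
#' @param n_outlier_samples Number of planted low-quality samples.
#' @param outlier_missing_rate,outlier_log2_shift Outlier corruption knobs.
#' @param rng_seed Integer seed; equal seeds give byte-identical cohorts.
#' @return Object of class `pcp_sim_config` (a validated list).
#' @export
sim_config <- function(samples_per_tissue = default_cohort_sizes(),
                       n_proteins = 2000,
                       baseline_log2_mean = 14,
                       baseline_log2_sd = 2,
                       noise_log2_sd = 0.5,
                       n_housekeeping = 200,
                       hk_log2_boost = 2,
                       n_tissue_enriched = c("1" = 50, "2" = 20,
                                             "3" = 10, "4+" = 5),
                       enrichment_log2_effect = 3,
                       n_cancer_up = 30,
                       n_cancer_down = 30,
                       cancer_log2_effect = 2,
                       missing_rate = 0.05,
                       missing_intensity_slope = 1,
                       n_outlier_samples = 5,
                       outlier_missing_rate = 0.65,
                       outlier_log2_shift = 2,
                       rng_seed = 1) {
  cfg <- list(samples_per_tissue = samples_per_tissue,
              n_proteins = as.integer(n_proteins),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              noise_log2_sd = noise_log2_sd,
              n_housekeeping = as.integer(n_housekeeping),
              hk_log2_boost = hk_log2_boost,
              n_tissue_enriched = n_tissue_enriched,
              enrichment_log2_effect = enrichment_log2_effect,
              n_cancer_up = as.integer(n_cancer_up),
              n_cancer_down = as.integer(n_cancer_down),
              cancer_log2_effect = cancer_log2_effect,
              missing_rate = missing_rate,
              missing_intensity_slope = missing_intensity_slope,
              n_outlier_samples = as.integer(n_outlier_samples),
              outlier_missing_rate = outlier_missing_rate,
              outlier_log2_shift = outlier_log2_shift,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "pcp_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  spt <- cfg$samples_per_tissue
  if (!is.data.frame(spt) ||
      !all(c("tissue", "n_tumor", "n_normal") %in% names(spt)))
    stop("samples_per_tissue needs columns tissue, n_tumor, n_normal")
  bad <- setdiff(spt$tissue, pcp_tissues())
  if (length(bad) > 0)
    stop("unknown tissue(s) in samples_per_tissue: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(spt$tissue)) stop("duplicate tissues in samples_per_tissue")
  counts <- c(cfg$n_proteins, cfg$n_housekeeping, cfg$n_tissue_enriched,
              cfg$n_cancer_up, cfg$n_cancer_down, cfg$n_outlier_samples,
              spt$n_tumor, spt$n_normal)
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (!all(names(cfg$n_tissue_enriched) %in% c("1", "2", "3", "4+")))
    stop("n_tissue_enriched names must be among '1','2','3','4+'")
  n_cancers <- nrow(spt)
  n_planted <- cfg$n_housekeeping + sum(cfg$n_tissue_enriched) +
    n_cancers * (cfg$n_cancer_up + cfg$n_cancer_down)
  if (n_planted > cfg$n_proteins)
    stop("infeasible config: planted signal proteins (", n_planted,
         ") exceed n_proteins (", cfg$n_proteins, ")")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  if (cfg$noise_log2_sd < 0 || cfg$baseline_log2_sd < 0)
    stop("SDs must be non-negative")
  invisible(cfg)
}

# center the logistic dropout curve so the marginal miss rate is hit
calibrate_dropout <- function(x, slope, rate) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  if (slope == 0) return(NA_real_)  # caller uses constant rate
  f <- function(m) mean(plogis(slope * (m - x))) - rate
  uniroot(f, lower = min(x) - 50, upper = max(x) + 50, tol = 1e-10)$root
}

#' Generate a synthetic pan-cancer cohort with planted ground truth
#'
#' See [sim_config] for the generative model.  Returns the raw-scale
#' intensity matrix (NA = missing), the sample metadata and a ground-truth
#' list naming every planted housekeeping / enriched / regulated protein
#' and every planted outlier sample.
#'
#' @param config A `pcp_sim_config` object.
#' @return List with elements `matrix` (proteins x samples, raw
#'   intensities), `metadata` (data.frame), `truth` (list:
#'   `housekeeping_ids`, `enriched_map`, `cancer_up_map`,
#'   `cancer_down_map`, `outlier_sample_ids`).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  spt <- config$samples_per_tissue
  tissues <- spt$tissue

  ## ---- samples -------------------------------------------------------
  md_list <- lapply(seq_len(nrow(spt)), function(i) {
    tis <- spt$tissue[i]; nt <- spt$n_tumor[i]; nn <- spt$n_normal[i]
    state_n <- rep("NAT", nn)
    if (tis == "prostate") state_n <- rep("normal", nn)
    if (tis == "ovary" && nn > 0)
      state_n[max(1, nn - 4):nn] <- "normal"
    data.frame(
      sample_id = c(sprintf("%s_T%02d", tis, seq_len(nt)),
                    sprintf("%s_N%02d", tis, seq_len(nn))),
      patient_id = sprintf("%s_P%02d", tis, c(seq_len(nt), seq_len(nn))),
      tissue = tis,
      state = c(rep("tumor", nt), state_n),
      stringsAsFactors = FALSE)
  })
  md <- do.call(rbind, md_list)
  md$group <- sample_group(md$state)
  n_s <- nrow(md)

  ## ---- protein id blocks ----------------------------------------------
  n_p <- config$n_proteins
  pids <- sprintf("P%05d", seq_len(n_p))
  cursor <- 0L
  take <- function(k) {
    idx <- cursor + seq_len(k); cursor <<- cursor + k; idx
  }
  hk_idx <- take(config$n_housekeeping)
  enr_cat <- config$n_tissue_enriched
  mult_of <- c("1" = 1L, "2" = 2L, "3" = 3L, "4+" = 4L)
  enriched_map <- list()
  enr_idx <- integer(0)
  for (cat in names(enr_cat)) {
    k <- enr_cat[[cat]]
    if (k == 0) next
    idx <- take(k)
    enr_idx <- c(enr_idx, idx)
    m <- mult_of[[cat]]
    for (i in idx)
      enriched_map[[pids[i]]] <- sort(sample(tissues, m))
  }
  # tumor-vs-normal effects are only meaningful where normals exist; a
  # normal-free cohort (e.g. brain) gets none planted
  cancer_up_map <- list(); cancer_down_map <- list()
  for (ti in seq_along(tissues)) {
    if (spt$n_normal[ti] == 0) next
    tis <- tissues[ti]
    for (i in take(config$n_cancer_up))
      cancer_up_map[[pids[i]]] <- tis
    for (i in take(config$n_cancer_down))
      cancer_down_map[[pids[i]]] <- tis
  }

  ## ---- latent log2 matrix ---------------------------------------------
  base <- rnorm(n_p, config$baseline_log2_mean, config$baseline_log2_sd)
  base[hk_idx] <- rnorm(length(hk_idx),
                        config$baseline_log2_mean + config$hk_log2_boost,
                        config$baseline_log2_sd / 4)
  x <- matrix(base, n_p, n_s) +
    matrix(rnorm(n_p * n_s, 0, config$noise_log2_sd), n_p, n_s)
  rownames(x) <- pids; colnames(x) <- md$sample_id

  for (pid in names(enriched_map)) {
    cols <- md$tissue %in% enriched_map[[pid]]
    x[pid, cols] <- x[pid, cols] + config$enrichment_log2_effect
  }
  tumor_cols <- md$group == "tumor"
  for (pid in names(cancer_up_map)) {
    cols <- tumor_cols & md$tissue == cancer_up_map[[pid]]
    x[pid, cols] <- x[pid, cols] + config$cancer_log2_effect
  }
  for (pid in names(cancer_down_map)) {
    cols <- tumor_cols & md$tissue == cancer_down_map[[pid]]
    x[pid, cols] <- x[pid, cols] - config$cancer_log2_effect
  }

  ## ---- outlier samples -------------------------------------------------
  tissue_n <- table(md$tissue)
  big <- md$sample_id[tissue_n[md$tissue] >= 6]
  n_out <- min(config$n_outlier_samples, length(big))
  outlier_ids <- if (n_out > 0) sort(sample(big, n_out)) else character(0)
  for (k in seq_along(outlier_ids)) {
    s <- outlier_ids[k]
    shift <- config$outlier_log2_shift * if (k %% 2 == 1) 1 else -1
    x[, s] <- x[, s] + shift
    repl <- sample(n_p, floor(n_p / 2))
    x[repl, s] <- rnorm(length(repl), config$baseline_log2_mean + shift,
                        sqrt(config$baseline_log2_sd^2 +
                             config$noise_log2_sd^2))
  }

  ## ---- intensity-dependent dropout ------------------------------------
  miss <- matrix(FALSE, n_p, n_s, dimnames = dimnames(x))
  slope <- config$missing_intensity_slope
  reg_cols <- !(md$sample_id %in% outlier_ids)
  if (config$missing_rate > 0) {
    if (slope == 0) {
      p_miss <- matrix(config$missing_rate, n_p, sum(reg_cols))
    } else {
      m0 <- calibrate_dropout(as.vector(x[, reg_cols]), slope,
                              config$missing_rate)
      p_miss <- plogis(slope * (m0 - x[, reg_cols, drop = FALSE]))
    }
    miss[, reg_cols] <- matrix(runif(n_p * sum(reg_cols)), n_p) < p_miss
  }
  # outlier dropout is uniform, not intensity-dependent: a degraded sample
  # loses values across the whole intensity range, and upper-tail-only
  # censoring would mask the planted median shift in the observed values
  for (s in outlier_ids)
    miss[, s] <- runif(n_p) < config$outlier_missing_rate

  mat <- 2^x
  mat[miss] <- NA_real_

  truth <- list(housekeeping_ids = pids[hk_idx],
                enriched_map = enriched_map,
                cancer_up_map = cancer_up_map,
                cancer_down_map = cancer_down_map,
                outlier_sample_ids = outlier_ids)
  list(matrix = mat, metadata = md, truth = truth)
}

#' Build a synthetic annotation table from planted ground truth
#'
#' Produces the annotation flag table ([read_annotation] contract) that the
#' candidate-filtering stage consumes, derived deterministically from a
#' generated cohort's ground truth so that candidate lists have a known
#' answer: a housekeeping reference list with partial overlap and decoys,
#' FDA-approved drug-target flags on a subset of planted up-regulated
#' proteins plus unregulated decoys, cancer/testis-antigen flags (by
#' default 21 antigens of which 20 are planted up somewhere), and driver
#' flags on a mix of regulated and unregulated proteins.
#'
#' Selection is deterministic (sorted-id order), so the table is a pure
#' function of the cohort.
#'
#' @param cohort Result of [generate_cohort].
#' @param n_hk_ref,n_hk_decoy Reference housekeeping list composition.
#' @param n_fda_targets,n_target_decoys FDA-approved drug-target flags on
#'   planted-up proteins / unregulated decoys.
#' @param n_ct,n_ct_null CT antigens total and how many of them are *not*
#'   planted up anywhere.
#' @param n_driver_reg,n_driver_null Driver flags on regulated /
#'   unregulated proteins.
#' @return Annotation data.frame (see [read_annotation]).
#' @export
simulate_annotation <- function(cohort,
                                n_hk_ref = 150, n_hk_decoy = 50,
                                n_fda_targets = 100, n_target_decoys = 20,
                                n_ct = 21, n_ct_null = 1,
                                n_driver_reg = 60, n_driver_null = 40) {
  truth <- cohort$truth
  pids <- rownames(cohort$matrix)
  up <- sort(names(truth$cancer_up_map))
  down <- sort(names(truth$cancer_down_map))
  hk <- sort(truth$housekeeping_ids)
  null_ids <- sort(setdiff(pids, c(up, down, hk, names(truth$enriched_map))))
  first <- function(v, k) head(v, min(k, length(v)))

  ann <- data.frame(protein_id = pids, stringsAsFactors = FALSE)
  hk_ref <- c(first(hk, n_hk_ref), first(null_ids, n_hk_decoy))
  ann$is_hpa_housekeeping <- pids %in% hk_ref

  fda <- first(up, n_fda_targets)
  decoy_pool <- setdiff(null_ids, hk_ref)
  decoys <- first(decoy_pool, n_target_decoys)
  ann$is_fda_approved_target <- pids %in% c(fda, decoys)
  ann$is_drug_target <- ann$is_fda_approved_target
  ann$drugs <- ifelse(ann$is_drug_target,
                      paste0("drug_", ann$protein_id), "")

  k_ct <- max(0, n_ct - n_ct_null)
  ct_up <- if (k_ct > 0 && length(up) > 0)
    up[unique(round(seq(1, length(up), length.out = min(k_ct, length(up)))))]
  else character(0)
  ct_null <- first(rev(decoy_pool), n_ct_null)
  ann$is_ct_antigen <- pids %in% c(ct_up, ct_null)

  drv <- c(first(c(rev(down), up), n_driver_reg),
           first(setdiff(null_ids, c(hk_ref, decoys, ct_null)),
                 n_driver_null))
  ann$is_driver_gene <- pids %in% drv
  read_annotation(ann)
}

#' Write a generated cohort to disk
#'
#' Writes the wide-TSV intensity matrix, the metadata TSV and the
#' ground-truth JSON into a directory.
#'
#' @param cohort Result of [generate_cohort].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "intensity_matrix.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_intensity_matrix(cohort$matrix, paths[["matrix"]])
  write.table(cohort$metadata, paths[["metadata"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(paths)
}
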