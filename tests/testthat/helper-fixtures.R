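# shared fixtures and independent oracles, built in code at test time

# independent brute-force BH step-up: sort, scale by m/rank, cumulative
# minimum from the largest p, unsort
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# a small cohort: few tissues, modest protein count, fast to generate
small_sim <- function(seed = 1, n_tissues = 4, n_tumor = 6, n_normal = 6,
                      n_proteins = 300, ...) {
  spt <- default_cohort_sizes()[seq(2, 1 + n_tissues), , drop = FALSE]
  spt$n_tumor <- as.integer(n_tumor)
  spt$n_normal <- as.integer(n_normal)
  args <- list(samples_per_tissue = spt, n_proteins = n_proteins,
               n_housekeeping = 20,
               n_tissue_enriched = c("1" = 8, "2" = 4, "3" = 2, "4+" = 1),
               n_cancer_up = 5, n_cancer_down = 5,
               n_outlier_samples = 0, rng_seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# hand-built 2-tissue matrix with controlled missingness for filter and
# imputation fixtures: 6 liver samples + 5 stomach samples
tiny_two_tissue <- function() {
  liver <- sprintf("liver_T%02d", 1:6)
  stomach <- sprintf("stomach_T%02d", 1:5)
  md <- data.frame(
    sample_id = c(liver, stomach),
    patient_id = paste0("p", 1:11),
    tissue = rep(c("liver", "stomach"), c(6, 5)),
    state = "tumor", stringsAsFactors = FALSE)
  mat <- matrix(1000, 4, 11,
                dimnames = list(paste0("P", 1:4), md$sample_id))
  list(matrix = mat, metadata = md, liver = liver, stomach = stomach)
}

# four planted expression archetypes on top of a null cohort:
# normal-high, pan-tumor-high, and two complementary tissue-restricted
# patterns; returns matrix, metadata and the archetype labels
archetype_cohort <- function(seed = 5, per_group = 40, effect = 2,
                             noise = 0.4) {
  spt <- default_cohort_sizes()[2:7, ]
  spt$n_tumor <- 6L; spt$n_normal <- 6L
  cfg <- sim_config(samples_per_tissue = spt,
                    n_proteins = 4 * per_group, n_housekeeping = 0,
                    n_tissue_enriched = c("1" = 0), n_cancer_up = 0,
                    n_cancer_down = 0, missing_rate = 0,
                    n_outlier_samples = 0, noise_log2_sd = noise,
                    rng_seed = seed)
  co <- generate_cohort(cfg)
  md <- co$metadata
  lm2 <- log2(co$matrix)
  arch <- rep(1:4, each = per_group)
  tum <- md$group == "tumor"
  half <- md$tissue %in% spt$tissue[1:3]
  lm2[arch == 1, !tum] <- lm2[arch == 1, !tum] + effect
  lm2[arch == 2, tum] <- lm2[arch == 2, tum] + effect
  lm2[arch == 3, half] <- lm2[arch == 3, half] + effect
  lm2[arch == 4, !half] <- lm2[arch == 4, !half] + effect
  list(matrix = 2^lm2, metadata = md, labels = arch)
}

# hand-built pairwise-stats object where each protein's comparisons
# against the other tissues are given for the FIRST tissue only
fake_stats <- function(fc_rows, adjp_rows, tissues = pcp_tissues()) {
  T <- length(tissues)
  pids <- rownames(fc_rows)
  fc <- array(NA_real_, c(nrow(fc_rows), T, T),
              dimnames = list(pids, tissues, tissues))
  adj <- fc
  fc[, 1, -1] <- fc_rows;  fc[, -1, 1] <- -fc_rows
  adj[, 1, -1] <- adjp_rows; adj[, -1, 1] <- adjp_rows
  structure(list(log2_fc = fc, adj_p = adj, tissues = tissues,
                 proteins = pids),
            class = "pcp_pairwise_stats")
}

# planted (protein, tissue) enrichment pairs as "pid tissue" strings
planted_enrichment_pairs <- function(truth) {
  unlist(lapply(names(truth$enriched_map), function(p)
    paste(p, truth$enriched_map[[p]])))
}

called_enrichment_pairs <- function(enr) {
  idx <- which(enr$calls, arr.ind = TRUE)
  paste(rownames(enr$calls)[idx[, 1]], colnames(enr$calls)[idx[, 2]])
}

planted_diff_pairs <- function(truth) {
  list(up = paste(names(truth$cancer_up_map), unlist(truth$cancer_up_map)),
       down = paste(names(truth$cancer_down_map),
                    unlist(truth$cancer_down_map)))
}
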