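# a hand-built differential table over n cancers
fake_diff <- function(up_counts, n_cancers = 16) {
  cancers <- pcp_tissues()[seq_len(n_cancers)]
  rows <- do.call(rbind, lapply(names(up_counts), function(p) {
    k <- up_counts[[p]]
    data.frame(protein_id = p, cancer = cancers,
               log2_fc = c(rep(2, k), rep(0, n_cancers - k)),
               p = 0.001, adj_p = c(rep(0.01, k), rep(0.9, n_cancers - k)),
               call = c(rep("up", k), rep("none", n_cancers - k)),
               stringsAsFactors = FALSE)
  }))
  attr(rows, "analyzed_cancers") <- cancers
  rows
}

test_that("calls require both the fold-change and the significance gate", {
  t <- tiny_two_tissue()
  md <- t$metadata
  md$state[md$tissue == "liver"][4:6] <- "NAT"
  set.seed(1)
  mat <- matrix(2^rnorm(11 * 60, 12, 0.01), 60,
                dimnames = list(sprintf("P%02d", 1:60), md$sample_id))
  tum <- md$sample_id[md$tissue == "liver" & md$state == "tumor"]
  nor <- md$sample_id[md$tissue == "liver" & md$state == "NAT"]
  mat["P01", tum] <- mat["P01", tum] * 2^1.5   # clear up call
  mat["P02", tum] <- mat["P02", tum] * 2^0.8   # significant, FC too small
  mat["P03", nor] <- mat["P03", nor] * 2^1.5   # clear down call
  res <- suppressMessages(tumor_vs_normal(mat, md, cancers = "liver"))
  calls <- setNames(res$call, res$protein_id)
  expect_equal(unname(calls[c("P01", "P02", "P03")]),
               c("up", "none", "down"))
  expect_lt(res$adj_p[res$protein_id == "P02"], 0.05)
  expect_true(all(calls[sprintf("P%02d", 4:60)] == "none"))
})

test_that("cancers without enough normals are skipped and logged", {
  cfg <- small_sim(seed = 71, n_proteins = 120)
  cfg$samples_per_tissue$n_normal[1] <- 0L
  co <- generate_cohort(cfg)
  expect_message(res <- tumor_vs_normal(co$matrix, co$metadata),
                 "skipped")
  skipped <- cfg$samples_per_tissue$tissue[1]
  expect_false(skipped %in% res$cancer)
  expect_equal(attr(res, "skipped_cancers"), skipped)
  expect_setequal(attr(res, "analyzed_cancers"),
                  setdiff(cfg$samples_per_tissue$tissue, skipped))
})

test_that("the >40% aggregation rule is strict and order-invariant", {
  d <- fake_diff(list(seven = 7, six = 6, all16 = 16))
  agg <- aggregate_cross_cancer(d, 0.4)
  expect_setequal(agg$protein_id, c("seven", "all16"))   # 7 > 6.4, 6 < 6.4
  expect_equal(agg$n_up[agg$protein_id == "seven"], 7)
  # inclusive mode admits the 40%-exact case
  d2 <- fake_diff(list(forty = 8), n_cancers = 16)
  expect_equal(nrow(aggregate_cross_cancer(d2, 0.5)), 0)
  expect_equal(aggregate_cross_cancer(d2, 0.5, inclusive = TRUE)$protein_id,
               "forty")
  # cancer row order does not matter
  dperm <- d[sample(nrow(d)), ]
  attr(dperm, "analyzed_cancers") <- attr(d, "analyzed_cancers")
  expect_equal(aggregate_cross_cancer(dperm, 0.4), agg)
})

test_that("unique proteins are up in exactly one cancer", {
  d <- fake_diff(list(solo = 1, duo = 2, never = 0))
  u <- unique_cancer_proteins(d)
  expect_equal(u$protein_id, "solo")
  expect_equal(u$cancer, pcp_tissues()[1])
  # unique and common-up sets are disjoint
  agg <- aggregate_cross_cancer(d, 0.4)
  expect_length(intersect(u$protein_id, agg$protein_id), 0)
})

test_that("null cohorts only show FDR-level leakage", {
  cfg <- small_sim(seed = 72, n_proteins = 300, n_cancer_up = 0,
                   n_cancer_down = 0)
  co <- generate_cohort(cfg)
  qf <- quantifiability_filter(co$matrix, co$metadata)
  imp <- suppressWarnings(impute_missing(qf$matrix, co$metadata))
  res <- suppressMessages(tumor_vs_normal(imp, co$metadata))
  expect_lte(mean(res$call != "none"), 0.05)
})

test_that("planted tumor effects are called at adequate power", {
  spt <- default_cohort_sizes()[2:5, ]
  spt$n_tumor <- 8L; spt$n_normal <- 8L
  cfg <- sim_config(samples_per_tissue = spt, n_proteins = 300,
                    n_housekeeping = 20,
                    n_tissue_enriched = c("1" = 4), n_cancer_up = 8,
                    n_cancer_down = 8, noise_log2_sd = 0.3,
                    missing_rate = 0, n_outlier_samples = 0, rng_seed = 73)
  co <- generate_cohort(cfg)
  res <- suppressMessages(tumor_vs_normal(co$matrix, co$metadata))
  pl <- planted_diff_pairs(co$truth)
  key <- paste(res$protein_id, res$cancer)
  expect_gte(mean(pl$up %in% key[res$call == "up"]), 0.95)
  expect_gte(mean(pl$down %in% key[res$call == "down"]), 0.95)
})

test_that("clustering is deterministic and k = 1 is a single group", {
  ac <- archetype_cohort(seed = 81, per_group = 10)
  r1 <- cluster_protein_groups(ac$matrix, ac$metadata,
                               rownames(ac$matrix), k = 4)
  r2 <- cluster_protein_groups(ac$matrix, ac$metadata,
                               rownames(ac$matrix), k = 4)
  expect_identical(r1, r2)
  rk1 <- cluster_protein_groups(ac$matrix, ac$metadata,
                                rownames(ac$matrix), k = 1)
  expect_equal(unique(rk1$group), "PG-1")
  expect_error(cluster_protein_groups(ac$matrix, ac$metadata,
                                      rownames(ac$matrix)[1:3], k = 4),
               "fewer proteins")
})

test_that("two well-separated blocks are recovered perfectly at k = 2", {
  ac <- archetype_cohort(seed = 82, per_group = 20)
  keep <- ac$labels %in% 1:2   # normal-high vs pan-tumor-high
  res <- cluster_protein_groups(ac$matrix[keep, ], ac$metadata,
                                rownames(ac$matrix)[keep], k = 2)
  ari <- mclust::adjustedRandIndex(ac$labels[keep], res$group)
  expect_equal(ari, 1)
  # direction labels: PG-1 is the tumor-high side
  tum_high <- res$protein_id[res$group == "PG-1"]
  expect_true(all(tum_high %in% rownames(ac$matrix)[ac$labels == 2]))
})
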