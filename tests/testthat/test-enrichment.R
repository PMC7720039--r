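test_that("the 70% coverage rule needs exactly 11 of 15 wins at T = 16", {
  win15 <- function(k) c(rep(3, k), rep(0, 15 - k))
  fc <- rbind(p_eleven = win15(11), p_ten = win15(10))
  adj <- matrix(0.01, 2, 15, dimnames = list(rownames(fc), NULL))
  enr <- classify_enriched(fake_stats(fc, adj))
  expect_equal(enr$required, 11)
  expect_true(enr$calls["p_eleven", 1])
  expect_false(enr$calls["p_ten", 1])
  expect_equal(unname(enr$multiplicity), c(1, 0))
})

test_that("both the fold-change and the adjusted-p gate are required", {
  fc <- rbind(big_fc_bad_p = rep(3, 15),
              sig_small_fc = rep(1.9, 15),   # below log2(4) = 2
              both = rep(2.5, 15))
  adj <- rbind(rep(0.2, 15), rep(0.001, 15), rep(0.01, 15))
  rownames(adj) <- rownames(fc)
  enr <- classify_enriched(fake_stats(fc, adj))
  expect_equal(unname(enr$calls[, 1]), c(FALSE, FALSE, TRUE))
  expect_error(classify_enriched(fake_stats(fc, adj), coverage = 1.5),
               "coverage")
})

test_that("pairwise stats are antisymmetric and recover planted effects", {
  cfg <- small_sim(seed = 61, n_proteins = 200, missing_rate = 0)
  co <- generate_cohort(cfg)
  st <- pairwise_tissue_stats(co$matrix, co$metadata)
  # antisymmetry
  expect_equal(st$log2_fc[, 1, 2], -st$log2_fc[, 2, 1])
  expect_equal(st$adj_p[, 1, 2], st$adj_p[, 2, 1])
  # planted single-tissue protein: fc near the planted effect everywhere
  single <- names(co$truth$enriched_map)[
    lengths(co$truth$enriched_map) == 1][1]
  tis <- co$truth$enriched_map[[single]]
  fcs <- st$log2_fc[single, tis, setdiff(st$tissues, tis)]
  expect_true(all(abs(fcs - cfg$enrichment_log2_effect) < 0.8))
})

test_that("planted multiplicities are recovered exactly at low noise", {
  # 16 tissues: a multiplicity-4 protein wins 12 of 15 comparisons, which
  # clears the 11-win coverage bar only when all tissue types are present
  spt <- default_cohort_sizes()
  spt$n_tumor <- 4L; spt$n_normal[spt$n_normal > 0] <- 4L
  cfg <- sim_config(samples_per_tissue = spt, n_proteins = 200,
                    n_housekeeping = 10,
                    n_tissue_enriched = c("1" = 8, "2" = 4, "3" = 2,
                                          "4+" = 1),
                    n_cancer_up = 2, n_cancer_down = 2,
                    missing_rate = 0, n_outlier_samples = 0,
                    noise_log2_sd = 0.3, rng_seed = 62)
  co <- generate_cohort(cfg)
  st <- pairwise_tissue_stats(co$matrix, co$metadata)
  enr <- classify_enriched(st)
  truth_m <- lengths(co$truth$enriched_map)
  expect_equal(unname(enr$multiplicity[names(truth_m)]),
               unname(truth_m))
  others <- setdiff(st$proteins, names(truth_m))
  expect_true(all(enr$multiplicity[others] == 0))
  mb <- multiplicity_breakdown(enr)
  expect_equal(mb$n, unname(c(8L, 4L, 2L, 1L)))
  expect_equal(sum(mb$n), sum(enr$multiplicity > 0))
  expect_equal(sum(mb$percent), 100)
})

test_that("no planted signal means no enrichment calls", {
  cfg <- small_sim(seed = 63, n_proteins = 150)
  cfg$n_tissue_enriched <- c("1" = 0)
  co <- generate_cohort(cfg)
  qf <- quantifiability_filter(co$matrix, co$metadata)
  imp <- suppressWarnings(impute_missing(qf$matrix, co$metadata))
  enr <- classify_enriched(pairwise_tissue_stats(imp, co$metadata))
  expect_lte(sum(enr$multiplicity > 0), 1)
  mb <- multiplicity_breakdown(enr)
  expect_equal(sum(mb$n), sum(enr$multiplicity > 0))
})

test_that("permuting tissue labels destroys planted enrichment", {
  cfg <- small_sim(seed = 64, missing_rate = 0)
  co <- generate_cohort(cfg)
  md <- co$metadata
  set.seed(1)
  md$tissue <- sample(md$tissue)
  enr <- classify_enriched(pairwise_tissue_stats(co$matrix, md))
  planted <- planted_enrichment_pairs(co$truth)
  called <- called_enrichment_pairs(enr)
  expect_lte(mean(planted %in% called), 0.05)
})

test_that("group enrichment pools member tissues against the rest", {
  spt <- default_cohort_sizes()
  spt <- spt[spt$tissue %in% c("colon", "stomach", "esophagus", "pancreas",
                               "liver", "bladder", "kidney", "breast"), ]
  spt$n_tumor <- 4L; spt$n_normal <- 4L
  cfg <- sim_config(samples_per_tissue = spt, n_proteins = 100,
                    n_housekeeping = 0, n_tissue_enriched = c("1" = 0),
                    n_cancer_up = 0, n_cancer_down = 0, missing_rate = 0,
                    n_outlier_samples = 0, noise_log2_sd = 0.3,
                    rng_seed = 65)
  co <- generate_cohort(cfg)
  dig <- pcp_tissue_groups()$digestive
  in_dig <- co$metadata$tissue %in% dig
  mat <- co$matrix
  mat["P00001", in_dig] <- mat["P00001", in_dig] * 16  # all 5 dig tissues
  res <- group_enrichment(mat, co$metadata)
  expect_true("P00001" %in% res$digestive)
  expect_false("P00001" %in% res$urinary)
  expect_false("P00002" %in% res$digestive)  # constant protein
  expect_error(group_enrichment(mat, co$metadata,
                                groups = list(bad = "spleen")),
               "unknown tissue")
})
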