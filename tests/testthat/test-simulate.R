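test_that("equal seeds give identical cohorts, different seeds differ", {
  cfg <- small_sim(seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_sim(seed = 4))
  expect_false(identical(a$matrix, c$matrix))
})

test_that("sample count equals the configured cohort sizes", {
  cfg <- small_sim(seed = 1, n_tissues = 5, n_tumor = 7, n_normal = 3)
  co <- generate_cohort(cfg)
  spt <- cfg$samples_per_tissue
  expect_equal(ncol(co$matrix), sum(spt$n_tumor + spt$n_normal))
  expect_equal(nrow(co$metadata), ncol(co$matrix))
  expect_equal(unname(table(co$metadata$tissue)[spt$tissue]),
               unname(as.table(spt$n_tumor + spt$n_normal)),
               ignore_attr = TRUE)
})

test_that("degenerate no-signal zero-noise config is constant per protein", {
  cfg <- small_sim(seed = 2, n_proteins = 50, noise_log2_sd = 0,
                   missing_rate = 0, n_housekeeping = 0,
                   n_tissue_enriched = c("1" = 0), n_cancer_up = 0,
                   n_cancer_down = 0)
  co <- generate_cohort(cfg)
  ranges <- apply(log2(co$matrix), 1, function(v) diff(range(v)))
  expect_true(all(ranges < 1e-12))
})

test_that("planted enrichment effect is recovered by sample means", {
  cfg <- small_sim(seed = 6, n_proteins = 100, missing_rate = 0,
                   enrichment_log2_effect = 4)
  cfg$n_tissue_enriched <- c("1" = 1)
  co <- generate_cohort(cfg)
  pid <- names(co$truth$enriched_map)[1]
  tis <- co$truth$enriched_map[[pid]]
  inn <- co$metadata$tissue %in% tis
  gap <- mean(log2(co$matrix[pid, inn])) - mean(log2(co$matrix[pid, !inn]))
  # Monte-Carlo error: noise 0.5 over ~12 vs ~36 samples
  expect_equal(gap, 4, tolerance = 0.5)
})

test_that("uniform missingness hits the configured rate", {
  cfg <- small_sim(seed = 8, n_proteins = 400, missing_rate = 0.2,
                   missing_intensity_slope = 0)
  co <- generate_cohort(cfg)
  n <- length(co$matrix)
  frac <- mean(is.na(co$matrix))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("intensity-dependent dropout removes low-abundance values", {
  cfg <- small_sim(seed = 12, n_proteins = 400, missing_rate = 0.15,
                   missing_intensity_slope = 1)
  co <- generate_cohort(cfg)
  # same seed with missing_rate 0 reproduces the latent matrix exactly
  cfg0 <- cfg; cfg0$missing_rate <- 0
  latent <- log2(generate_cohort(cfg0)$matrix)
  mis <- is.na(co$matrix)
  expect_identical(2^latent[!mis], co$matrix[!mis])
  expect_lt(mean(latent[mis]), mean(latent[!mis]))
})

test_that("outlier samples carry elevated missingness and a median shift", {
  cfg <- small_sim(seed = 15, n_proteins = 300, n_outlier_samples = 3)
  co <- generate_cohort(cfg)
  out <- co$truth$outlier_sample_ids
  expect_length(out, 3)
  miss_out <- colMeans(is.na(co$matrix[, out, drop = FALSE]))
  miss_in <- mean(is.na(co$matrix[, setdiff(colnames(co$matrix), out)]))
  expect_true(all(miss_out >= 0.5))
  expect_lt(miss_in, 0.2)
})

test_that("ground-truth ids always exist in the generated matrix", {
  co <- generate_cohort(small_sim(seed = 20))
  ids <- rownames(co$matrix)
  expect_true(all(co$truth$housekeeping_ids %in% ids))
  expect_true(all(names(co$truth$enriched_map) %in% ids))
  expect_true(all(names(co$truth$cancer_up_map) %in% ids))
  expect_true(all(lengths(co$truth$enriched_map) >= 1))
  expect_true(all(co$truth$outlier_sample_ids %in% colnames(co$matrix)))
})

test_that("infeasible and invalid configs are rejected up front", {
  expect_error(small_sim(n_proteins = 10), "infeasible")
  expect_error(small_sim(missing_rate = 1.5), "missing_rate")
  expect_error(small_sim(noise_log2_sd = -1), "non-negative")
})

test_that("cohort files round-trip through the writers", {
  co <- generate_cohort(small_sim(seed = 31, n_proteins = 40,
                                  n_housekeeping = 5,
                                  n_tissue_enriched = c("1" = 2),
                                  n_cancer_up = 1, n_cancer_down = 1))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- read_intensity_matrix(paths[["matrix"]])
  expect_equal(back, co$matrix, tolerance = 1e-12)
  md <- read_metadata(paths[["metadata"]], colnames(back))
  expect_equal(md$tissue, co$metadata$tissue)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(sort(unlist(truth$housekeeping_ids)),
               sort(co$truth$housekeeping_ids))
})

test_that("synthetic annotation is deterministic and truth-linked", {
  co <- generate_cohort(small_sim(seed = 40))
  a1 <- simulate_annotation(co)
  a2 <- simulate_annotation(co)
  expect_identical(a1, a2)
  # CT antigens: all but n_ct_null are planted up somewhere
  ct <- a1$protein_id[a1$is_ct_antigen]
  expect_length(ct, 21)
  expect_equal(sum(ct %in% names(co$truth$cancer_up_map)), 20)
})
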