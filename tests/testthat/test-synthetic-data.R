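test_that("generators are deterministic given the configuration", {
  cfg <- synthetic_config(seed = 42, n_proteins = 100, n_genes = 30,
                          planted_fibro_enriched = 12,
                          planted_epi_enriched = 5)
  expect_identical(generate_identifications(cfg),
                   generate_identifications(cfg))
  expect_identical(generate_quant(cfg), generate_quant(cfg))
  expect_identical(generate_annotations(cfg), generate_annotations(cfg))
  expect_identical(generate_votes(cfg), generate_votes(cfg))
  expect_identical(generate_plasma(cfg), generate_plasma(cfg))
  expect_identical(generate_survival(cfg), generate_survival(cfg))
  cfg2 <- synthetic_config(seed = 43, n_proteins = 100, n_genes = 30,
                           planted_fibro_enriched = 12,
                           planted_epi_enriched = 5)
  expect_false(identical(generate_quant(cfg), generate_quant(cfg2)))
})

test_that("generators leave the session RNG stream untouched", {
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(runif(0))
  g <- generate_plasma(synthetic_config(seed = 9))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("decoy-free identification tables contain no decoy rows", {
  cfg <- synthetic_config(seed = 2, n_proteins = 100, fraction_decoy = 0,
                          planted_fibro_enriched = 12,
                          planted_epi_enriched = 5)
  ids <- generate_identifications(cfg)
  expect_false(any(ids$runs[[1]]$is_decoy))
})

test_that("the planted FDR threshold round-trips through estimation", {
  cfg <- synthetic_config(seed = 3, n_proteins = 500)
  ids <- generate_identifications(cfg)
  for (r in seq_along(ids$runs)) {
    t <- estimate_fdr_threshold(ids$runs[[r]], cfg$target_fdr)
    expect_lte(abs(t - ids$truth$thresholds[r]), cfg$score_grid)
  }
})

test_that("acceptance recovers the planted passer set per run", {
  cfg <- synthetic_config(seed = 4, n_proteins = 300)
  ids <- generate_identifications(cfg)
  for (r in seq_along(ids$runs)) {
    res <- accept_proteins(ids$runs[r], ids$truth$thresholds[r],
                           min_unique_peptides = 2)
    expect_setequal(res$accepted_accessions, ids$truth$pass_by_run[[r]])
  }
})

test_that("quant matrices have a unit reference column and planted truth", {
  cfg <- synthetic_config(seed = 5, n_proteins = 200)
  q <- generate_quant(cfg)
  design <- channel_design()
  for (m in q$runs) {
    expect_true(all(m[, design$reference] == 1))
    expect_true(all(m > 0))
  }
  expect_equal(sum(q$truth$true_class == "fibroblast_enriched"), 116)
  expect_equal(sum(q$truth$true_class == "epithelial_enriched"), 44)
})

test_that("null quant generation keeps enrichment calls below chance", {
  cfg <- synthetic_config(seed = 6, n_proteins = 1500, fc_effect = 1)
  q <- generate_quant(cfg)
  per_run <- lapply(q$runs, per_run_enrichment, design = channel_design())
  calls <- call_enrichment(per_run)
  rate <- mean(calls$call != "neither")
  bound <- 2 * (0.05^3 + 3 * sqrt(0.05^3 / 1500))  # both directions
  expect_lte(rate, bound)
})

test_that("strong planted effects are recovered with high recall", {
  cfg <- synthetic_config(seed = 7, n_proteins = 400, fc_effect = 8,
                          ratio_cv = 0.2)
  q <- generate_quant(cfg)
  per_run <- lapply(q$runs, per_run_enrichment, design = channel_design())
  calls <- call_enrichment(per_run)
  merged <- merge(calls, q$truth, by = "accession")
  planted <- merged$true_class != "neither"
  expect_gt(mean(merged$call[planted] == merged$true_class[planted]), 0.95)
})

test_that("planted vote genes are all recovered and nulls rarely called", {
  cfg <- synthetic_config(seed = 8, n_genes = 200)
  v <- generate_votes(cfg)
  res <- screen_catalog(v$votes)
  merged <- merge(res$calls, v$truth, by = "gene")
  planted <- merged$true_status != "unclassified"
  expect_equal(merged$status[planted], merged$true_status[planted])
  expect_lt(mean(merged$status[!planted] != "unclassified"), 0.05)
})

test_that("plasma samples honor the configured group design", {
  cfg <- synthetic_config(seed = 9)
  pl <- generate_plasma(cfg)
  expect_equal(sum(pl$is_case), 42)
  expect_equal(sum(!pl$is_case), 48)
  expect_true(all(pl$concentration_ng_ml > 0))
  big <- synthetic_config(seed = 10, n_case = 5000, n_control = 5000)
  pb <- generate_plasma(big)
  expect_equal(mean(pb$concentration_ng_ml[pb$is_case]), 61.6,
               tolerance = 0.02)
  expect_equal(mean(pb$concentration_ng_ml[!pb$is_case]), 45.0,
               tolerance = 0.02)
})

test_that("vanishing plasma noise drives the AUC to its separation limit", {
  tight <- synthetic_config(seed = 11, sd_case = 1e-4, sd_control = 1e-4)
  pl <- generate_plasma(tight)
  expect_equal(auc(roc_points(pl$concentration_ng_ml, pl$is_case)), 1)
  flat <- synthetic_config(seed = 12, mean_case = 50, mean_control = 50,
                           sd_case = 8, sd_control = 8,
                           n_case = 3000, n_control = 3000)
  pf <- generate_plasma(flat)
  expect_equal(auc(roc_points(pf$concentration_ng_ml, pf$is_case)), 0.5,
               tolerance = 0.03)
})

test_that("survival generator plants the hazard ratio direction", {
  cfg <- synthetic_config(seed = 13, n_survival = 600, hazard_ratio = 3)
  d <- generate_survival(cfg)
  expect_true(all(d$time_months > 0))
  lr <- logrank_test(d$time_months, d$event, d$group)
  expect_lt(lr$p_value, 0.001)
  # null hazard ratio: p roughly uniform, so rarely tiny
  nulls <- vapply(1:20, function(s) {
    d0 <- generate_survival(synthetic_config(seed = s, n_survival = 80,
                                             hazard_ratio = 1))
    logrank_test(d0$time_months, d0$event, d0$group)$p_value
  }, numeric(1))
  expect_gt(mean(nulls > 0.05), 0.7)
})

test_that("written synthetic inputs round-trip through the readers", {
  cfg <- synthetic_config(seed = 14, n_proteins = 60, n_genes = 20,
                          planted_fibro_enriched = 8, planted_epi_enriched = 3,
                          n_vote_up = 4, n_vote_down = 2)
  dir <- tempfile("sim")
  paths <- write_synthetic_inputs(cfg, dir)
  runs <- read_identification_tables(paths["identifications"])
  expect_length(runs, cfg$n_runs)
  q <- read_quant_long(paths["quant"])
  expect_length(q, cfg$n_runs)
  expect_equal(sort(rownames(q[[1]])),
               sort(generate_quant(cfg)$truth$accession))
  votes <- read_vote_table(paths["votes"])
  expect_equal(nrow(votes), 20)
})
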