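test_that("archetype counts equal rounded proportions and configs validate", {
  cfg <- peak_sim_config(n_features = 100,
                         archetype_props = c(unresponsive = 0.7, lps_specific = 0,
                                             shared_jak = 0, ifng_specific = 0.3),
                         seed = 1)
  truth <- generate_peak_truth(cfg)
  tab <- table(truth$features$archetype)
  expect_equal(unname(tab[["unresponsive"]]), 70)
  expect_equal(unname(tab[["ifng_specific"]]), 30)

  expect_error(peak_sim_config(archetype_props = c(unresponsive = 0.6, lps_specific = 0.1,
                                                   shared_jak = 0.1, ifng_specific = 0.1)),
               "archetype_props.*sum to 1")
  expect_error(peak_sim_config(timepoints_h = c(0, 8, 8)), "strictly increasing")
  expect_error(gene_sim_config(lps_traj = c(`0` = 2, `1` = 2, `3` = 5, `6` = 12, `12` = 8)),
               "0 h must be 1")
})

test_that("truth generation and count simulation are deterministic", {
  cfg <- peak_sim_config(n_features = 50, seed = 33)
  t1 <- generate_peak_truth(cfg)
  t2 <- generate_peak_truth(cfg)
  expect_identical(t1$features, t2$features)
  expect_identical(t1$true_cpm, t2$true_cpm)

  s1 <- simulate_counts(t1, cfg)
  s2 <- simulate_counts(t2, cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$design, s2$design)

  g1 <- simulate_genes(gene_sim_config(n_features = 40, seed = 4))
  g2 <- simulate_genes(gene_sim_config(n_features = 40, seed = 4))
  expect_identical(g1$counts$counts, g2$counts$counts)
})

test_that("simulated counts have the configured NB mean and variance", {
  # single feature at true CPM 1000, library 1e6: replicate draws over many
  # samples recover the mean within 2%, and the NB variance law holds
  cfg <- peak_sim_config(n_features = 1, library_size_cv = 0,
                         n_replicates = 1250, seed = 8,
                         archetype_props = c(unresponsive = 1, lps_specific = 0,
                                             shared_jak = 0, ifng_specific = 0))
  truth <- generate_peak_truth(cfg)
  truth$true_cpm[] <- 1000
  truth$features$dispersion <- 1e-8
  sim <- simulate_counts(truth, cfg)
  draws <- as.numeric(sim$counts$counts)
  expect_equal(length(draws), 1250 * 8)
  expect_lt(abs(mean(draws) - 1000) / 1000, 0.02)

  truth$true_cpm[] <- 100
  truth$features$dispersion <- 0.1
  draws <- as.numeric(simulate_counts(truth, cfg)$counts$counts)
  expect_lt(abs(stats::var(draws) - (100 + 0.1 * 100^2)) / (100 + 0.1 * 100^2), 0.1)

  truth$true_cpm[] <- 0
  expect_true(all(simulate_counts(truth, cfg)$counts$counts == 0))
})

test_that("feature-count mismatch between truth and config is an error", {
  cfg <- peak_sim_config(n_features = 20, seed = 1)
  truth <- generate_peak_truth(cfg)
  cfg2 <- peak_sim_config(n_features = 21, seed = 1)
  expect_error(simulate_counts(truth, cfg2), "20 features but config expects 21")
})

test_that("every (condition, replicate) cell yields exactly one sample", {
  sim <- simulate_peaks(peak_sim_config(n_features = 10, n_replicates = 3, seed = 2))
  d <- sim$design
  cell <- paste(d$stimulus, d$time_h, d$washout_treatment, d$replicate)
  expect_equal(anyDuplicated(cell), 0L)
  expect_equal(nrow(d), 8 * 3) # 8 conditions x 3 replicates
  expect_setequal(d$sample_id, colnames(sim$counts$counts))

  g <- simulate_genes(gene_sim_config(n_features = 10, seed = 2))$design
  cellg <- paste(g$pretreatment, g$washout_treatment, g$time_h, g$replicate)
  expect_equal(anyDuplicated(cellg), 0L)
  expect_equal(nrow(g), (2 + 4 * 5) * 2)
})

test_that("null archetypes carry zero true effects in all conditions", {
  pt <- generate_peak_truth(peak_sim_config(n_features = 200, seed = 6))
  unresp <- pt$features$archetype == "unresponsive"
  base <- pt$features$base_cpm
  expect_true(all(abs(pt$true_cpm[unresp, ] - base[unresp]) < 1e-12))

  gt <- generate_gene_truth(gene_sim_config(n_features = 200, seed = 6))
  hk <- gt$features$archetype == "housekeeping"
  expect_true(all(abs(gt$true_cpm[hk, ] - gt$features$base_cpm[hk]) < 1e-12))
  # exactly one archetype per feature by construction of the table
  expect_equal(nrow(gt$features), 200)
  expect_false(anyNA(gt$features$archetype))
})

test_that("gene truth encodes the designed memory phenotypes", {
  gt <- generate_gene_truth(gene_sim_config(n_features = 400, seed = 14))
  f <- gt$features
  tc <- gt$true_cpm
  pot <- f$archetype == "potentiated_unchanged_basal"
  # unchanged basal: identical 0 h in both media arms, elevated late ratios
  expect_equal(tc[pot, "ifng_media_0h"], tc[pot, "pbs_media_0h"])
  r6 <- tc[pot, "ifng_media_6h"] / tc[pot, "pbs_media_6h"]
  expect_true(all(r6 >= 2))
  jak <- f$archetype == "jak_dependent_induction"
  # JAK-dependent induction is flat under ruxolitinib
  expect_equal(tc[jak, "pbs_ruxolitinib_6h"], tc[jak, "pbs_ruxolitinib_0h"])
  expect_true(all(tc[jak, "pbs_media_6h"] / tc[jak, "pbs_media_0h"] > 4))
  tol <- f$archetype == "tolerized"
  expect_true(all(tc[tol, "ifng_media_3h"] / tc[tol, "pbs_media_3h"] <= 0.5))
})
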