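test_that("persistence calls require nonnegative L2FC at FDR < 0.01", {
  ct <- data.frame(feature_id = c("a", "b", "c", "d"),
                   mean_cpm_a = 1, mean_cpm_b = 1,
                   l2fc = c(0.5, -0.2, 1.0, 0),
                   p_value = 0, fdr = c(0.001, 0.001, 0.05, 0.005))
  got <- classify_persistent(ct, c("a", "b", "c", "d"))
  expect_equal(unname(got), c(TRUE, FALSE, FALSE, TRUE), ignore_attr = TRUE)
  expect_error(classify_persistent(ct, c("a", "zzz")), "'zzz'")
  expect_error(classify_persistent(ct, character(0)), "empty induced set")
  # alternative reading: washout-vs-8h contrast, sign only
  alt <- classify_persistent(ct, c("a", "b", "c"), mode = "vs_8h")
  expect_equal(unname(alt), c(TRUE, FALSE, TRUE), ignore_attr = TRUE)
})

test_that("persistence fractions are simple ratios over the induced set", {
  calls <- c(rep(TRUE, 7), rep(FALSE, 3))
  names(calls) <- letters[1:10]
  expect_equal(persistence_fraction(calls), 0.7)
  expect_equal(persistence_fraction(rep(TRUE, 5)), 1)
  expect_error(persistence_fraction(logical(0)), "empty induced set")
})

test_that("shared peaks are the set intersection", {
  expect_setequal(shared_peaks(c("a", "b", "c"), c("b", "c", "d")), c("b", "c"))
  expect_length(shared_peaks(c("a", "b"), c("x", "y")), 0)
})

test_that("persistence fraction is invariant to order and library rescaling", {
  sim <- simulate_peaks(peak_sim_config(n_features = 500, seed = 41))
  pm <- peak_memory(sim$counts, sim$design)
  f0 <- pm$fractions

  scaled <- count_matrix(sim$counts$counts * 3, sim$counts$coords)
  pm_s <- peak_memory(scaled, sim$design)
  expect_equal(pm_s$fractions, f0, tolerance = 0.02)

  perm <- sample(nrow(sim$counts$counts))
  shuffled <- count_matrix(sim$counts$counts[perm, ], sim$counts$coords[perm, ])
  pm_p <- peak_memory(shuffled, sim$design)
  expect_equal(sort(names(pm_p$persistent$media)), sort(names(pm$persistent$media)))
  expect_equal(pm_p$fractions, f0)
})

test_that("washout shifts separate persisting from decaying peak sets", {
  sim <- simulate_peaks(peak_sim_config(n_features = 500, seed = 43))
  tr <- sim$truth$features
  cpm <- cpm_normalize(sim$counts)
  mean_cond <- function(stim_prefix) {
    s <- grep(stim_prefix, colnames(cpm), value = TRUE)
    rowMeans(cpm[, s, drop = FALSE])
  }
  c8 <- mean_cond("^ifng_r")
  cw <- mean_cond("^ifng_wash_media_r")
  persist_ids <- tr$feature_id[tr$washout_behavior == "persist"]
  decay_ids <- tr$feature_id[tr$washout_behavior == "decay" &
                               tr$archetype != "lps_specific"]
  sp <- washout_shift(c8[persist_ids], cw[persist_ids])
  sd_ <- washout_shift(c8[decay_ids], cw[decay_ids])
  expect_lt(abs(sp$mean_l2fc), 0.15)
  expect_lt(sd_$mean_l2fc, -0.5)
  expect_lt(sd_$p_value, 1e-6)
})

test_that("the peak driver recovers induced and shared archetypes", {
  sim <- simulate_peaks(peak_sim_config(n_features = 1000, seed = 45))
  tr <- sim$truth$features
  pm <- peak_memory(sim$counts, sim$design)
  ifng_true <- tr$feature_id[tr$archetype %in% c("shared_jak", "ifng_specific")]
  lps_true <- tr$feature_id[tr$archetype %in% c("shared_jak", "lps_specific")]
  expect_gt(mean(ifng_true %in% pm$induced$ifng), 0.9)
  expect_gt(mean(lps_true %in% pm$induced$lps), 0.9)
  expect_lt(mean(!(pm$induced$ifng %in% ifng_true)), 0.05)
  shared_true <- tr$feature_id[tr$archetype == "shared_jak"]
  expect_gt(mean(shared_true %in% pm$shared), 0.9)
  # every persistent call refers to an induced peak
  for (tr_arm in names(pm$persistent)) {
    expect_true(all(names(pm$persistent[[tr_arm]]) %in% pm$induced$ifng))
  }
})
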