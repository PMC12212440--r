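test_that("CPM normalization is exact arithmetic and columns sum to 1e6", {
  counts <- matrix(c(100, 300, 600, 0, 0, 0), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  counts[, 2] <- c(10, 20, 70)
  m <- count_matrix(counts)
  cpm <- cpm_normalize(m)
  expect_equal(unname(cpm[, 1]), c(1e5, 3e5, 6e5))
  expect_equal(unname(colSums(cpm)), rep(1e6, 2), tolerance = 1e-6)

  zero_feature <- count_matrix(rbind(counts, z = c(0, 0)))
  expect_equal(unname(cpm_normalize(zero_feature)["z", ]), c(0, 0))

  empty <- count_matrix(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1")))
  expect_error(cpm_normalize(empty), "zero library size.*s1")
})

test_that("log2 fold change honors the prior and is antisymmetric", {
  expect_equal(log2_fc(40, 10, 1e-12), 2, tolerance = 1e-9)
  expect_equal(log2_fc(0, 0, 0.5), 0)
  for (i in 1:20) {
    a <- stats::runif(1, 0, 100); b <- stats::runif(1, 0, 100)
    expect_equal(log2_fc(b, a, 0.5), -log2_fc(a, b, 0.5))
  }
  expect_error(log2_fc(1, 1, 0), "prior")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (i in 1:100) {
    p <- stats::runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  p <- stats::runif(1000)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
})

test_that("NB LRT has the Poisson closed-form limit and null identity", {
  null <- nb_test(c(10, 10), c(10, 10), phi = 0)
  expect_equal(null$lrt_stat, 0, tolerance = 1e-8)
  expect_equal(null$p_value, 1)

  # Poisson-limit fixture: fitted group means 5 and 50, pooled 27.5
  fix <- nb_test(c(5, 5), c(50, 50), phi = 0)
  closed_form <- 2 * (10 * log(5 / 27.5) + 100 * log(50 / 27.5))
  expect_equal(fix$lrt_stat, closed_form, tolerance = 1e-6)
  expect_equal(round(fix$lrt_stat, 2), 85.47)

  zero <- nb_test(c(0, 0), c(0, 0, 0), phi = 0.1)
  expect_equal(zero$p_value, 1)
  expect_equal(zero$l2fc, 0)

  expect_error(nb_test(numeric(0), c(1, 2)), "at least one replicate")
  expect_error(nb_test(c(1.5, 2), c(1, 2)), "non-negative integers")
})

test_that("NB LRT p-values match brute-force likelihood maximization", {
  set.seed(7)
  for (i in 1:50) {
    n_a <- sample(2:4, 1); n_b <- sample(2:4, 1)
    phi <- stats::runif(1, 0, 0.3)
    lib_a <- stats::runif(n_a, 5e5, 2e6)
    lib_b <- stats::runif(n_b, 5e5, 2e6)
    a <- stats::rnbinom(n_a, size = 10, mu = stats::runif(1, 2, 200))
    b <- stats::rnbinom(n_b, size = 10, mu = stats::runif(1, 2, 200))
    if (sum(a) + sum(b) == 0) next
    got <- nb_test(a, b, lib_a, lib_b, phi = phi)$p_value
    want <- nb_lrt_oracle(a, b, lib_a, lib_b, phi)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("differential testing is calibrated on null NB features", {
  # no fold change anywhere, phi = 0.05, 3 replicates per group
  cfg <- peak_sim_config(
    n_features = 1500,
    archetype_props = c(unresponsive = 1, lps_specific = 0,
                        shared_jak = 0, ifng_specific = 0),
    dispersion_log_sd = 0, n_replicates = 3, seed = 21)
  sim <- simulate_peaks(cfg)
  a <- sim$design$sample_id[sim$design$stimulus == "unstim"]
  b <- sim$design$sample_id[sim$design$stimulus == "ifng" & sim$design$time_h == 8]
  ct <- nb_diff(sim$counts, a, b)
  expect_gt(mean(ct$p_value < 0.05), 0.02)
  expect_lt(mean(ct$p_value < 0.05), 0.08)
  expect_equal(mean(abs(ct$l2fc)) < 0.25, TRUE)
})

test_that("acute abundance filter applies the any-condition median rule", {
  # 4 features whose per-condition max mean CPM ranks 1 < 2 < 3 < 4:
  # equal library contributions make CPM proportional to counts
  mk <- function(v) matrix(rep(v, 2), length(v), 2)
  fix <- tiny_peak_matrix(list(
    unstim_0h = mk(c(10, 20, 30, 40)),
    ifng_8h = mk(c(10, 20, 30, 40)),
    lps_8h = mk(c(10, 20, 30, 40))))
  keep <- acute_abundance_filter(fix$m, fix$design)
  expect_equal(unname(keep), c(FALSE, FALSE, TRUE, TRUE)) # median 25

  same <- tiny_peak_matrix(list(unstim_0h = mk(c(7, 7, 7)), ifng_8h = mk(c(7, 7, 7)),
                                lps_8h = mk(c(7, 7, 7))))
  expect_true(all(acute_abundance_filter(same$m, same$design)))

  # feature 1 is above the median in exactly one condition -> kept
  one <- tiny_peak_matrix(list(unstim_0h = mk(c(1, 10, 20, 30)),
                               ifng_8h = mk(c(100, 10, 20, 30)),
                               lps_8h = mk(c(1, 10, 20, 30))))
  expect_true(acute_abundance_filter(one$m, one$design)[["pk01"]])

  expect_error(acute_abundance_filter(fix$m, fix$design,
                                      acute_conditions = c("unstim_0h", "ifnb_8h")),
               "no samples found for acute condition 'ifnb_8h'")
  expect_error(acute_abundance_filter(fix$m, fix$design, acute_conditions = character(0)),
               "nonempty")
})

test_that("induction calls use strict cutoffs on both axes", {
  ct <- data.frame(feature_id = c("a", "b", "c", "d"),
                   mean_cpm_a = 1, mean_cpm_b = 10,
                   l2fc = c(2.5, 2.5, 2.0, 3.0),
                   p_value = 0, fdr = c(0.005, 0.02, 0.001, 0.001))
  got <- call_induced(ct)
  expect_equal(unname(got), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("CPM, fold changes and calls are invariant to count rescaling", {
  sim <- simulate_peaks(peak_sim_config(n_features = 120, seed = 9))
  m1 <- sim$counts
  m2 <- count_matrix(m1$counts * 4, m1$coords)
  a <- sim$design$sample_id[sim$design$stimulus == "unstim"]
  b <- sim$design$sample_id[sim$design$stimulus == "ifng" & sim$design$time_h == 8]
  expect_equal(cpm_normalize(m1), cpm_normalize(m2))
  ct1 <- nb_diff(m1, a, b)
  ct2 <- nb_diff(m2, a, b)
  expect_equal(ct1$l2fc, ct2$l2fc, tolerance = 1e-9)
  # calls agree on clearly separated features
  clear <- abs(ct1$l2fc) > 2.5 | abs(ct1$l2fc) < 1
  expect_equal(call_induced(ct1)[clear], call_induced(ct2)[clear])
})
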