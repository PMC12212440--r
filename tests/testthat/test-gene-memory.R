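tc <- function(...) {
  v <- c(...)
  names(v) <- c("0", "1", "3", "6", "12")
  v
}

test_that("acute induction uses an inclusive 5-fold criterion", {
  expect_true(call_ifng_induced_gene(100, 10, prior = 1e-9))
  expect_false(call_ifng_induced_gene(40, 10, prior = 1e-9))
  # exactly 5-fold with the prior folded in: (49.5+0.5)/(9.5+0.5) = 5
  expect_true(call_ifng_induced_gene(49.5, 9.5, prior = 0.5))
})

test_that("persistence tiers split at 90% and 20% retention", {
  expect_equal(persistence_tier(100, 95), "ge90")
  expect_equal(persistence_tier(100, 50), "mid20_90")
  expect_equal(persistence_tier(100, 10), "lt20")
  expect_error(persistence_tier(100, 50, induced = FALSE), "non-induced")
})

test_that("LPS inducibility takes the max fold over post-LPS timepoints", {
  expect_true(call_lps_inducible(tc(10, 12, 30, 60, 55), 5, prior = 1e-9))
  expect_false(call_lps_inducible(tc(10, 10, 10, 10, 10), 5))
  # exactly 4-fold with the prior folded in: (39.5+0.5)/(9.5+0.5) = 4
  expect_true(call_lps_inducible(tc(9.5, 39.5, 10, 10, 10), 4, prior = 0.5))
  expect_error(call_lps_inducible(c(`0` = 10), 5), "no post-LPS timepoints")
  expect_error(call_lps_inducible(c(1, 2, 3), 5), "named by time")
})

test_that("potentiation needs two contiguous timepoints at ratio >= 2", {
  pbs <- tc(10, 10, 10, 10, 10)
  expect_true(call_potentiated(pbs * c(1.0, 1.5, 2.25, 2.17, 2.12), pbs, prior = 1e-9))
  expect_false(call_potentiated(pbs * c(1.0, 2.5, 1.5, 2.5, 1.5), pbs, prior = 1e-9))
  expect_false(call_potentiated(pbs, pbs))
  bad <- pbs; names(bad) <- c("0", "1", "3", "6", "24")
  expect_error(call_potentiated(bad, pbs), "mismatched timepoints")
})

test_that("basal class splits at L2FC 0.5 with ties going to elevated", {
  pbs <- tc(10, 10, 10, 10, 10)
  expect_equal(classify_basal(pbs, pbs), "unchanged")
  expect_equal(classify_basal(pbs * 4, pbs, prior = 1e-9), "elevated")
  # boundary probed where log2 is exact: (19.5+0.5)/(9.5+0.5) = 2 -> L2FC = 1
  exact2 <- tc(19.5, 10, 10, 10, 10)
  pbs95 <- tc(9.5, 10, 10, 10, 10)
  expect_equal(classify_basal(exact2, pbs95, l2fc_cutoff = 1, prior = 0.5), "elevated")
  expect_equal(classify_basal(exact2, pbs95, l2fc_cutoff = 1 + 1e-9, prior = 0.5),
               "unchanged")
})

test_that("tolerance needs contiguous suppression plus rux-resistant induction", {
  pbs <- tc(10, 10, 10, 10, 10)
  rux_ind <- tc(10, 20, 60, 55, 30)  # 6-fold under ruxolitinib
  rux_flat <- tc(10, 12, 25, 30, 20) # only 3-fold
  supp <- pbs * c(1.0, 0.4, 0.45, 0.8, 0.9)
  gap <- pbs * c(1.0, 0.4, 0.8, 0.4, 0.8)
  expect_true(call_tolerized(supp, pbs, rux_ind, prior = 1e-9))
  expect_false(call_tolerized(gap, pbs, rux_ind, prior = 1e-9))
  expect_false(call_tolerized(supp, pbs, rux_flat, prior = 1e-9))
  expect_error(call_tolerized(supp, pbs, NULL), "ruxolitinib arm is required")
})

test_that("classifier reproduces the rule-implied label for every combination", {
  # factorial truth table over inducibility, arm-ratio pattern, basal class
  # and rux compatibility, with expectations transcribed from the rules
  base <- tc(10, 10, 10, 10, 10)
  induc <- tc(10, 20, 60, 120, 80)
  patterns <- list(
    none = c(1, 1, 1, 1, 1),
    up_contig = c(1, 1, 2.5, 2.5, 1),
    up_gapped = c(1, 2.5, 1, 2.5, 1),
    down_contig = c(1, 0.4, 0.4, 1, 1),
    down_gapped = c(1, 0.4, 1, 0.4, 1)
  )
  for (inducible in c(TRUE, FALSE)) {
    for (pat in names(patterns)) {
      for (basal_hi in c(TRUE, FALSE)) {
        for (rux_ok in c(TRUE, FALSE)) {
          pbs_media <- if (inducible) induc else base
          ratio <- patterns[[pat]]
          ifng_media <- pbs_media * ratio
          if (basal_hi) ifng_media["0"] <- pbs_media["0"] * 4
          rux_tc <- if (rux_ok) induc else base
          got <- classify_gene(10, 10, pbs_media, ifng_media, rux_tc, rux_tc,
                               prior = 1e-9)
          want_pot <- inducible && pat == "up_contig"
          want_tol <- inducible && pat == "down_contig" && rux_ok
          expect_identical(got$potentiated, want_pot,
                           label = sprintf("potentiated(%s,%s,%s,%s)",
                                           inducible, pat, basal_hi, rux_ok))
          expect_identical(got$tolerized, want_tol,
                           label = sprintf("tolerized(%s,%s,%s,%s)",
                                           inducible, pat, basal_hi, rux_ok))
          expect_false(got$potentiated && got$tolerized)
          expect_identical(got$rux_compatible_inducible, rux_ok)
          expect_identical(got$lps_inducible, inducible)
          want_basal <- if (!inducible) "n/a" else if (basal_hi) "elevated" else "unchanged"
          expect_identical(got$basal_class, want_basal)
        }
      }
    }
  }
})

test_that("a gene showing both patterns resolves to the stronger, exclusively", {
  pbs <- tc(10, 10, 10, 10, 10) * c(1, 2, 6, 12, 8)
  both <- pbs * c(1, 0.2, 0.2, 2.5, 2.5) # strong early suppression, mild late gain
  got <- classify_gene(10, 10, pbs, both, pbs, pbs, prior = 1e-9)
  expect_true(got$tolerized)
  expect_false(got$potentiated)
})

test_that("gene calls are invariant to uniform CPM rescaling", {
  pbs <- tc(8, 16, 40, 96, 64)
  ifng <- pbs * c(1, 1, 2.5, 2.5, 2)
  a <- classify_gene(50, 8, pbs, ifng, pbs, ifng, prior = 0.5)
  b <- classify_gene(500, 80, pbs * 10, ifng * 10, pbs * 10, ifng * 10, prior = 5)
  expect_identical(a, b)
})

test_that("the gene driver classifies a small simulated cohort coherently", {
  sim <- simulate_genes(gene_sim_config(n_features = 400, seed = 27))
  gm <- gene_memory(sim$counts, sim$design)
  calls <- gm$calls
  tr <- sim$truth$features
  expect_false(any(calls$potentiated & calls$tolerized))
  expect_true(all(calls$persistence_tier[!calls$ifng_induced_8h] == "not_induced"))
  pot_true <- tr$archetype %in% c("potentiated_elevated_basal",
                                  "potentiated_unchanged_basal")
  expect_gt(f1_score(calls$potentiated, pot_true), 0.85)
  # ISG tier structure: persistent ISGs sit in the >= 90% tier in media,
  # and collapse below 20% under ruxolitinib
  pers <- tr$archetype == "isg_persistent" & calls$ifng_induced_8h
  expect_gt(mean(calls$persistence_tier[pers] == "ge90"), 0.6)
  expect_gt(mean(calls$persistence_tier_rux[pers] == "lt20"), 0.8)
})

test_that("rux criteria gate classes on JAK-independent induction", {
  sim <- simulate_genes(gene_sim_config(n_features = 400, seed = 29))
  gm <- gene_memory(sim$counts, sim$design, criteria = "rux")
  tr <- sim$truth$features
  jak <- tr$archetype == "jak_dependent_induction"
  expect_gt(mean(!gm$calls$lps_inducible[jak]), 0.95)
})
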