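# Gene-level memory classifiers -----------------------------------------

# a time course is a named numeric CPM vector, names = hours ("0","1",...)
check_tc <- function(tc, what = "time course") {
  if (is.null(names(tc))) stopf("%s must be named by time in hours", what)
  if (!"0" %in% names(tc)) stopf("%s must include the 0 h (pre-LPS) value", what)
  if (any(tc < 0)) stopf("%s has negative CPM", what)
  invisible(tc)
}

post_lps_times <- function(tc) {
  t <- as.numeric(names(tc))
  names(tc)[order(t)][-1] # all but 0 h, in time order
}

#' Acute IFN-gamma induction call for a gene
#'
#' Induced when the prior-adjusted CPM ratio at 8 h of IFN-gamma vs the
#' reference (time-matched vehicle by default) reaches `fold_cutoff`
#' (inclusive: "at least").
#'
#' @param cpm_ifng_8h,cpm_ref CPM at 8 h IFN-gamma and in the reference.
#' @param fold_cutoff inclusive fold threshold (default 5).
#' @param prior prior CPM.
#' @return logical.
#' @export
call_ifng_induced_gene <- function(cpm_ifng_8h, cpm_ref, fold_cutoff = 5,
                                   prior = 0.5) {
  (cpm_ifng_8h + prior) / (cpm_ref + prior) >= fold_cutoff
}

#' Post-washout persistence tier of an induced gene
#'
#' Retained fraction = (washout CPM + prior) / (8 h CPM + prior); tiers:
#' `ge90` (>= 0.9), `mid20_90` (0.2 <= r < 0.9), `lt20` (< 0.2).
#'
#' @param cpm_8h,cpm_washout CPM at acute 8 h and post-washout.
#' @param induced the gene's induction call; tiers are undefined (error)
#'   for non-induced genes.
#' @param prior prior CPM.
#' @return one of `"ge90"`, `"mid20_90"`, `"lt20"`.
#' @export
persistence_tier <- function(cpm_8h, cpm_washout, induced = TRUE, prior = 0.5) {
  if (!isTRUE(induced)) stopf("persistence tier is undefined for a non-induced gene")
  retained <- (cpm_washout + prior) / (cpm_8h + prior)
  if (retained >= 0.9) "ge90" else if (retained >= 0.2) "mid20_90" else "lt20"
}

#' LPS inducibility of a gene time course
#'
#' Inducible when the maximum prior-adjusted fold over the arm's own 0 h
#' level across post-LPS timepoints reaches `fold_cutoff` (inclusive).
#'
#' @param tc named CPM time course including 0 h.
#' @param fold_cutoff inclusive fold threshold: 5 for media arms, 4 for the
#'   ruxolitinib arm.
#' @param prior prior CPM.
#' @return logical.
#' @export
call_lps_inducible <- function(tc, fold_cutoff = 5, prior = 0.5) {
  check_tc(tc)
  post <- post_lps_times(tc)
  if (!length(post)) stopf("time course has no post-LPS timepoints")
  folds <- (tc[post] + prior) / (tc[["0"]] + prior)
  max(folds) >= fold_cutoff
}

# IFN-gamma/PBS ratios over post-LPS timepoints, both arms on shared times
arm_ratios <- function(tc_ifng, tc_pbs, prior) {
  check_tc(tc_ifng, "IFN-gamma arm")
  check_tc(tc_pbs, "PBS arm")
  if (!setequal(names(tc_ifng), names(tc_pbs))) {
    stopf("arms have mismatched timepoints")
  }
  post <- post_lps_times(tc_pbs)
  (tc_ifng[post] + prior) / (tc_pbs[post] + prior)
}

# strongest contiguous pair: max over adjacent post-LPS pairs (both
# satisfying `cmp` against `cutoff`) of the pair's min |log2 ratio|;
# -Inf when no qualifying pair exists
contiguous_score <- function(ratios, cutoff, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  ok <- if (direction == "ge") ratios >= cutoff else ratios <= cutoff
  score <- -Inf
  for (i in seq_len(length(ratios) - 1)) {
    if (ok[i] && ok[i + 1]) {
      score <- max(score, min(abs(log2(ratios[c(i, i + 1)]))))
    }
  }
  score
}

#' Potentiation call
#'
#' Potentiated when the IFN-gamma-pretreated arm shows at least
#' `ratio_cutoff`-fold greater expression than the PBS arm at two
#' contiguous post-LPS timepoints. The gene must be LPS-inducible for the
#' call to be meaningful; the driver gates on that.
#'
#' @param tc_ifng,tc_pbs time courses of the two pretreatment arms (same
#'   washout treatment, shared timepoints).
#' @param ratio_cutoff inclusive ratio threshold (default 2).
#' @param prior prior CPM.
#' @return logical.
#' @export
call_potentiated <- function(tc_ifng, tc_pbs, ratio_cutoff = 2, prior = 0.5) {
  r <- arm_ratios(tc_ifng, tc_pbs, prior)
  contiguous_score(r, ratio_cutoff, "ge") > -Inf
}

#' Basal set-point class
#'
#' Compares pre-LPS (0 h) expression of the IFN-gamma-pretreated arm with
#' the PBS arm: `unchanged` when the log2 fold change is < `l2fc_cutoff`
#' (the paper's equivalence criterion), `elevated` otherwise.
#'
#' @param tc_ifng,tc_pbs time courses (only the 0 h values are used).
#' @param l2fc_cutoff threshold (default 0.5); exactly 0.5 is `elevated`.
#' @param prior prior CPM.
#' @return `"unchanged"` or `"elevated"`.
#' @export
classify_basal <- function(tc_ifng, tc_pbs, l2fc_cutoff = 0.5, prior = 0.5) {
  check_tc(tc_ifng, "IFN-gamma arm")
  check_tc(tc_pbs, "PBS arm")
  l2 <- log2_fc(tc_ifng[["0"]], tc_pbs[["0"]], prior)
  if (l2 < l2fc_cutoff) "unchanged" else "elevated"
}

#' Tolerance call
#'
#' Tolerized when the IFN-gamma arm shows at least a two-fold reduction
#' (ratio <= 0.5) vs PBS at two contiguous post-LPS timepoints AND the
#' gene remains LPS-inducible (>= `rux_fold_cutoff`) in the ruxolitinib
#' arm, confirming that its induction does not itself require JAK
#' signaling.
#'
#' @param tc_ifng,tc_pbs media-arm time courses.
#' @param tc_rux ruxolitinib-arm time course (missing is an error).
#' @param ratio_cutoff suppression threshold (default 0.5).
#' @param rux_fold_cutoff inclusive rux-arm induction threshold (default 4).
#' @param prior prior CPM.
#' @return logical.
#' @export
call_tolerized <- function(tc_ifng, tc_pbs, tc_rux, ratio_cutoff = 0.5,
                           rux_fold_cutoff = 4, prior = 0.5) {
  if (missing(tc_rux) || is.null(tc_rux)) stopf("ruxolitinib arm is required")
  r <- arm_ratios(tc_ifng, tc_pbs, prior)
  suppressed <- contiguous_score(r, ratio_cutoff, "le") > -Inf
  suppressed && call_lps_inducible(tc_rux, rux_fold_cutoff, prior)
}

#' Classify one gene from its full set of time courses
#'
#' Applies every gene-level rule to one gene and resolves the (rare) case
#' where both the potentiation and tolerance contiguity patterns fire by
#' keeping the direction with the larger absolute log2 arm ratio among its
#' qualifying contiguous pairs, so the two calls are mutually exclusive.
#'
#' @param cpm_ifng_8h,cpm_ref_8h acute CPM for the IFN-gamma induction call.
#' @param tc_pbs_media,tc_ifng_media,tc_pbs_rux,tc_ifng_rux arm time
#'   courses (named CPM vectors including 0 h).
#' @param criteria `"media"` (5-fold LPS inducibility in the media arms) or
#'   `"rux"` (4-fold inducibility in the ruxolitinib arm, the
#'   JAK-independent criterion set).
#' @param induction_fold,lps_fold_media,lps_fold_rux,ratio_cutoff,
#'   basal_l2fc_cutoff,prior rule thresholds.
#' @return named list: `ifng_induced_8h`, `persistence_tier`,
#'   `persistence_tier_rux`, `lps_inducible`, `rux_compatible_inducible`,
#'   `potentiated`, `tolerized`, `basal_class`.
#' @export
classify_gene <- function(cpm_ifng_8h, cpm_ref_8h,
                          tc_pbs_media, tc_ifng_media,
                          tc_pbs_rux, tc_ifng_rux,
                          criteria = c("media", "rux"),
                          induction_fold = 5, lps_fold_media = 5,
                          lps_fold_rux = 4, ratio_cutoff = 2,
                          basal_l2fc_cutoff = 0.5, prior = 0.5) {
  criteria <- match.arg(criteria)
  induced <- call_ifng_induced_gene(cpm_ifng_8h, cpm_ref_8h, induction_fold, prior)
  tier <- if (induced) {
    persistence_tier(cpm_ifng_8h, tc_ifng_media[["0"]], TRUE, prior)
  } else "not_induced"
  tier_rux <- if (induced) {
    persistence_tier(cpm_ifng_8h, tc_ifng_rux[["0"]], TRUE, prior)
  } else "not_induced"

  inducible_media <- call_lps_inducible(tc_pbs_media, lps_fold_media, prior) ||
    call_lps_inducible(tc_ifng_media, lps_fold_media, prior)
  rux_compatible <- call_lps_inducible(tc_pbs_rux, lps_fold_rux, prior) ||
    call_lps_inducible(tc_ifng_rux, lps_fold_rux, prior)
  lps_inducible <- if (criteria == "media") inducible_media else rux_compatible

  r <- arm_ratios(tc_ifng_media, tc_pbs_media, prior)
  pot_score <- contiguous_score(r, ratio_cutoff, "ge")
  tol_score <- contiguous_score(r, 1 / ratio_cutoff, "le")
  potentiated <- lps_inducible && pot_score > -Inf
  tolerized <- lps_inducible && tol_score > -Inf && rux_compatible
  if (potentiated && tolerized) { # both patterns: keep the stronger
    if (pot_score >= tol_score) tolerized <- FALSE else potentiated <- FALSE
  }
  basal <- if (lps_inducible) {
    classify_basal(tc_ifng_media, tc_pbs_media, basal_l2fc_cutoff, prior)
  } else "n/a"

  list(ifng_induced_8h = induced, persistence_tier = tier,
       persistence_tier_rux = tier_rux, lps_inducible = lps_inducible,
       rux_compatible_inducible = rux_compatible,
       potentiated = potentiated, tolerized = tolerized, basal_class = basal)
}

#' Gene-memory analysis of a restimulation experiment
#'
#' Computes replicate-mean CPM per arm and timepoint from a gene count
#' matrix and sample sheet, then applies the interferon-stimulated-gene
#' persistence tiers and the LPS time-course classifiers
#' (inducible / potentiated / tolerized / basal set point) to every gene.
#'
#' @param m a [count_matrix()] of gene counts.
#' @param design sample sheet; expects acute 8 h samples
#'   (`stimulus` = `ifng`/`pbs`, `washout_treatment` = `none`) and LPS
#'   time-course samples with `pretreatment` in `pbs`/`ifng` and
#'   `washout_treatment` in `media`/`ruxolitinib`.
#' @param criteria `"media"` or `"rux"` criterion set (see
#'   [classify_gene()]).
#' @param induction_fold,lps_fold_media,lps_fold_rux,ratio_cutoff,
#'   basal_l2fc_cutoff,prior rule thresholds.
#' @return object of class `gene_memory`: list with `calls` (one row per
#'   gene), `summary` (class counts) and `options`.
#' @export
gene_memory <- function(m, design, criteria = c("media", "rux"),
                        induction_fold = 5, lps_fold_media = 5,
                        lps_fold_rux = 4, ratio_cutoff = 2,
                        basal_l2fc_cutoff = 0.5, prior = 0.5) {
  criteria <- match.arg(criteria)
  cpm <- cpm_normalize(m)
  arm_mean <- function(pre, wt, t) {
    s <- design$sample_id[design$pretreatment == pre &
                            design$washout_treatment == wt &
                            design$time_h == t]
    if (!length(s)) stopf("no samples for arm %s/%s at %s h", pre, wt, t)
    rowMeans(cpm[, s, drop = FALSE])
  }
  tc_for <- function(pre, wt) {
    tps <- sort(unique(design$time_h[design$washout_treatment == wt &
                                       design$pretreatment == pre]))
    mat <- sapply(tps, function(t) arm_mean(pre, wt, t))
    colnames(mat) <- as.character(tps)
    mat
  }
  acute_ifng <- arm_mean("ifng", "none", 8)
  acute_ref <- arm_mean("pbs", "none", 8)
  tcs <- list(pbs_media = tc_for("pbs", "media"),
              ifng_media = tc_for("ifng", "media"),
              pbs_rux = tc_for("pbs", "ruxolitinib"),
              ifng_rux = tc_for("ifng", "ruxolitinib"))

  rows <- lapply(seq_len(nrow(cpm)), function(i) {
    classify_gene(acute_ifng[i], acute_ref[i],
                  tcs$pbs_media[i, ], tcs$ifng_media[i, ],
                  tcs$pbs_rux[i, ], tcs$ifng_rux[i, ],
                  criteria = criteria, induction_fold = induction_fold,
                  lps_fold_media = lps_fold_media, lps_fold_rux = lps_fold_rux,
                  ratio_cutoff = ratio_cutoff,
                  basal_l2fc_cutoff = basal_l2fc_cutoff, prior = prior)
  })
  calls <- data.frame(gene_id = m$feature_ids,
                      do.call(rbind, lapply(rows, function(r)
                        as.data.frame(r, stringsAsFactors = FALSE))),
                      stringsAsFactors = FALSE)
  summ <- list(
    criteria = criteria,
    n_ifng_induced = sum(calls$ifng_induced_8h),
    tier_counts = table(factor(calls$persistence_tier,
                               levels = c("ge90", "mid20_90", "lt20", "not_induced"))),
    tier_counts_rux = table(factor(calls$persistence_tier_rux,
                                   levels = c("ge90", "mid20_90", "lt20", "not_induced"))),
    n_lps_inducible = sum(calls$lps_inducible),
    n_potentiated = sum(calls$potentiated),
    n_potentiated_elevated = sum(calls$potentiated & calls$basal_class == "elevated"),
    n_potentiated_unchanged = sum(calls$potentiated & calls$basal_class == "unchanged"),
    n_tolerized = sum(calls$tolerized),
    n_rux_compatible = sum(calls$rux_compatible_inducible)
  )
  structure(list(calls = calls, summary = summ,
                 options = list(criteria = criteria,
                                induction_fold = induction_fold,
                                lps_fold_media = lps_fold_media,
                                lps_fold_rux = lps_fold_rux,
                                ratio_cutoff = ratio_cutoff,
                                basal_l2fc_cutoff = basal_l2fc_cutoff,
                                prior = prior)),
            class = "gene_memory")
}

#' @export
print.gene_memory <- function(x, ...) {
  s <- x$summary
  cat(sprintf("gene_memory analysis (%s criteria)\n", s$criteria))
  cat(sprintf("  IFNg-induced at 8 h (>= %g-fold): %d genes\n",
              x$options$induction_fold, s$n_ifng_induced))
  tc <- s$tier_counts
  cat(sprintf("  persistence tiers (media): >=90%%: %d, 20-90%%: %d, <20%%: %d\n",
              tc[["ge90"]], tc[["mid20_90"]], tc[["lt20"]]))
  cat(sprintf("  LPS-inducible: %d; potentiated: %d (elevated basal %d / unchanged %d); tolerized: %d\n",
              s$n_lps_inducible, s$n_potentiated, s$n_potentiated_elevated,
              s$n_potentiated_unchanged, s$n_tolerized))
  invisible(x)
}

#' @export
summary.gene_memory <- function(object, ...) object$summary
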