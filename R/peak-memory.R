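# Washout-persistence classification of induced peaks -------------------

#' Persistence call for induced peaks
#'
#' A peak already called induced at the acute timepoint is persistent when
#' the post-washout contrast retains a nonnegative log2 fold change at
#' FDR < `fdr_cutoff`. The default reference for that contrast is the
#' unstimulated baseline (`mode = "vs_unstim"`): the washout signal must
#' still be significantly above baseline. The alternative reading
#' (`mode = "vs_8h"`) applies the same rule to a washout-vs-acute contrast.
#'
#' @param washout_contrast an `nb_contrast` (see `mode` for the reference).
#' @param induced_ids feature ids previously called induced; asking for a
#'   feature outside this set is an error (persistence is undefined there).
#' @param fdr_cutoff FDR threshold (default 0.01).
#' @param mode which contrast reference the rule is applied to; recorded in
#'   the result's attributes.
#' @return named logical vector over `induced_ids`.
#' @export
classify_persistent <- function(washout_contrast, induced_ids,
                                fdr_cutoff = 0.01, mode = c("vs_unstim", "vs_8h")) {
  mode <- match.arg(mode)
  idx <- match(induced_ids, washout_contrast$feature_id)
  if (anyNA(idx)) {
    stopf("feature '%s' is not in the washout contrast", induced_ids[which(is.na(idx))[1]])
  }
  if (!length(induced_ids)) stopf("persistence is undefined for an empty induced set")
  out <- washout_contrast$l2fc[idx] >= 0 &
    (if (mode == "vs_unstim") washout_contrast$fdr[idx] < fdr_cutoff else TRUE)
  names(out) <- induced_ids
  attr(out, "mode") <- mode
  out
}

#' Fraction of induced peaks persisting under one washout arm
#'
#' @param persistent named logical vector from [classify_persistent()] (or
#'   a `peak_memory` object plus `treatment`).
#' @param treatment washout arm name, used when `persistent` is a
#'   `peak_memory` object.
#' @return fraction in [0, 1].
#' @export
persistence_fraction <- function(persistent, treatment = NULL) {
  if (inherits(persistent, "peak_memory")) {
    persistent <- persistent$persistent[[treatment]]
  }
  if (!length(persistent)) stopf("persistence fraction is undefined for an empty induced set")
  mean(persistent)
}

#' Washout shift of induced peaks
#'
#' Per-peak log2 fold change of post-washout vs acute replicate-mean CPM,
#' its arithmetic mean, and a two-sided paired Wilcoxon signed-rank p-value
#' on the paired log2 CPM values.
#'
#' @param cpm_8h,cpm_washout per-peak replicate-mean CPM at the acute and
#'   washout timepoints (equal lengths; pairing by position).
#' @param prior prior CPM.
#' @return list with `l2fc` (per peak), `mean_l2fc`, `p_value`, `n`.
#' @export
washout_shift <- function(cpm_8h, cpm_washout, prior = 0.5) {
  if (length(cpm_8h) != length(cpm_washout)) {
    stopf("unpaired inputs: %d vs %d peaks", length(cpm_8h), length(cpm_washout))
  }
  l2fc <- log2_fc(cpm_washout, cpm_8h, prior)
  wt <- paired_wilcoxon(log2(cpm_8h + prior), log2(cpm_washout + prior))
  list(l2fc = l2fc, mean_l2fc = mean(l2fc), p_value = wt$p_value,
       n = length(l2fc))
}

#' Peaks induced by both stimuli
#'
#' @param induced_ifng,induced_lps feature-id sets (character vectors).
#' @return the intersection, in the order of `induced_ifng`.
#' @export
shared_peaks <- function(induced_ifng, induced_lps) {
  intersect(induced_ifng, induced_lps)
}

#' Full washout-persistence analysis of a peak experiment
#'
#' Runs the standard pipeline on a peak count matrix: acute abundance
#' filter, stimulus-vs-unstimulated differential tests and induction calls,
#' shared-peak logic, per-arm washout persistence, washout shift statistics
#' on induced and shared peaks, and z-scored k-means behavioral clustering
#' of the IFN-gamma-induced peaks across baseline/acute/washout conditions.
#'
#' @param m a [count_matrix()].
#' @param design sample sheet (see [read_design()]).
#' @param stimuli acute stimuli to call induction for.
#' @param acute_time,washout_time hours defining the acute and washout
#'   conditions.
#' @param l2fc_cutoff,fdr_cutoff induction thresholds (strict).
#' @param prior prior CPM for fold changes.
#' @param persistence_mode see [classify_persistent()].
#' @param cluster_k,cluster_seed,cluster_restarts behavioral clustering
#'   parameters; clustering uses replicate columns by default
#'   (`cluster_on = "replicates"`) or condition means.
#' @param cluster_on whether clustering sees replicate columns or
#'   condition-mean columns.
#' @return object of class `peak_memory`; see Details.
#' @details The returned object carries `contrasts` (per stimulus),
#'   `induced` (id sets), `shared`, `persistent` (per washout arm, logical
#'   over IFN-gamma-induced peaks), `fractions`, `shift` (per stimulus and
#'   for shared peaks), `clusters` and the options used.
#' @export
peak_memory <- function(m, design,
                        stimuli = c("ifng", "lps"),
                        acute_time = 8, washout_time = 96,
                        l2fc_cutoff = 2, fdr_cutoff = 0.01,
                        prior = 0.5,
                        persistence_mode = c("vs_unstim", "vs_8h"),
                        cluster_k = 3, cluster_seed = 1, cluster_restarts = 50,
                        cluster_on = c("replicates", "condition_means")) {
  persistence_mode <- match.arg(persistence_mode)
  cluster_on <- match.arg(cluster_on)
  labels <- condition_label(design)
  unstim <- "unstim_0h"
  acute_lab <- function(s) sprintf("%s_%dh", s, acute_time)
  keep <- acute_abundance_filter(m, design,
                                 acute_conditions = c(unstim, acute_lab(stimuli)))
  mf <- subset_counts(m, features = which(keep))

  s_unstim <- samples_for(design, unstim)
  contrasts <- list()
  induced <- list()
  for (s in stimuli) {
    ct <- nb_diff(mf, s_unstim, samples_for(design, acute_lab(s)), prior = prior)
    contrasts[[s]] <- ct
    induced[[s]] <- ct$feature_id[call_induced(ct, l2fc_cutoff, fdr_cutoff)]
  }
  shared <- if (all(c("ifng", "lps") %in% stimuli)) {
    shared_peaks(induced$ifng, induced$lps)
  } else character(0)

  # washout arms available for IFN-gamma in this design
  wash_rows <- design$stimulus == "ifng" & design$time_h == washout_time
  treatments <- unique(design$washout_treatment[wash_rows])
  persistent <- list()
  wash_contrasts <- list()
  for (tr in treatments) {
    lab <- sprintf("ifng_%dh_%s", washout_time, tr)
    ct <- if (persistence_mode == "vs_unstim") {
      nb_diff(mf, s_unstim, samples_for(design, lab), prior = prior)
    } else {
      nb_diff(mf, samples_for(design, acute_lab("ifng")), samples_for(design, lab),
              prior = prior)
    }
    wash_contrasts[[tr]] <- ct
    if (length(induced$ifng)) {
      persistent[[tr]] <- classify_persistent(ct, induced$ifng, fdr_cutoff,
                                              persistence_mode)
    }
  }
  fractions <- vapply(persistent, mean, numeric(1))

  # washout shift (media arm) per stimulus and on shared peaks
  shift <- list()
  for (s in stimuli) {
    lab <- sprintf("%s_%dh_media", s, washout_time)
    if (!any(labels == lab) || !length(induced[[s]])) next
    cm <- condition_mean_cpm(mf, design, c(acute_lab(s), lab))
    idx <- match(induced[[s]], rownames(cm))
    shift[[s]] <- washout_shift(cm[idx, 1], cm[idx, 2], prior)
    if (length(shared)) {
      sidx <- match(shared, rownames(cm))
      shift[[paste0("shared_", s)]] <- washout_shift(cm[sidx, 1], cm[sidx, 2], prior)
    }
  }

  # behavioral clustering of IFN-gamma-induced peaks
  clusters <- NULL
  if (length(induced$ifng) >= cluster_k) {
    conds <- c(unstim, acute_lab("ifng"), sprintf("ifng_%dh_media", washout_time))
    if (cluster_on == "condition_means") {
      mat <- condition_mean_cpm(mf, design, conds)
      col_cond <- conds
    } else {
      samp <- unlist(lapply(conds, samples_for, design = design))
      mat <- cpm_normalize(mf)[, samp, drop = FALSE]
      col_cond <- rep(conds, vapply(conds, function(x)
        length(samples_for(design, x)), integer(1)))
    }
    z <- zscore_rows(log2(mat[match(induced$ifng, mf$feature_ids), , drop = FALSE] + prior))
    clusters <- kmeans_cluster(z, k = cluster_k, seed = cluster_seed,
                               n_restarts = cluster_restarts,
                               post_cols = which(col_cond == conds[3]),
                               acute_cols = which(col_cond == conds[2]))
  }

  structure(list(contrasts = contrasts, induced = induced, shared = shared,
                 wash_contrasts = wash_contrasts, persistent = persistent,
                 fractions = fractions, shift = shift, clusters = clusters,
                 filter_keep = keep,
                 options = list(l2fc_cutoff = l2fc_cutoff, fdr_cutoff = fdr_cutoff,
                                prior = prior, persistence_mode = persistence_mode,
                                cluster_on = cluster_on, acute_time = acute_time,
                                washout_time = washout_time)),
            class = "peak_memory")
}

#' @export
print.peak_memory <- function(x, ...) {
  cat("peak_memory analysis\n")
  cat(sprintf("  features passing abundance filter: %d / %d\n",
              sum(x$filter_keep), length(x$filter_keep)))
  for (s in names(x$induced)) {
    cat(sprintf("  induced by %s: %d peaks\n", s, length(x$induced[[s]])))
  }
  cat(sprintf("  shared (IFNg & LPS): %d peaks\n", length(x$shared)))
  for (tr in names(x$fractions)) {
    cat(sprintf("  persistence after washout (%s): %.1f%%\n",
                tr, 100 * x$fractions[[tr]]))
  }
  invisible(x)
}

#' @export
summary.peak_memory <- function(object, ...) {
  sh <- lapply(object$shift, function(s)
    c(mean_l2fc = s$mean_l2fc, p = s$p_value, n = s$n))
  list(n_induced = lengths(object$induced),
       n_shared = length(object$shared),
       persistence_fractions = object$fractions,
       washout_shift = sh,
       cluster_sizes = if (!is.null(object$clusters))
         table(object$clusters$assignment$cluster_label) else NULL,
       options = object$options)
}
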