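# Gene time-course simulator --------------------------------------------

gene_conditions <- function(config) {
  tps <- config$timepoints_h
  c("pbs_acute_8h", "ifng_acute_8h",
    as.vector(outer(c("pbs_media", "ifng_media", "pbs_ruxolitinib", "ifng_ruxolitinib"),
                    tps, function(a, t) paste0(a, "_", t, "h"))))
}

#' Generate ground-truth gene archetypes and trajectories
#'
#' Assigns each gene one of seven archetypes (rounded proportions), draws
#' baseline CPM and dispersion, and tabulates the true CPM of every gene in
#' every arm/timepoint of the restimulation design: acute 8 h samples for
#' PBS and IFN-gamma pretreatment, then an LPS time course under each
#' (pretreatment x washout-treatment) arm. LPS induction folds are the
#' configured piecewise-constant trajectory scaled by a per-gene log-normal
#' jitter; potentiation, tolerance, ISG persistence and JAK dependence are
#' applied per archetype as documented in [gene_sim_config()].
#' Deterministic given `config$seed`.
#'
#' @param config a [gene_sim_config()].
#' @return an object of class `sim_truth` (see [generate_peak_truth()]).
#' @export
generate_gene_truth <- function(config) {
  stopifnot(inherits(config, "gene_sim_config"))
  with_seed(config$seed, {
    n <- config$n_features
    sizes <- proportion_counts(n, config$archetype_props)
    archetype <- rep(names(sizes), times = sizes)
    ids <- sprintf("gene_%05d", seq_len(n))
    tps <- config$timepoints_h
    tlab <- as.character(tps)

    is_isg <- archetype %in% c("isg_persistent", "isg_transient")
    is_lps <- archetype %in% c("potentiated_elevated_basal",
                               "potentiated_unchanged_basal",
                               "tolerized", "jak_dependent_induction")
    base_cpm <- numeric(n)
    base_cpm[!is_isg & !is_lps] <- stats::rlnorm(sum(!is_isg & !is_lps),
                                                 config$base_cpm_log_mean,
                                                 config$base_cpm_log_sd)
    base_cpm[is_isg] <- stats::rlnorm(sum(is_isg),
                                      config$isg_base_cpm_log_mean,
                                      config$isg_base_cpm_log_sd)
    base_cpm[is_lps] <- stats::rlnorm(sum(is_lps),
                                      config$inducible_base_cpm_log_mean,
                                      config$inducible_base_cpm_log_sd)
    phi <- stats::rlnorm(n, config$dispersion_log_mean, config$dispersion_log_sd)
    isg_l2fc <- ifelse(is_isg,
                       rnorm_clamped(n, config$isg_l2fc_mean, config$isg_l2fc_sd,
                                     config$isg_l2fc_range),
                       0)
    jitter <- stats::rlnorm(n, 0, config$traj_jitter_log_sd)

    conds <- gene_conditions(config)
    true_cpm <- matrix(0, n, length(conds), dimnames = list(ids, conds))

    # per-gene LPS fold trajectory (fold over that arm's 0 h level)
    traj <- matrix(rep(config$lps_traj[tlab], each = n), n, length(tps))
    traj <- 1 + (traj - 1) * jitter # jitter scales induction, keeps 0 h at 1
    colnames(traj) <- tlab

    pot_all <- archetype == "potentiated_elevated_basal"
    pot_late <- archetype == "potentiated_unchanged_basal"
    tol <- archetype == "tolerized"
    jak <- archetype == "jak_dependent_induction"
    pf <- config$potentiation_factor

    # acute pretreatment samples
    true_cpm[, "pbs_acute_8h"] <- base_cpm
    true_cpm[, "ifng_acute_8h"] <- base_cpm * 2^isg_l2fc

    # post-washout 0 h level of ISGs per washout treatment: persistent ISGs
    # hold most of their acute level only while signaling continues (media);
    # transient ISGs and any ISG under ruxolitinib fall back to baseline
    isg_wash <- function(treatment) {
      lvl <- base_cpm
      keep <- archetype == "isg_persistent" & treatment == "media"
      lvl[keep] <- config$isg_retention_persistent * true_cpm[keep, "ifng_acute_8h"]
      lvl
    }

    for (pre in c("pbs", "ifng")) {
      for (wt in c("media", "ruxolitinib")) {
        for (ti in seq_along(tps)) {
          t <- tps[ti]
          lvl <- base_cpm
          # LPS induction; abolished under ruxolitinib for JAK-dependent genes
          fold <- traj[, tlab[ti]]
          fold[jak & wt == "ruxolitinib"] <- 1
          lvl[is_lps] <- (base_cpm * fold)[is_lps]
          # ISGs: flat across the LPS course at their washout level
          if (pre == "ifng") {
            lvl[is_isg] <- isg_wash(wt)[is_isg]
            if (wt == "media") {
              # potentiation/tolerance require continued IFN-gamma signaling
              lvl[pot_all] <- lvl[pot_all] * pf
              if (t %in% config$potentiation_times_unchanged) {
                lvl[pot_late] <- lvl[pot_late] * pf
              }
              if (t %in% config$tolerized_times) {
                lvl[tol] <- lvl[tol] * config$tolerized_ratio
              }
            }
          }
          true_cpm[, paste0(pre, "_", wt, "_", t, "h")] <- lvl
        }
      }
    }

    features <- data.frame(
      feature_id = ids, archetype = archetype,
      base_cpm = base_cpm, dispersion = phi,
      ifng_acute_l2fc = isg_l2fc, traj_jitter = jitter,
      stringsAsFactors = FALSE
    )
    structure(list(features = features, true_cpm = true_cpm, config = config),
              class = c("gene_sim_truth", "sim_truth"))
  })
}

#' One-call gene simulation
#'
#' @param config a [gene_sim_config()].
#' @return list with `counts`, `design` and `truth`.
#' @export
simulate_genes <- function(config = gene_sim_config()) {
  truth <- generate_gene_truth(config)
  sim <- simulate_counts(truth, config)
  c(sim, list(truth = truth))
}
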