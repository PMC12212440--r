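# Simulation configurations ---------------------------------------------

check_props <- function(p, field) {
  if (abs(sum(p) - 1) > 1e-9) {
    stopf("configuration error: `%s` must sum to 1 (got %.12f)", field, sum(p))
  }
  if (any(p < 0)) stopf("configuration error: `%s` has negative entries", field)
  invisible(p)
}

# split n into integer class sizes that match rounded proportions; any
# rounding drift is absorbed by the largest class
proportion_counts <- function(n, props) {
  k <- round(props * n)
  drift <- n - sum(k)
  if (drift != 0) k[which.max(k)] <- k[which.max(k)] + drift
  stats::setNames(as.integer(k), names(props))
}

validate_sim_common <- function(cfg) {
  if (cfg$n_features < 1) stopf("configuration error: `n_features` must be >= 1")
  if (cfg$library_size_mean <= 0) stopf("configuration error: `library_size_mean` must be > 0")
  if (cfg$library_size_cv < 0) stopf("configuration error: `library_size_cv` must be >= 0")
  if (cfg$n_replicates < 1) stopf("configuration error: `n_replicates` must be >= 1")
  if (any(diff(cfg$timepoints_h) <= 0)) {
    stopf("configuration error: `timepoints_h` must be strictly increasing")
  }
  invisible(cfg)
}

#' Configuration for the peak-assay simulator
#'
#' Defines a washout experiment on chromatin features (H3K4me1 CUT&Tag or
#' ATAC peaks): acute stimulation at 8 h with IFN-gamma, LPS, or LPS under
#' ruxolitinib, then washout arms re-assayed at 96 h under media,
#' anti-IFN-gamma antibody, or ruxolitinib. Counts are negative-binomial
#' with per-feature dispersion and library-size variation; each feature is
#' assigned one archetype with known true effects.
#'
#' Baseline CPM for unresponsive (pre-existing) features is log-normal and
#' deliberately larger than that of responsive features: de novo enhancers
#' start near background. Washout effects retain a behavior-specific
#' fraction of the induced log2 effect (persist 1, decay 0, augment > 1),
#' multiplied by a treatment factor (media 1, antibody 0.45, ruxolitinib
#' 0.15) that encodes how thoroughly each arm severs continued signaling.
#'
#' @param n_features number of peaks.
#' @param archetype_props named fractions over `unresponsive`,
#'   `lps_specific`, `shared_jak`, `ifng_specific`; must sum to 1.
#' @param behavior_props washout behavior mix for IFN-gamma-induced peaks
#'   (`persist`, `decay`, `augment`); must sum to 1.
#' @param base_cpm_log_mean,base_cpm_log_sd log-normal baseline CPM of
#'   unresponsive peaks.
#' @param induced_base_cpm_log_mean,induced_base_cpm_log_sd log-normal
#'   baseline CPM of responsive (de novo) peaks.
#' @param dispersion_log_mean,dispersion_log_sd log-normal NB dispersion
#'   (variance = mu + phi mu^2).
#' @param induced_l2fc_mean,induced_l2fc_sd normal induced log2 effect.
#' @param induced_l2fc_range clamp range for the induced effect.
#' @param washout_retention named fractions of the induced log2 effect
#'   retained post-washout per behavior.
#' @param treatment_effects named retention multipliers per washout arm.
#' @param treatment_effect_sd per-peak standard deviation of each arm's
#'   retention multiplier (clamped to `[0, 1.5]`): media leaves signaling
#'   intact (sd 0), antibody neutralization is incomplete and varies from
#'   peak to peak, JAK inhibition is near-uniform.
#' @param n_replicates biological replicates per condition.
#' @param library_size_mean,library_size_cv log-normal library sizes.
#' @param timepoints_h assay times (0 = unstimulated, 8 = acute, 96 = washout).
#' @param seed RNG seed for truth generation and count draws.
#' @return a validated list of class `peak_sim_config`.
#' @export
peak_sim_config <- function(n_features = 2000,
                            archetype_props = c(unresponsive = 0.70,
                                                lps_specific = 0.10,
                                                shared_jak = 0.08,
                                                ifng_specific = 0.12),
                            behavior_props = c(persist = 0.55,
                                               decay = 0.35,
                                               augment = 0.10),
                            base_cpm_log_mean = log(300),
                            base_cpm_log_sd = 1,
                            induced_base_cpm_log_mean = log(50),
                            induced_base_cpm_log_sd = 0.3,
                            dispersion_log_mean = log(0.05),
                            dispersion_log_sd = 0.5,
                            induced_l2fc_mean = 3.8,
                            induced_l2fc_sd = 0.5,
                            induced_l2fc_range = c(3, 5.5),
                            washout_retention = c(persist = 1.0,
                                                  decay = 0.0,
                                                  augment = 1.6),
                            treatment_effects = c(media = 1.0,
                                                  anti_ifng_ab = 0.45,
                                                  ruxolitinib = 0.15),
                            treatment_effect_sd = c(media = 0,
                                                    anti_ifng_ab = 0.25,
                                                    ruxolitinib = 0.10),
                            n_replicates = 2,
                            library_size_mean = 1e6,
                            library_size_cv = 0.2,
                            timepoints_h = c(0, 8, 96),
                            seed = 1) {
  cfg <- structure(as.list(environment()), class = c("peak_sim_config", "sim_config"))
  check_props(archetype_props, "archetype_props")
  check_props(behavior_props, "behavior_props")
  need <- c("unresponsive", "lps_specific", "shared_jak", "ifng_specific")
  if (!setequal(names(archetype_props), need)) {
    stopf("configuration error: `archetype_props` must name %s", paste(need, collapse = ", "))
  }
  if (any(washout_retention < 0)) stopf("configuration error: `washout_retention` must be >= 0")
  if (any(treatment_effects < 0)) stopf("configuration error: `treatment_effects` must be >= 0")
  if (!setequal(names(treatment_effect_sd), names(treatment_effects)) ||
      any(treatment_effect_sd < 0)) {
    stopf("configuration error: `treatment_effect_sd` must be >= 0 and name the same arms as `treatment_effects`")
  }
  validate_sim_common(cfg)
  cfg
}

#' Configuration for the gene time-course simulator
#'
#' Defines the restimulation experiment: macrophages pretreated with
#' IFN-gamma or PBS for 8 h, washed, cultured 88 h in media or ruxolitinib,
#' then stimulated with LPS and sampled at 0 (pre-LPS), 1, 3, 6 and 12 h.
#' Acute 8 h samples for both pretreatments are included so interferon-
#' stimulated gene (ISG) induction and washout persistence can be measured.
#'
#' Gene archetypes: `housekeeping` (flat), `isg_persistent` /
#' `isg_transient` (IFN-gamma induced; retain ~all / decay to baseline
#' post-washout in media, always decay under ruxolitinib),
#' `potentiated_elevated_basal` and `potentiated_unchanged_basal`
#' (LPS-inducible, expressed `potentiation_factor`-fold higher after
#' IFN-gamma pretreatment across all / only late timepoints),
#' `tolerized` (LPS-inducible, suppressed under IFN-gamma pretreatment,
#' induction intact under ruxolitinib) and `jak_dependent_induction`
#' (LPS induction abolished by ruxolitinib). Trajectories are
#' piecewise-constant per timepoint, scaled per gene by a mild log-normal
#' jitter, so every classification rule can be audited by hand.
#'
#' @param n_features number of genes.
#' @param archetype_props named fractions over the seven gene archetypes.
#' @param base_cpm_log_mean,base_cpm_log_sd baseline CPM of housekeeping genes.
#' @param isg_base_cpm_log_mean,isg_base_cpm_log_sd baseline CPM of ISGs.
#' @param inducible_base_cpm_log_mean,inducible_base_cpm_log_sd baseline
#'   CPM of LPS-inducible genes.
#' @param dispersion_log_mean,dispersion_log_sd log-normal NB dispersion.
#' @param isg_l2fc_mean,isg_l2fc_sd,isg_l2fc_range acute IFN-gamma log2 effect.
#' @param isg_retention_persistent fraction of acute CPM kept post-washout
#'   by persistent ISGs (transient ISGs decay to baseline).
#' @param lps_traj named fold-over-baseline LPS trajectory at
#'   `timepoints_h` (0 h must be 1).
#' @param traj_jitter_log_sd per-gene log-normal jitter on induction folds.
#' @param potentiation_factor fold elevation of the IFN-gamma arm.
#' @param potentiation_times_unchanged post-LPS hours at which
#'   unchanged-basal potentiated genes are elevated (elevated-basal genes
#'   are elevated at all times including 0 h).
#' @param tolerized_ratio IFN-gamma/PBS expression ratio of tolerized genes
#'   at `tolerized_times`.
#' @param tolerized_times post-LPS hours of suppression.
#' @param n_replicates,library_size_mean,library_size_cv,seed as in
#'   [peak_sim_config()].
#' @param timepoints_h LPS time course (hours; first must be 0).
#' @return a validated list of class `gene_sim_config`.
#' @export
gene_sim_config <- function(n_features = 2000,
                            archetype_props = c(housekeeping = 0.55,
                                                isg_persistent = 0.06,
                                                isg_transient = 0.06,
                                                potentiated_elevated_basal = 0.08,
                                                potentiated_unchanged_basal = 0.08,
                                                tolerized = 0.07,
                                                jak_dependent_induction = 0.10),
                            base_cpm_log_mean = log(300),
                            base_cpm_log_sd = 1,
                            isg_base_cpm_log_mean = log(50),
                            isg_base_cpm_log_sd = 0.4,
                            inducible_base_cpm_log_mean = log(20),
                            inducible_base_cpm_log_sd = 0.4,
                            dispersion_log_mean = log(0.05),
                            dispersion_log_sd = 0.5,
                            isg_l2fc_mean = 3,
                            isg_l2fc_sd = 0.4,
                            isg_l2fc_range = c(2.6, 5),
                            isg_retention_persistent = 0.95,
                            lps_traj = c(`0` = 1, `1` = 2, `3` = 5, `6` = 12, `12` = 8),
                            traj_jitter_log_sd = 0.2,
                            potentiation_factor = 2^1.9,
                            potentiation_times_unchanged = c(3, 6, 12),
                            tolerized_ratio = 0.25,
                            tolerized_times = c(1, 3, 6),
                            n_replicates = 2,
                            library_size_mean = 1e6,
                            library_size_cv = 0.2,
                            timepoints_h = c(0, 1, 3, 6, 12),
                            seed = 1) {
  cfg <- structure(as.list(environment()), class = c("gene_sim_config", "sim_config"))
  check_props(archetype_props, "archetype_props")
  need <- c("housekeeping", "isg_persistent", "isg_transient",
            "potentiated_elevated_basal", "potentiated_unchanged_basal",
            "tolerized", "jak_dependent_induction")
  if (!setequal(names(archetype_props), need)) {
    stopf("configuration error: `archetype_props` must name %s", paste(need, collapse = ", "))
  }
  if (timepoints_h[1] != 0) stopf("configuration error: `timepoints_h` must start at 0")
  if (!setequal(names(lps_traj), as.character(timepoints_h))) {
    stopf("configuration error: `lps_traj` must be named by `timepoints_h`")
  }
  if (lps_traj[["0"]] != 1) stopf("configuration error: `lps_traj` at 0 h must be 1")
  if (potentiation_factor < 2) stopf("configuration error: `potentiation_factor` must be >= 2")
  if (tolerized_ratio > 0.5 || tolerized_ratio <= 0) {
    stopf("configuration error: `tolerized_ratio` must be in (0, 0.5]")
  }
  validate_sim_common(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("%s: %d features, %d replicates, seed %d\n",
              class(x)[1], x$n_features, x$n_replicates, as.integer(x$seed)))
  cat("archetypes:", paste(sprintf("%s=%.2f", names(x$archetype_props),
                                   x$archetype_props), collapse = ", "), "\n")
  invisible(x)
}
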