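# Peak-assay simulator: truth generation and NB count draws --------------

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rnorm_clamped <- function(n, mean, sd, range) {
  pmin(pmax(stats::rnorm(n, mean, sd), range[1]), range[2])
}

#' Generate ground-truth peak archetypes and effects
#'
#' Assigns each peak an archetype (class sizes are the rounded archetype
#' proportions), draws baseline CPM, dispersion and induced log2 effects,
#' assigns washout behaviors to IFN-gamma-inducible peaks (LPS-specific
#' peaks always decay, matching the transience of TLR-driven marks), and
#' tabulates the true CPM of every peak in every condition. Deterministic
#' given `config$seed`.
#'
#' @param config a [peak_sim_config()].
#' @return an object of class `sim_truth`: list with `features` (data.frame
#'   of per-peak labels and parameters), `true_cpm` (features x conditions
#'   matrix) and `config`.
#' @export
generate_peak_truth <- function(config) {
  stopifnot(inherits(config, "peak_sim_config"))
  with_seed(config$seed, {
    n <- config$n_features
    sizes <- proportion_counts(n, config$archetype_props)
    archetype <- rep(names(sizes), times = sizes)
    ids <- sprintf("peak_%05d", seq_len(n))

    responsive <- archetype != "unresponsive"
    base_cpm <- numeric(n)
    base_cpm[!responsive] <- stats::rlnorm(sum(!responsive),
                                           config$base_cpm_log_mean,
                                           config$base_cpm_log_sd)
    base_cpm[responsive] <- stats::rlnorm(sum(responsive),
                                          config$induced_base_cpm_log_mean,
                                          config$induced_base_cpm_log_sd)
    phi <- stats::rlnorm(n, config$dispersion_log_mean, config$dispersion_log_sd)
    l2fc <- ifelse(responsive,
                   rnorm_clamped(n, config$induced_l2fc_mean,
                                 config$induced_l2fc_sd, config$induced_l2fc_range),
                   0)

    # washout behaviors: IFN-gamma-inducible peaks get the configured mix,
    # LPS-specific peaks decay, unresponsive peaks have none
    behavior <- rep("n/a", n)
    ifng_ind <- archetype %in% c("shared_jak", "ifng_specific")
    for (a in c("shared_jak", "ifng_specific")) {
      idx <- which(archetype == a)
      bs <- proportion_counts(length(idx), config$behavior_props)
      behavior[idx] <- sample(rep(names(bs), times = bs))
    }
    behavior[archetype == "lps_specific"] <- "decay"

    # per-condition true log2 effects over baseline
    l2 <- list(
      unstim = rep(0, n),
      ifng = ifelse(ifng_ind, l2fc, 0),
      lps = ifelse(archetype %in% c("lps_specific", "shared_jak"), l2fc, 0),
      lps_rux = ifelse(archetype == "lps_specific", l2fc, 0)
    )
    retain <- config$washout_retention[behavior]
    retain[is.na(retain)] <- 0
    for (tr in names(config$treatment_effects)) {
      # per-peak retention multiplier: arms that sever signaling only
      # partially (antibody) do so with peak-to-peak variability
      mult <- pmin(pmax(stats::rnorm(n, config$treatment_effects[[tr]],
                                     config$treatment_effect_sd[[tr]]), 0), 1.5)
      l2[[paste0("ifng_wash_", tr)]] <-
        ifelse(ifng_ind, l2fc * retain * mult, 0)
    }
    l2$lps_wash_media <- ifelse(archetype %in% c("lps_specific", "shared_jak"),
                                l2fc * retain, 0)

    true_cpm <- do.call(cbind, lapply(l2, function(e) base_cpm * 2^e))
    rownames(true_cpm) <- ids

    # BED coordinates: non-overlapping windows scattered over chromosomes
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    start <- integer(n)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      start[i] <- sort(sample.int(2e8, length(i))) # distinct, sorted per chrom
    }
    width <- sample(300:800, n, replace = TRUE)

    features <- data.frame(
      feature_id = ids, chrom = chrom, start = start, end = start + width,
      archetype = archetype, washout_behavior = behavior,
      base_cpm = base_cpm, dispersion = phi, induced_l2fc = l2fc,
      stringsAsFactors = FALSE
    )
    structure(list(features = features, true_cpm = true_cpm, config = config),
              class = c("peak_sim_truth", "sim_truth"))
  })
}

#' Draw NB counts for a simulated truth
#'
#' For every condition and replicate, draws a library size and then
#' per-feature counts `NB(mean = lib * cpm / 1e6, dispersion = phi)`.
#' Zero-CPM features yield exactly zero counts. Deterministic given the
#' config seed (a distinct stream from truth generation).
#'
#' @param truth a `sim_truth` from [generate_peak_truth()] or
#'   [generate_gene_truth()].
#' @param config the same config used to build `truth` (defaults to the one
#'   stored in `truth`); a feature-count mismatch is an error.
#' @return list with `counts` (a [count_matrix()]) and `design` (sample sheet).
#' @export
simulate_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (nrow(truth$features) != config$n_features) {
    stopf("truth has %d features but config expects %d",
          nrow(truth$features), config$n_features)
  }
  assay <- if (inherits(truth, "peak_sim_truth")) "h3k4me1" else "rnaseq"
  design <- sim_design(truth, config)
  with_seed(config$seed + 1, {
    libs <- round(rlnorm_mean_cv(nrow(design), config$library_size_mean,
                                 config$library_size_cv))
    phi <- truth$features$dispersion
    counts <- matrix(0, nrow = config$n_features, ncol = nrow(design),
                     dimnames = list(truth$features$feature_id, design$sample_id))
    cond <- design$condition
    for (j in seq_len(nrow(design))) {
      mu <- truth$true_cpm[, cond[j]] * libs[j] / 1e6
      counts[, j] <- stats::rnbinom(config$n_features, size = 1 / phi, mu = mu)
    }
    coords <- if (assay == "h3k4me1") {
      truth$features[, c("chrom", "start", "end")]
    } else NULL
    design$assay <- assay
    list(counts = count_matrix(counts, coords),
         design = design[, c("sample_id", "assay", "stimulus", "time_h",
                             "washout_treatment", "pretreatment", "replicate")])
  })
}

# sample sheet for a truth object; `condition` column names the true_cpm column
sim_design <- function(truth, config) {
  if (inherits(truth, "peak_sim_truth")) {
    t_acute <- config$timepoints_h[2]
    t_wash <- config$timepoints_h[length(config$timepoints_h)]
    rows <- rbind(
      data.frame(stimulus = "unstim", time_h = 0, washout_treatment = "none",
                 condition = "unstim", stringsAsFactors = FALSE),
      data.frame(stimulus = c("ifng", "lps", "lps_rux"), time_h = t_acute,
                 washout_treatment = "none",
                 condition = c("ifng", "lps", "lps_rux")),
      data.frame(stimulus = "ifng", time_h = t_wash,
                 washout_treatment = names(config$treatment_effects),
                 condition = paste0("ifng_wash_", names(config$treatment_effects))),
      data.frame(stimulus = "lps", time_h = t_wash, washout_treatment = "media",
                 condition = "lps_wash_media")
    )
    rows$pretreatment <- "none"
  } else {
    tps <- config$timepoints_h
    arms <- expand.grid(pretreatment = c("pbs", "ifng"),
                        washout_treatment = c("media", "ruxolitinib"),
                        time_h = tps, stringsAsFactors = FALSE)
    arms$stimulus <- "lps"
    arms$condition <- paste0(arms$pretreatment, "_", arms$washout_treatment,
                             "_", arms$time_h, "h")
    acute <- data.frame(pretreatment = c("pbs", "ifng"),
                        washout_treatment = "none", time_h = 8,
                        stimulus = c("pbs", "ifng"),
                        condition = c("pbs_acute_8h", "ifng_acute_8h"),
                        stringsAsFactors = FALSE)
    rows <- rbind(acute[, c("stimulus", "time_h", "washout_treatment",
                            "condition", "pretreatment")],
                  arms[, c("stimulus", "time_h", "washout_treatment",
                           "condition", "pretreatment")])
  }
  reps <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    d <- rows
    d$replicate <- r
    d
  }))
  reps$sample_id <- paste0(reps$condition, "_r", reps$replicate)
  reps <- reps[order(match(reps$condition, rows$condition), reps$replicate), ]
  rownames(reps) <- NULL
  reps
}

#' One-call peak simulation
#'
#' @param config a [peak_sim_config()].
#' @return list with `counts`, `design` and `truth`.
#' @export
simulate_peaks <- function(config = peak_sim_config()) {
  truth <- generate_peak_truth(config)
  sim <- simulate_counts(truth, config)
  c(sim, list(truth = truth))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d features\n", nrow(x$features)))
  print(table(x$features$archetype))
  invisible(x)
}

#' Write simulated truth as TSV
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
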