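# Run configuration and end-to-end pipeline -----------------------------

default_run_config <- function() {
  list(
    mode = "peaks",              # "peaks" or "genes"
    counts = NULL, design = NULL, # input paths; NULL -> simulate
    simulate = list(),            # overrides for the sim config
    seed = 1,
    thresholds = list(l2fc_cutoff = 2, fdr_cutoff = 0.01, prior = 0.5,
                      induction_fold = 5, lps_fold_media = 5, lps_fold_rux = 4,
                      ratio_cutoff = 2, basal_l2fc_cutoff = 0.5,
                      persistence_mode = "vs_unstim", criteria = "media"),
    clustering = list(k = 3, seed = 17, n_restarts = 50,
                      cluster_on = "replicates"),
    out_dir = "macmem_out"
  )
}

#' Load and validate a run configuration
#'
#' Accepts a YAML path or a list; unknown top-level keys are rejected and
#' referenced input files must exist.
#'
#' @param config YAML file path or a (possibly partial) config list; unset
#'   fields take defaults.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_run_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(config[[k]])) {
      utils::modifyList(base[[k]], config[[k]])
    } else config[[k]]
  }
  if (!base$mode %in% c("peaks", "genes")) stopf("mode must be 'peaks' or 'genes'")
  num_thresh <- c("l2fc_cutoff", "fdr_cutoff", "prior", "induction_fold",
                  "lps_fold_media", "lps_fold_rux", "ratio_cutoff",
                  "basal_l2fc_cutoff")
  for (k in num_thresh) {
    if (base$thresholds[[k]] <= 0) stopf("threshold `%s` must be positive", k)
  }
  for (k in c("counts", "design")) {
    if (!is.null(base[[k]]) && !file.exists(base[[k]])) {
      stopf("configured %s file not found: %s", k, base[[k]])
    }
  }
  structure(base, class = "run_config")
}

#' Run the full analysis workflow
#'
#' Simulates (or loads) counts, then runs the stage order
#' filter -> differential -> classify -> cluster -> summarize and writes
#' TSV/BED/JSON artifacts plus a run manifest recording every configurable
#' decision. Byte-identical outputs for identical config + seed.
#'
#' @param config a [read_run_config()] input (path or list).
#' @return invisibly, a list with the result object (`peak_memory` or
#'   `gene_memory`), the simulation (when simulated) and artifact paths.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(manifest = file.path(cfg$out_dir, "manifest.json"))
  th <- cfg$thresholds
  sim <- NULL

  if (is.null(cfg$counts)) {
    sim_cfg <- if (cfg$mode == "peaks") {
      do.call(peak_sim_config, c(cfg$simulate, list(seed = cfg$seed)))
    } else {
      do.call(gene_sim_config, c(cfg$simulate, list(seed = cfg$seed)))
    }
    sim <- if (cfg$mode == "peaks") simulate_peaks(sim_cfg) else simulate_genes(sim_cfg)
    m <- sim$counts
    design <- sim$design
    paths$counts <- file.path(cfg$out_dir, "counts.tsv")
    paths$design <- file.path(cfg$out_dir, "design.csv")
    paths$truth <- file.path(cfg$out_dir, "truth.tsv")
    write_counts(m, paths$counts)
    write_design(design, paths$design)
    write_truth(sim$truth, paths$truth)
  } else {
    m <- read_counts(cfg$counts)
    design <- read_design(cfg$design)
  }

  if (cfg$mode == "peaks") {
    res <- peak_memory(m, design,
                       l2fc_cutoff = th$l2fc_cutoff, fdr_cutoff = th$fdr_cutoff,
                       prior = th$prior, persistence_mode = th$persistence_mode,
                       cluster_k = cfg$clustering$k,
                       cluster_seed = cfg$clustering$seed,
                       cluster_restarts = cfg$clustering$n_restarts,
                       cluster_on = cfg$clustering$cluster_on)
    for (s in names(res$contrasts)) {
      p <- file.path(cfg$out_dir, sprintf("contrast_%s_vs_unstim.tsv", s))
      utils::write.table(res$contrasts[[s]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[paste0("contrast_", s)]] <- p
    }
    if (!is.null(m$coords)) {
      feats <- data.frame(feature_id = m$feature_ids, m$coords,
                          stringsAsFactors = FALSE)
      for (s in names(res$induced)) {
        sel <- feats[feats$feature_id %in% res$induced[[s]], ]
        sel$l2fc <- res$contrasts[[s]]$l2fc[match(sel$feature_id,
                                                  res$contrasts[[s]]$feature_id)]
        p <- file.path(cfg$out_dir, sprintf("induced_%s.bed", s))
        write_bed(sel, p)
        paths[[paste0("induced_bed_", s)]] <- p
      }
      cl <- res$clusters
      for (tr in names(res$persistent)) {
        ids <- names(res$persistent[[tr]])[res$persistent[[tr]]]
        sel <- feats[feats$feature_id %in% ids, ]
        if (!is.null(cl)) {
          sel$feature_id <- paste0(
            sel$feature_id, "|",
            cl$assignment$cluster_label[match(sel$feature_id,
                                              cl$assignment$feature_id)])
        }
        p <- file.path(cfg$out_dir, sprintf("persistent_%s.bed", tr))
        write_bed(sel, p)
        paths[[paste0("persistent_bed_", tr)]] <- p
      }
    }
    if (!is.null(res$clusters)) {
      p <- file.path(cfg$out_dir, "clusters.tsv")
      utils::write.table(res$clusters$assignment, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths$clusters <- p
    }
    summ <- summary(res)
    summ$washout_shift <- lapply(summ$washout_shift, as.list)
    summ$cluster_sizes <- as.list(summ$cluster_sizes)
  } else {
    res <- gene_memory(m, design, criteria = th$criteria,
                       induction_fold = th$induction_fold,
                       lps_fold_media = th$lps_fold_media,
                       lps_fold_rux = th$lps_fold_rux,
                       ratio_cutoff = th$ratio_cutoff,
                       basal_l2fc_cutoff = th$basal_l2fc_cutoff,
                       prior = th$prior)
    paths$calls <- file.path(cfg$out_dir, "gene_calls.tsv")
    utils::write.table(res$calls, paths$calls, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    summ <- res$summary
    summ$tier_counts <- as.list(summ$tier_counts)
    summ$tier_counts_rux <- as.list(summ$tier_counts_rux)
  }

  paths$summary <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summ, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    package = "macmem",
    version = as.character(utils::packageVersion("macmem")),
    mode = cfg$mode, seed = cfg$seed,
    thresholds = cfg$thresholds, clustering = cfg$clustering,
    simulated = is.null(cfg$counts),
    sim_config = if (!is.null(sim)) {
      s <- unclass(sim$truth$config)
      lapply(s, function(v) if (!is.null(names(v))) as.list(v) else v)
    },
    artifacts = lapply(paths, basename),
    stages_complete = c("filter", "differential", "classify", "cluster",
                        "summarize")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(result = res, sim = sim, paths = paths, config = cfg))
}
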