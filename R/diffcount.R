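#' Counts-per-million normalization
#'
#' @param m a [count_matrix()] (or a bare matrix, in which case column sums
#'   are used as library sizes).
#' @return numeric matrix of CPM values, same dimensions as the counts.
#' @export
cpm_normalize <- function(m) {
  if (inherits(m, "count_matrix")) {
    counts <- m$counts
    libs <- m$lib_sizes
  } else {
    counts <- as.matrix(m)
    libs <- colSums(counts)
  }
  zero <- which(libs <= 0)
  if (length(zero)) {
    stopf("zero library size for sample '%s'",
          colnames(counts)[zero[1L]] %||% as.character(zero[1L]))
  }
  sweep(counts, 2, libs, "/") * 1e6
}

#' Log2 fold change with a prior count
#'
#' `log2((b + prior) / (a + prior))`, antisymmetric under swapping arguments.
#' The default prior of 0.5 CPM keeps zero-abundance features finite.
#'
#' @param cpm_b,cpm_a numeric CPM values (numerator condition first).
#' @param prior positive pseudo-CPM added to both sides.
#' @return log2 fold change(s), b vs a.
#' @export
log2_fc <- function(cpm_b, cpm_a, prior = 0.5) {
  if (any(prior <= 0)) stopf("`prior` must be > 0")
  log2((cpm_b + prior) / (cpm_a + prior))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment preserving input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values (FDR), same order as input.
#' @export
bh_adjust <- function(p) {
  assert_prob(p)
  stats::p.adjust(p, method = "BH")
}

# NB log-likelihood for one feature in one group at common CPM `mu_cpm`,
# with per-sample library-size offsets. phi = 0 falls back to Poisson.
nb_loglik <- function(counts, libs, mu_cpm, phi) {
  mu <- mu_cpm * libs / 1e6
  if (phi <= 0) {
    sum(stats::dpois(counts, lambda = pmax(mu, 1e-300), log = TRUE))
  } else {
    sum(stats::dnbinom(counts, size = 1 / phi, mu = pmax(mu, 1e-300), log = TRUE))
  }
}

# Maximize the NB likelihood over a single common CPM. Closed form for the
# Poisson limit; 1-D optimization on log(cpm) otherwise.
nb_fit_mu <- function(counts, libs, phi) {
  tot <- sum(counts)
  start <- tot / sum(libs) * 1e6 # Poisson MLE; exact when phi = 0
  if (tot == 0 || phi <= 0) {
    return(list(mu_cpm = start, loglik = nb_loglik(counts, libs, start, phi)))
  }
  lo <- log(start) - 4
  hi <- log(start) + 4
  opt <- stats::optimize(function(lmu) nb_loglik(counts, libs, exp(lmu), phi),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  list(mu_cpm = exp(opt$maximum), loglik = opt$objective)
}

#' Negative-binomial likelihood-ratio test for one feature
#'
#' Fits a common CPM under the null and per-group CPMs under the
#' alternative by NB maximum likelihood with library-size offsets, and
#' compares twice the log-likelihood difference to chi-squared(1). With
#' `phi = 0` this reduces exactly to the Poisson likelihood-ratio test.
#' An all-zero feature returns `p = 1`, `l2fc = 0`.
#'
#' @param counts_a,counts_b non-negative integer replicate counts per group.
#' @param lib_a,lib_b library sizes (same length as the counts vectors).
#' @param phi NB dispersion (variance = mu + phi * mu^2); `phi = 0` gives
#'   the Poisson limit.
#' @param prior prior CPM for the reported log2 fold change.
#' @return list with `l2fc` (b vs a), `p_value`, `lrt_stat`,
#'   `mean_cpm_a`, `mean_cpm_b`.
#' @export
nb_test <- function(counts_a, counts_b, lib_a = NULL, lib_b = NULL,
                    phi = 0, prior = 0.5) {
  if (length(counts_a) < 1L || length(counts_b) < 1L) {
    stopf("each group needs at least one replicate")
  }
  if (any(c(counts_a, counts_b) < 0) ||
      any(c(counts_a, counts_b) != round(c(counts_a, counts_b)))) {
    stopf("counts must be non-negative integers")
  }
  lib_a <- lib_a %||% rep(1e6, length(counts_a))
  lib_b <- lib_b %||% rep(1e6, length(counts_b))
  cpm_a <- mean(counts_a / lib_a * 1e6)
  cpm_b <- mean(counts_b / lib_b * 1e6)
  if (sum(counts_a) + sum(counts_b) == 0) {
    return(list(l2fc = 0, p_value = 1, lrt_stat = 0,
                mean_cpm_a = 0, mean_cpm_b = 0))
  }
  fit0 <- nb_fit_mu(c(counts_a, counts_b), c(lib_a, lib_b), phi)
  fit_a <- nb_fit_mu(counts_a, lib_a, phi)
  fit_b <- nb_fit_mu(counts_b, lib_b, phi)
  lrt <- max(0, 2 * (fit_a$loglik + fit_b$loglik - fit0$loglik))
  list(l2fc = log2_fc(cpm_b, cpm_a, prior),
       p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       lrt_stat = lrt,
       mean_cpm_a = cpm_a, mean_cpm_b = cpm_b)
}

# Per-feature method-of-moments dispersion on depth-scaled counts, pooled
# within groups, then shrunk toward a lowess trend on log mean CPM with
# `prior_df` prior degrees of freedom.
estimate_dispersions <- function(counts, libs, group, prior_df = 20) {
  scale <- mean(libs) / libs
  q <- sweep(counts, 2, scale, "*") # counts at common depth
  groups <- unique(group)
  n <- ncol(counts)
  resid_df <- n - length(groups)
  mu <- rowMeans(q)
  if (resid_df <= 0) {
    return(rep(0.05, nrow(counts))) # no replication: fall back to a typical value
  }
  ss <- 0
  for (g in groups) {
    cols <- which(group == g)
    qg <- q[, cols, drop = FALSE]
    ss <- ss + rowSums((qg - rowMeans(qg))^2)
  }
  s2 <- ss / resid_df
  phi_raw <- pmax((s2 - mu) / mu^2, 0)
  phi_raw[!is.finite(phi_raw)] <- 0
  # trend over expression; lowess is robust to the many zero MoM estimates
  keep <- mu > 0
  phi_trend <- rep(0.05, nrow(counts))
  if (sum(keep) >= 10) {
    lx <- log(mu[keep])
    fit <- stats::lowess(lx, phi_raw[keep], f = 0.5)
    phi_trend[keep] <- pmax(stats::approx(fit$x, fit$y, xout = lx, rule = 2,
                                          ties = mean)$y, 1e-8)
  }
  pmax((resid_df * phi_raw + prior_df * phi_trend) / (resid_df + prior_df), 1e-8)
}

#' Differential test between two sample groups across all features
#'
#' Runs the NB likelihood-ratio test ([nb_test()]) per feature with
#' empirical-Bayes moderated dispersions: per-feature method-of-moments
#' estimates shrunk toward a lowess mean-dispersion trend with a fixed
#' prior-degrees-of-freedom weight.
#'
#' @param m a [count_matrix()].
#' @param samples_a,samples_b sample ids of the reference (a) and test (b)
#'   groups; the reported `l2fc` is b vs a.
#' @param prior prior CPM for fold changes.
#' @param prior_df shrinkage weight for the dispersion trend (prior df).
#' @param phi optional fixed dispersion (scalar or per-feature vector)
#'   overriding estimation; mainly for calibration studies.
#' @return a `data.frame` of class `nb_contrast` with columns `feature_id`,
#'   `mean_cpm_a`, `mean_cpm_b`, `l2fc`, `p_value`, `fdr`.
#' @export
nb_diff <- function(m, samples_a, samples_b, prior = 0.5, prior_df = 20,
                    phi = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  miss <- setdiff(c(samples_a, samples_b), colnames(m$counts))
  if (length(miss)) stopf("unknown sample(s): %s", paste(miss, collapse = ", "))
  ca <- m$counts[, samples_a, drop = FALSE]
  cb <- m$counts[, samples_b, drop = FALSE]
  la <- m$lib_sizes[samples_a]
  lb <- m$lib_sizes[samples_b]
  nfeat <- nrow(m$counts)
  if (is.null(phi)) {
    phi <- estimate_dispersions(cbind(ca, cb), c(la, lb),
                                c(rep("a", length(samples_a)), rep("b", length(samples_b))),
                                prior_df = prior_df)
  }
  phi <- rep_len(phi, nfeat)
  l2fc <- p <- ma <- mb <- numeric(nfeat)
  for (i in seq_len(nfeat)) {
    r <- nb_test(ca[i, ], cb[i, ], la, lb, phi = phi[i], prior = prior)
    l2fc[i] <- r$l2fc; p[i] <- r$p_value
    ma[i] <- r$mean_cpm_a; mb[i] <- r$mean_cpm_b
  }
  out <- data.frame(feature_id = m$feature_ids,
                    mean_cpm_a = ma, mean_cpm_b = mb,
                    l2fc = l2fc, p_value = p, fdr = bh_adjust(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("nb_contrast", "data.frame")
  attr(out, "prior") <- prior
  out
}

#' @export
print.nb_contrast <- function(x, ...) {
  cat(sprintf("nb_contrast: %d features; %d at FDR < 0.01; l2fc range [%.2f, %.2f]\n",
              nrow(x), sum(x$fdr < 0.01), min(x$l2fc), max(x$l2fc)))
  NextMethod()
}

#' Acute abundance filter
#'
#' Keeps a feature if its replicate-mean CPM reaches the top half of
#' features (>= the across-feature median) in at least one acute condition
#' (by default: unstimulated, IFN-gamma 8 h, LPS 8 h).
#'
#' @param m a [count_matrix()].
#' @param design sample sheet `data.frame` (see [read_design()]).
#' @param acute_conditions condition labels (as produced by
#'   `stimulus_timeh` naming, e.g. `"ifng_8h"`) defining acute stimulation.
#' @return logical keep-mask over features, named by feature id.
#' @export
acute_abundance_filter <- function(m, design,
                                   acute_conditions = c("unstim_0h", "ifng_8h", "lps_8h")) {
  if (!length(acute_conditions)) stopf("`acute_conditions` must be nonempty")
  cpm <- cpm_normalize(m)
  keep <- rep(FALSE, nrow(cpm))
  for (cond in acute_conditions) {
    s <- samples_for(design, cond)
    if (!length(s)) stopf("no samples found for acute condition '%s'", cond)
    v <- rowMeans(cpm[, s, drop = FALSE])
    keep <- keep | (v >= stats::median(v))
  }
  names(keep) <- m$feature_ids
  keep
}

#' Induction call from a contrast
#'
#' A feature is induced when `l2fc > l2fc_cutoff` and `fdr < fdr_cutoff`,
#' both strict.
#'
#' @param contrast an `nb_contrast` (stimulus 8 h vs unstimulated).
#' @param l2fc_cutoff,fdr_cutoff strict thresholds (defaults 2 and 0.01).
#' @return logical vector named by feature id.
#' @export
call_induced <- function(contrast, l2fc_cutoff = 2, fdr_cutoff = 0.01) {
  out <- contrast$l2fc > l2fc_cutoff & contrast$fdr < fdr_cutoff
  names(out) <- contrast$feature_id
  out
}

# replicate-mean CPM per condition label; returns features x conditions matrix
condition_mean_cpm <- function(m, design, conditions) {
  cpm <- cpm_normalize(m)
  out <- sapply(conditions, function(cond) {
    s <- samples_for(design, cond)
    if (!length(s)) stopf("no samples for condition '%s'", cond)
    rowMeans(cpm[, s, drop = FALSE])
  })
  rownames(out) <- m$feature_ids
  out
}
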