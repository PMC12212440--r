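# Independent oracles used to cross-check the package's implementations.
# Each is written from the definition, not from the package's code path.

# Benjamini-Hochberg step-up, coded directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact two-sided signed-rank p by full enumeration of all sign vectors
# (zero differences dropped, ties mid-ranked, p = min(1, 2 * min tail))
wilcoxon_enum_oracle <- function(x, y) {
  d <- (y - x)[(y - x) != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# NB log-likelihood written from the gamma-function form (not dnbinom)
nb_ll_oracle <- function(counts, libs, mu_cpm, phi) {
  mu <- mu_cpm * libs / 1e6
  if (phi <= 0) return(sum(counts * log(mu) - mu - lgamma(counts + 1)))
  a <- 1 / phi
  sum(lgamma(counts + a) - lgamma(a) - lgamma(counts + 1) +
        a * log(a / (a + mu)) + counts * log(mu / (a + mu)))
}

# brute-force NB LRT p: generic numerical maximization over log-CPM
nb_lrt_oracle <- function(counts_a, counts_b, lib_a, lib_b, phi) {
  maximize <- function(counts, libs) {
    start <- log(max(sum(counts) / sum(libs) * 1e6, 1e-4))
    opt <- stats::optim(start, function(lmu) -nb_ll_oracle(counts, libs, exp(lmu), phi),
                        method = "Brent", lower = start - 8, upper = start + 8)
    -opt$value
  }
  ll0 <- maximize(c(counts_a, counts_b), c(lib_a, lib_b))
  ll1 <- maximize(counts_a, lib_a) + maximize(counts_b, lib_b)
  stats::pchisq(max(0, 2 * (ll1 - ll0)), df = 1, lower.tail = FALSE)
}

f1_score <- function(pred, truth) {
  tp <- sum(pred & truth)
  if (tp == 0) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(truth)
  2 * prec * rec / (prec + rec)
}

# best label agreement over all bijections between predicted and true labels
bijective_agreement <- function(pred, truth) {
  labs <- unique(c(pred, truth))
  perms <- combinat_perms(seq_along(labs))
  best <- 0
  for (p in perms) {
    mapped <- labs[p][match(pred, labs)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# tiny well-formed peak count matrix with an explicit design, for unit tests
tiny_peak_matrix <- function(counts_by_cond, n_rep = 2) {
  conds <- names(counts_by_cond)
  mats <- lapply(conds, function(cn) {
    m <- counts_by_cond[[cn]]
    colnames(m) <- paste0(cn, "_r", seq_len(ncol(m)))
    m
  })
  counts <- do.call(cbind, mats)
  rownames(counts) <- sprintf("pk%02d", seq_len(nrow(counts)))
  m <- count_matrix(counts)
  parse_cond <- function(cn) {
    # labels like "unstim_0h", "ifng_8h", "ifng_96h_media"
    parts <- strsplit(cn, "_(?=[0-9]+h)", perl = TRUE)[[1]]
    rest <- strsplit(parts[2], "_")[[1]]
    list(stimulus = parts[1], time_h = as.numeric(sub("h", "", rest[1])),
         washout = if (length(rest) > 1) paste(rest[-1], collapse = "_") else "none")
  }
  design <- do.call(rbind, lapply(conds, function(cn) {
    pc <- parse_cond(cn)
    nr <- ncol(counts_by_cond[[cn]])
    data.frame(sample_id = paste0(cn, "_r", seq_len(nr)), assay = "h3k4me1",
               stimulus = pc$stimulus, time_h = pc$time_h,
               washout_treatment = pc$washout, pretreatment = "none",
               replicate = seq_len(nr), stringsAsFactors = FALSE)
  }))
  list(m = m, design = design)
}
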