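# Z-scored k-means behavioral clustering --------------------------------

#' Row-wise z-scoring
#'
#' Subtracts each row's mean and divides by its sample standard deviation
#' (n - 1 denominator). Constant rows map to all-zero.
#'
#' @param values numeric matrix, features x conditions, >= 2 columns.
#' @return z-scored matrix of the same dimensions.
#' @export
zscore_rows <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stopf("z-scoring needs at least 2 columns")
  mu <- rowMeans(values)
  sd <- apply(values, 1, stats::sd)
  z <- (values - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

# squared Euclidean distances from every row of x to every center row
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- apply(dist2_to_centers(x, centers[seq_len(j - 1), , drop = FALSE]),
                  1, min)
      d2 <- pmax(d2, 0)
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
    }
  }
  centers
}

# one Lloyd run; returns assignment, centers, final WCSS and per-iteration
# WCSS trace (non-increasing by construction)
lloyd_run <- function(x, k, max_iter = 100) {
  centers <- kmeanspp_init(x, k)
  assign_prev <- rep(0L, nrow(x))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assign_cur <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters with the point farthest from its center
    for (j in seq_len(k)) {
      if (!any(assign_cur == j)) {
        far <- which.max(d2[cbind(seq_len(nrow(x)), assign_cur)])
        centers[j, ] <- x[far, ]
        assign_cur[far] <- j
      }
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assign_cur == j, , drop = FALSE])
    }
    wcss <- sum((x - centers[assign_cur, , drop = FALSE])^2)
    trace <- c(trace, wcss)
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
  }
  list(assignment = assign_cur, centers = centers,
       wcss = trace[length(trace)], trace = trace)
}

#' Behavioral k-means clustering of z-scored signals
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_restarts` by total
#' within-cluster sum of squares, deterministic given `seed`. When
#' `post_cols` and `acute_cols` are supplied and `k = 3`, clusters are
#' relabeled by descending (mean post-washout z minus mean acute z) as
#' `augment` > `persist` > `decay`, reproducing the three washout behaviors
#' seen in stimulus-washout heatmaps.
#'
#' @param z z-scored matrix ([zscore_rows()]) with feature ids as rownames.
#' @param k number of clusters (>= 1; k = 1 is a degenerate mode for
#'   diagnostics).
#' @param seed RNG seed.
#' @param n_restarts independent k-means++ starts.
#' @param post_cols,acute_cols column indices (or names) of the
#'   post-washout and acute-stimulation conditions used for trend labeling.
#' @param labels semantic labels assigned in descending trend order.
#' @return object of class `behavior_clusters`: list with `assignment`
#'   (data.frame feature_id, cluster_id in `[0, k)`, cluster_label),
#'   `centers`, `wcss`, `trace` (per-iteration WCSS of the best run),
#'   `k`, `seed`, `n_restarts`.
#' @export
kmeans_cluster <- function(z, k = 3, seed = 1, n_restarts = 50,
                           post_cols = NULL, acute_cols = NULL,
                           labels = c("augment", "persist", "decay")) {
  z <- as.matrix(z)
  if (k > nrow(z)) stopf("k = %d exceeds the %d available features", k, nrow(z))
  if (k < 1) stopf("k must be >= 1")
  best <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      run <- lloyd_run(z, k)
      if (is.null(best) || run$wcss < best$wcss) best <- run
    }
    best
  })
  # canonical cluster order: by trend when labeling columns are given,
  # otherwise by first feature occurrence (stable across row order)
  if (!is.null(post_cols) && !is.null(acute_cols)) {
    trend <- sapply(seq_len(k), function(j) {
      mean(best$centers[j, post_cols]) - mean(best$centers[j, acute_cols])
    })
    ord <- order(trend, decreasing = TRUE)
  } else {
    ord <- unique(best$assignment)
  }
  remap <- match(seq_len(k), ord)
  cluster_id <- remap[best$assignment] - 1L
  lab <- if (k == length(labels)) labels[cluster_id + 1L] else
    paste0("cluster_", cluster_id)
  assignment <- data.frame(
    feature_id = rownames(z) %||% as.character(seq_len(nrow(z))),
    cluster_id = cluster_id, cluster_label = lab,
    stringsAsFactors = FALSE
  )
  structure(list(assignment = assignment,
                 centers = best$centers[ord, , drop = FALSE],
                 wcss = best$wcss, trace = best$trace,
                 k = k, seed = seed, n_restarts = n_restarts),
            class = "behavior_clusters")
}

#' @export
print.behavior_clusters <- function(x, ...) {
  cat(sprintf("behavior_clusters: k = %d, WCSS = %.2f (best of %d restarts, seed %d)\n",
              x$k, x$wcss, x$n_restarts, x$seed))
  print(table(x$assignment$cluster_label))
  invisible(x)
}

# Match cluster centroids to acute-response templates (used for the acute
# stimulus-specificity clustering): templates are z-profiles over the
# condition columns; each cluster takes the label of its best-correlated
# template (greedy one-to-one).
label_clusters_by_template <- function(clusters, templates) {
  k <- clusters$k
  if (nrow(templates) != k) stopf("need one template per cluster")
  cors <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cors[i, j] <- stats::cor(clusters$centers[i, ], templates[j, ])
  }
  lab <- rep(NA_character_, k)
  for (step in seq_len(k)) {
    ij <- arrayInd(which.max(cors), dim(cors))
    lab[ij[1]] <- rownames(templates)[ij[2]]
    cors[ij[1], ] <- -Inf
    cors[, ij[2]] <- -Inf
  }
  out <- clusters
  out$assignment$cluster_label <- lab[out$assignment$cluster_id + 1L]
  out
}
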