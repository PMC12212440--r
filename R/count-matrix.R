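#' Feature-by-sample count matrix
#'
#' Container for non-negative integer counts with optional BED-style peak
#' coordinates (0-based, half-open) and per-sample library sizes. Library
#' sizes are always the column sums of the count matrix; they are recomputed
#' at construction so the invariant cannot drift.
#'
#' @param counts integer matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids).
#' @param coords optional `data.frame` with columns `chrom`, `start`, `end`,
#'   one row per feature in matrix order; `start < end` is enforced.
#' @return an object of class `count_matrix`: a list with elements `counts`,
#'   `feature_ids`, `coords` (or `NULL`) and `lib_sizes`.
#' @examples
#' m <- count_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("pk1", "pk2"), c("s1", "s2"))))
#' m$lib_sizes
#' @export
count_matrix <- function(counts, coords = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("`counts` needs rownames (feature ids) and colnames (sample ids)")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stopf("duplicate feature_id: '%s'", dup)
  }
  if (anyDuplicated(colnames(counts))) {
    stopf("duplicate sample ids in counts")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(counts))
    stopf("counts must be non-negative integers; offending entry at row %d, column %d",
          rc[1L], rc[2L])
  }
  storage.mode(counts) <- "double" # exact for counts < 2^53, avoids int overflow
  if (!is.null(coords)) {
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(coords))) stopf("coords needs columns chrom, start, end")
    if (nrow(coords) != nrow(counts)) stopf("coords rows must match features")
    if (any(coords$start >= coords$end)) {
      i <- which(coords$start >= coords$end)[1L]
      stopf("coordinate start >= end at row %d ('%s')", i, rownames(counts)[i])
    }
    coords <- data.frame(chrom = as.character(coords$chrom),
                         start = as.integer(coords$start),
                         end = as.integer(coords$end),
                         stringsAsFactors = FALSE)
  }
  structure(list(counts = counts,
                 feature_ids = rownames(counts),
                 coords = coords,
                 lib_sizes = colSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$coords)) "" else " (with peak coordinates)"))
  cat(sprintf("library sizes: %s ... \n",
              paste(format(utils::head(x$lib_sizes, 4), big.mark = ","),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by feature and/or sample
#'
#' @param x a [count_matrix()].
#' @param features feature ids or indices (default: all).
#' @param samples sample ids or indices (default: all).
#' @return a `count_matrix` restricted to the requested rows/columns, with
#'   library sizes recomputed from the retained features' column sums only
#'   when `drop_libs = TRUE`; by default the original per-sample library
#'   sizes are kept so CPM stays comparable after feature filtering.
#' @param drop_libs recompute library sizes from the subset (default FALSE).
#' @export
subset_counts <- function(x, features = NULL, samples = NULL, drop_libs = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  fi <- if (is.null(features)) seq_len(nrow(x$counts)) else features
  si <- if (is.null(samples)) seq_len(ncol(x$counts)) else samples
  cm <- x$counts[fi, si, drop = FALSE]
  co <- if (is.null(x$coords)) NULL else {
    idx <- if (is.character(fi)) match(fi, x$feature_ids) else fi
    x$coords[idx, , drop = FALSE]
  }
  out <- count_matrix(cm, co)
  if (!drop_libs) out$lib_sizes <- x$lib_sizes[si]
  out
}

#' Read a counts TSV into a count_matrix
#'
#' Expects a header line; first column `feature_id`, optionally followed by
#' `chrom`, `start`, `end`, then one integer column per sample.
#'
#' @param path path to a tab-separated counts table.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stopf("counts file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(tab)) stopf("counts TSV must have a feature_id column")
  has_coords <- all(c("chrom", "start", "end") %in% names(tab))
  meta_cols <- if (has_coords) c("feature_id", "chrom", "start", "end") else "feature_id"
  samp_cols <- setdiff(names(tab), meta_cols)
  if (!length(samp_cols)) stopf("counts TSV has no sample columns")
  if (anyDuplicated(tab$feature_id)) {
    stopf("duplicate feature_id: '%s'", tab$feature_id[duplicated(tab$feature_id)][1L])
  }
  cm <- as.matrix(tab[, samp_cols, drop = FALSE])
  for (j in seq_along(samp_cols)) {
    col <- cm[, j]
    bad <- which(!is.finite(col) | col < 0 | col != round(col))
    if (length(bad)) {
      stopf("non-integer or negative count at row %d, column '%s'", bad[1L], samp_cols[j])
    }
  }
  rownames(cm) <- tab$feature_id
  count_matrix(cm, if (has_coords) tab[, c("chrom", "start", "end")] else NULL)
}

#' Write a count_matrix as TSV
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(feature_id = x$feature_ids, stringsAsFactors = FALSE)
  if (!is.null(x$coords)) tab <- cbind(tab, x$coords)
  tab <- cbind(tab, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' The sample sheet is a CSV with columns `sample_id`, `assay`, `stimulus`,
#' `time_h`, `washout_treatment`, `pretreatment`, `replicate`.
#'
#' @param path CSV path.
#' @return a `data.frame` with one row per sample.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stopf("design file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay", "stimulus", "time_h", "washout_treatment",
            "pretreatment", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("design missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stopf("duplicate sample_id in design")
  d
}

#' @rdname read_design
#' @param design a design `data.frame`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write peaks as 6-column BED
#'
#' Coordinates follow BED convention (0-based, half-open). The score column
#' is `round(1000 * min(1, l2fc / 5))`, clipped below at 0; strand is ".".
#' Rows are sorted by chromosome then start.
#'
#' @param features `data.frame` with `feature_id`, `chrom`, `start`, `end`
#'   and optionally `l2fc` (score defaults to 0 when absent).
#' @param path output path.
#' @export
write_bed <- function(features, path) {
  need <- c("feature_id", "chrom", "start", "end")
  if (!all(need %in% names(features))) {
    stopf("features must carry columns %s", paste(need, collapse = ", "))
  }
  if (nrow(features) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  l2fc <- if ("l2fc" %in% names(features)) features$l2fc else 0
  score <- round(1000 * pmin(1, pmax(0, l2fc / 5)))
  bed <- data.frame(chrom = features$chrom, start = features$start,
                    end = features$end, name = features$feature_id,
                    score = score, strand = ".", stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# condition label used throughout: stimulus_8h, ifng_96h_media, ...
condition_label <- function(design) {
  lab <- paste0(design$stimulus, "_", design$time_h, "h")
  w <- !is.na(design$washout_treatment) & design$washout_treatment != "none"
  lab[w] <- paste0(lab[w], "_", design$washout_treatment[w])
  lab
}

# sample ids belonging to one condition label
samples_for <- function(design, label) {
  design$sample_id[condition_label(design) == label]
}
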