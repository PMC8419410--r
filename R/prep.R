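#' Construct an ASV count table
#'
#' Light container for a samples-by-ASVs integer count matrix with unique
#' sample and ASV ids and optional per-ASV taxonomy strings.
#'
#' @param counts non-negative integer matrix, samples in rows, ASVs in
#'   columns, both dimensions named.
#' @param taxonomy optional character vector (Kingdom..Species strings),
#'   one per ASV.
#' @return object of class `asv_table` (the matrix, with a `taxonomy`
#'   attribute).
#' @export
asv_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_invalid("counts must have sample (row) and ASV (column) names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop_invalid("sample and ASV ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("counts must be non-negative integers")
  if (nrow(counts) && any(rowSums(counts) == 0))
    stop_invalid("all-zero sample rows are not allowed")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != ncol(counts))
      stop_invalid("taxonomy must have one entry per ASV")
    names(taxonomy) <- colnames(counts)
  }
  structure(counts, taxonomy = taxonomy, class = c("asv_table", "matrix", "array"))
}

counts_of <- function(table) {
  if (inherits(table, "asv_table")) return(unclass_table(table))
  if (is.matrix(table)) return(table)
  stop_invalid("expected an asv_table or matrix")
}

unclass_table <- function(table) {
  x <- table
  attr(x, "taxonomy") <- NULL
  class(x) <- c("matrix", "array")
  x
}

retable <- function(table, counts) {
  tax <- attr(table, "taxonomy")
  if (!is.null(tax)) tax <- tax[colnames(counts)]
  asv_table(counts, taxonomy = tax)
}

#' @export
print.asv_table <- function(x, ...) {
  cat("ASV count table:", nrow(x), "samples x", ncol(x), "ASVs;",
      "total reads", format(sum(as.numeric(x)), big.mark = ","), "\n")
  invisible(x)
}

#' Remove ASVs below a fraction of total reads
#'
#' Drops ASVs whose total count is strictly less than `min_fraction` of
#' the grand total (default 1e-5, i.e. less than 1/1000th of a percent of
#' total reads).  The sample set is unchanged.
#'
#' @param table an [asv_table()].
#' @param min_fraction fraction of the grand total below which an ASV is
#'   removed.
#' @return filtered [asv_table()].
#' @export
filter_min_fraction <- function(table, min_fraction = 1e-5) {
  counts <- counts_of(table)
  if (!length(counts)) stop_invalid("empty count table")
  thr <- min_fraction * sum(as.numeric(counts))
  keep <- colSums(counts) >= thr   # "less than" removed, ties kept
  retable(table, counts[, keep, drop = FALSE])
}

#' Keep ASVs present in at least a fraction of samples
#'
#' Prevalence is the fraction of samples with a nonzero count; ASVs with
#' prevalence >= `min_prevalence` are kept ("at least" semantics: ties at
#' the boundary are kept).
#'
#' @param table an [asv_table()].
#' @param min_prevalence fraction in \[0, 1\].
#' @return filtered [asv_table()].
#' @export
prevalence_filter <- function(table, min_prevalence) {
  check_prob(min_prevalence, "min_prevalence")
  counts <- counts_of(table)
  prev <- colSums(counts > 0) / nrow(counts)
  keep <- prev >= min_prevalence - 1e-12
  retable(table, counts[, keep, drop = FALSE])
}

#' Representative rarefaction to the minimum sequencing depth
#'
#' Each sample is subsampled without replacement `n_draws` times to the
#' minimum row sum; the per-sample centroid is the per-ASV mean over the
#' draws, and the retained profile is the draw closest to that centroid
#' (Euclidean by default; Bray-Curtis available).  Ties go to the lowest
#' draw index.  Deterministic for a given seed.
#'
#' @param table an [asv_table()]; all sample depths must be >= 1.
#' @param n_draws number of rarefaction draws (>= 1).
#' @param seed integer seed.
#' @param distance `"euclidean"` (default) or `"bray"` centroid distance.
#' @return an [asv_table()] with every row summing to the minimum depth
#'   and no count exceeding the original.
#' @export
representative_rarefaction <- function(table, n_draws = 100, seed,
                                       distance = c("euclidean", "bray")) {
  distance <- match.arg(distance)
  counts <- counts_of(table)
  if (n_draws < 1) stop_invalid("n_draws must be >= 1")
  depths <- rowSums(counts)
  if (any(depths < 1)) stop_invalid("zero-depth sample(s) present")
  depth <- min(depths)
  n <- nrow(counts)
  set.seed(as.integer(seed))
  draws <- vector("list", n_draws)
  centroid <- matrix(0, n, ncol(counts))
  for (d in seq_len(n_draws)) {
    draws[[d]] <- rarefy_once(counts, depth)
    centroid <- centroid + draws[[d]]
  }
  centroid <- centroid / n_draws
  best_dist <- rep(Inf, n)
  best <- matrix(0L, n, ncol(counts), dimnames = dimnames(counts))
  for (d in seq_len(n_draws)) {
    draw <- draws[[d]]
    dist_d <- if (distance == "euclidean") {
      rowSums((draw - centroid)^2)
    } else {
      rowSums(abs(draw - centroid)) / rowSums(draw + centroid)
    }
    upd <- dist_d < best_dist - 1e-12     # strict: ties keep earlier draw
    if (any(upd)) {
      best[upd, ] <- draw[upd, , drop = FALSE]
      best_dist[upd] <- dist_d[upd]
    }
  }
  retable(table, best)
}

# one exact subsample without replacement for every sample row:
# multivariate hypergeometric, drawn ASV by ASV with rhyper vectorized
# across samples (conditioning on the reads remaining to the right)
rarefy_once <- function(counts, depth) {
  n <- nrow(counts)
  p <- ncol(counts)
  n_rem <- rep(as.numeric(depth), n)     # reads still to draw, per sample
  N_rem <- rowSums(counts)               # reads still available, per sample
  out <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    m <- counts[, j]
    N_rem <- N_rem - m
    x <- stats::rhyper(n, m, N_rem, n_rem)
    out[, j] <- x
    n_rem <- n_rem - x
  }
  out
}

#' Dichotomize an ASV's rarefied counts by prevalence class
#'
#' ASVs present in 20% to <80% of samples are coded present/absent (1 iff
#' count > 0); ASVs in >= 80% of samples are coded high/low (1 iff count
#' >= the ASV's median count across all samples, zeros included; ties at
#' the median are "high").  Prevalence below 20% is a contract violation:
#' the caller must have prevalence-filtered first.
#'
#' @param table an [asv_table()] (normally the rarefied table restricted
#'   to the analytic cohort).
#' @param feature_id ASV id.
#' @return object of class `dichotomized_feature`: list with `feature_id`,
#'   `mode` (`"presence"` or `"median_split"`), `values` (named 0/1 per
#'   sample), `prevalence`.
#' @export
dichotomize <- function(table, feature_id) {
  counts <- counts_of(table)
  if (!feature_id %in% colnames(counts))
    stop_invalid("feature '", feature_id, "' not in table")
  x <- counts[, feature_id]
  prev <- mean(x > 0)
  if (prev < 0.20 - 1e-12)
    stop_invalid("feature '", feature_id, "' has prevalence ", round(prev, 3),
                 " < 0.20; filter before dichotomizing")
  if (prev >= 0.80 - 1e-12) {
    med <- stats::median(x)
    vals <- as.numeric(x >= med)
    mode <- "median_split"
  } else {
    vals <- as.numeric(x > 0)
    mode <- "presence"
  }
  names(vals) <- rownames(counts)
  structure(list(feature_id = feature_id, mode = mode, values = vals,
                 prevalence = prev), class = "dichotomized_feature")
}

#' Dichotomize a pathway abundance at its median
#'
#' Pathway abundances are split as above/at-or-below the median: value 1
#' iff abundance is strictly greater than the median (ties go to "low",
#' deliberately the opposite of the ASV >=-median rule).
#'
#' @param values named numeric per-subject abundances.
#' @param feature_id pathway id (for labelling).
#' @return a `dichotomized_feature` with mode `"median_split"`.
#' @export
dichotomize_pathway <- function(values, feature_id = "pathway") {
  if (is.null(names(values)))
    stop_invalid("pathway values must be named by subject id")
  if (length(unique(values)) == 1L) {
    warning("pathway '", feature_id, "': all abundances equal; all-zero feature")
    vals <- rep(0, length(values))
  } else {
    vals <- as.numeric(values > stats::median(values))
  }
  names(vals) <- names(values)
  structure(list(feature_id = feature_id, mode = "median_split",
                 values = vals, prevalence = mean(values > 0)),
            class = "dichotomized_feature")
}
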