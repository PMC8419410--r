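#' Centered log-ratio transform
#'
#' Per sample: log(count + pseudocount) minus the sample mean of the
#' logged values, mapping compositional counts onto an unconstrained scale
#' where correlations are meaningful.  Every transformed row sums to zero.
#'
#' @param table [asv_table()] or count matrix (samples x ASVs).
#' @param pseudocount positive offset added before logging (default 1).
#' @return real matrix, same dimnames.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  if (pseudocount <= 0) stop_invalid("pseudocount must be > 0")
  counts <- counts_of(table)
  lg <- log(counts + pseudocount)
  sweep(lg, 1L, rowMeans(lg))
}

#' Correlation matrix over CLR-transformed abundances
#'
#' Pearson by default.  `method = "sparse_selection"` additionally zeroes
#' correlations on pairs absent from a penalized neighborhood-selection
#' graph (per-column lasso regressions; an edge survives if either
#' direction selects it), a sparse estimate in the SPIEC-EASI spirit.
#'
#' @param clr real matrix (samples x ASVs), e.g. from [clr_transform()].
#' @param method `"pearson"` or `"sparse_selection"`.
#' @param lambda lasso penalty for sparse selection; default
#'   `sqrt(log(p)/n)`.
#' @return symmetric correlation matrix, unit diagonal.
#' @export
correlation_matrix <- function(clr, method = c("pearson", "sparse_selection"),
                               lambda = NULL) {
  method <- match.arg(method)
  if (nrow(clr) < 3) stop_invalid("need at least 3 samples")
  sds <- apply(clr, 2, stats::sd)
  if (any(sds == 0))
    stop_invalid("zero-variance column(s): ",
                 paste(colnames(clr)[sds == 0], collapse = ", "))
  r <- stats::cor(clr)
  if (method == "sparse_selection") {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop_invalid("sparse_selection requires the 'glmnet' package")
    p <- ncol(clr)
    lambda <- lambda %||% sqrt(log(p) / nrow(clr))
    sel <- matrix(FALSE, p, p)
    for (j in seq_len(p)) {
      fit <- glmnet::glmnet(clr[, -j, drop = FALSE], clr[, j],
                            lambda = lambda, standardize = TRUE)
      nz <- which(as.numeric(fit$beta) != 0)
      sel[j, seq_len(p)[-j][nz]] <- TRUE
    }
    keep <- sel | t(sel)
    diag(keep) <- TRUE
    r[!keep] <- 0
  }
  r
}

#' Soft-threshold a correlation matrix into an adjacency matrix
#'
#' Unsigned network: \eqn{a_{ij} = |r_{ij}|^\beta}, diagonal 1.
#'
#' @param corr correlation matrix.
#' @param beta soft-thresholding power (>= 1, default 6).
#' @return adjacency matrix with entries in \[0, 1\].
#' @export
soft_threshold <- function(corr, beta = 6) {
  if (beta < 1) stop_invalid("beta must be >= 1")
  a <- abs(corr)^beta
  diag(a) <- 1
  a
}

#' Select a soft-thresholding power by scale-free fit
#'
#' For each candidate power, builds the adjacency, computes node
#' connectivities, and fits log10 p(k) ~ log10 k over connectivity bins;
#' returns the smallest power whose fit R-squared reaches `target_r2`, or
#' the power maximizing it.  Falls back to `default` with a warning when
#' the degree distribution is degenerate.
#'
#' @param corr correlation matrix.
#' @param powers candidate powers (default 1:10).
#' @param target_r2 scale-free fit target (default 0.8).
#' @param default fallback power (default 6).
#' @return selected power.
#' @export
pick_soft_threshold <- function(corr, powers = 1:10, target_r2 = 0.8,
                                default = 6) {
  if (length(powers) < 2) stop_invalid("need at least 2 candidate powers")
  r2s <- vapply(powers, function(b) {
    a <- soft_threshold(corr, b)
    k <- rowSums(a) - 1
    if (length(unique(round(k, 10))) < 3) return(NA_real_)
    nb <- min(10L, length(unique(k)))
    bins <- cut(k, breaks = nb)
    kmean <- tapply(k, bins, mean)
    pk <- tapply(k, bins, length) / length(k)
    ok <- !is.na(kmean) & kmean > 0 & pk > 0
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(log10(kmean[ok]), log10(pk[ok]))^2
  }, numeric(1))
  if (all(is.na(r2s))) {
    warning("degenerate degree distribution; falling back to power ", default)
    return(default)
  }
  pass <- which(!is.na(r2s) & r2s >= target_r2)
  if (length(pass)) powers[min(pass)] else powers[which.max(r2s)]
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                       {\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{k_i = \sum_{u \ne i} a_{iu}}; diagonal 1.  Blends direct
#' adjacency with shared-neighbourhood strength.
#'
#' @param adjacency symmetric adjacency with unit diagonal, entries in
#'   \[0, 1\].
#' @return symmetric similarity matrix in \[0, 1\], unit diagonal.
#' @export
tom <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(a < 0 | a > 1)) stop_invalid("adjacency entries must lie in [0, 1]")
  k <- rowSums(a) - diag(a)
  # sum_{u != i,j} a_iu a_uj = (A^2)_ij - a_ii a_ij - a_ij a_jj
  l <- a %*% a - outer(diag(a), rep(1, ncol(a))) * a - a * outer(rep(1, nrow(a)), diag(a))
  num <- l + a
  den <- outer(k, k, pmin) + 1 - a
  t_mat <- num / den
  diag(t_mat) <- 1
  (t_mat + t(t_mat)) / 2
}

#' Detect co-occurrence modules from a TOM similarity
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM.
#' By default the dendrogram receives a static cut at dissimilarity
#' `cut_height` (0.99): correlated blocks merge well below it while
#' unrelated taxa, whose topological overlap is near zero, join only at
#' heights approaching 1 and are left as unassigned singletons.  A
#' quantile-of-merge-heights cut is available via `cut_quantile` but lets
#' background taxa chain-merge into the blocks.  Clusters smaller than
#' `min_size` are left unassigned (label 0).  Deterministic; module labels
#' are ordered by decreasing size, ties broken by smallest member id.
#'
#' @param tom_similarity TOM matrix from [tom()] with ASV dimnames.
#' @param min_size minimum members for a retained module (default 3).
#' @param cut_height static cut on the 1 - TOM scale (default 0.99).
#' @param cut_quantile optional: cut at this quantile of the merge heights
#'   instead of at `cut_height`.
#' @return object of class `module_set` with `assignment` (named integer,
#'   0 = unassigned); eigengenes are added by [merge_modules()].
#' @export
detect_modules <- function(tom_similarity, min_size = 3, cut_height = 0.99,
                           cut_quantile = NULL) {
  tm <- as.matrix(tom_similarity)
  if (nrow(tm) < min_size) stop_invalid("fewer ASVs than min_size")
  diss <- stats::as.dist(1 - tm)
  hc <- stats::hclust(diss, method = "average")
  h <- if (is.null(cut_quantile)) cut_height else
    stats::quantile(hc$height, cut_quantile, names = FALSE)
  cl <- stats::cutree(hc, h = h)
  relabel_modules(cl, min_size, colnames(tm))
}

relabel_modules <- function(cl, min_size, ids) {
  names(cl) <- ids
  tab <- table(cl)
  keep <- names(tab)[tab >= min_size]
  assignment <- integer(length(cl))
  names(assignment) <- ids
  if (length(keep)) {
    # order by decreasing size, ties by smallest member id
    first_id <- vapply(keep, function(k) min(ids[cl == k]), character(1))
    ord <- keep[order(-tab[keep], first_id)]
    for (m in seq_along(ord)) assignment[cl == ord[m]] <- m
  }
  structure(list(assignment = assignment, eigengenes = NULL,
                 variance_explained = NULL,
                 sizes = as.integer(table(factor(assignment[assignment > 0])))),
            class = "module_set")
}

#' Module eigengene
#'
#' First principal component of the module's standardized abundance
#' matrix: member columns are z-scored, the first right singular vector's
#' projection is rescaled to unit variance, and its sign is oriented so
#' the mean correlation with member columns is positive.
#'
#' @param abundance samples-by-members real matrix (CLR abundances).
#' @return list with `eigengene` (named per-sample values, unit variance)
#'   and `variance_explained` (first squared singular value over the
#'   total).
#' @export
eigengene <- function(abundance) {
  x <- as.matrix(abundance)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s) from eigengene computation: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 1) stop_invalid("no non-constant columns in module")
  z <- scale(x)
  sv <- svd(z)
  e <- sv$u[, 1] * sv$d[1]
  e <- e / stats::sd(e)
  if (mean(stats::cor(e, z)) < 0) e <- -e
  names(e) <- rownames(x)
  list(eigengene = e,
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Merge correlated modules by eigengene similarity
#'
#' Iteratively computes module eigengenes, merges the closest pair whose
#' eigengene correlation reaches `r_threshold`, and repeats until no pair
#' qualifies.  On convergence no two retained modules have eigengene
#' correlation >= `r_threshold`.
#'
#' @param moduleset a [detect_modules()] result.
#' @param abundances samples-by-ASVs CLR matrix covering the assigned
#'   ASVs.
#' @param r_threshold merge threshold on the eigengene correlation
#'   (default 0.5).
#' @param min_size retained-module size floor reapplied after merging.
#' @return `module_set` with final `assignment`, `eigengenes`
#'   (samples x modules matrix, columns `M1`, `M2`, ...),
#'   `variance_explained` and `sizes`.
#' @export
merge_modules <- function(moduleset, abundances, r_threshold = 0.5,
                          min_size = 3) {
  stopifnot(inherits(moduleset, "module_set"))
  cl <- moduleset$assignment
  ids <- names(cl)
  if (!all(ids %in% colnames(abundances)))
    stop_invalid("abundance matrix does not cover all assigned ASVs")
  if (!any(cl > 0)) stop_invalid("no retained modules to merge")

  eg_of <- function(cl) {
    labs <- sort(unique(cl[cl > 0]))
    egs <- sapply(labs, function(m)
      eigengene(abundances[, ids[cl == m], drop = FALSE])$eigengene)
    colnames(egs) <- as.character(labs)
    egs
  }
  repeat {
    labs <- sort(unique(cl[cl > 0]))
    if (length(labs) < 2) break
    egs <- eg_of(cl)
    cc <- stats::cor(egs)
    diag(cc) <- -Inf
    if (max(cc) < r_threshold) break
    pair <- which(cc == max(cc), arr.ind = TRUE)[1, ]  # closest pair first
    a <- as.integer(colnames(cc)[pair[2]])
    b <- as.integer(rownames(cc)[pair[1]])
    cl[cl == max(a, b)] <- min(a, b)
  }
  # finalize: size floor, relabel by size, compute eigengenes
  out <- relabel_modules(cl, min_size, ids)
  cl <- out$assignment
  labs <- sort(unique(cl[cl > 0]))
  if (length(labs)) {
    egl <- lapply(labs, function(m)
      eigengene(abundances[, ids[cl == m], drop = FALSE]))
    egs <- sapply(egl, `[[`, "eigengene")
    colnames(egs) <- paste0("M", labs)
    rownames(egs) <- rownames(abundances)
    out$eigengenes <- egs
    out$variance_explained <- stats::setNames(
      vapply(egl, `[[`, numeric(1), "variance_explained"), paste0("M", labs))
  }
  out
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- sum(unique(x$assignment) > 0)
  cat("Module set:", n_mod, "retained module(s);",
      sum(x$assignment > 0), "of", length(x$assignment), "ASVs assigned\n")
  if (!is.null(x$variance_explained)) {
    cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
    cat("  variance explained:",
        paste(round(x$variance_explained, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' End-to-end co-occurrence module construction
#'
#' Convenience wrapper: prevalence filter (network threshold) -> CLR ->
#' correlation -> soft threshold -> TOM -> average-linkage clustering with
#' quantile cut -> eigengene merging.  Operates on the unrarefied table.
#'
#' @param table [asv_table()] of unrarefied counts.
#' @param min_prevalence network prevalence filter (default 0.10).
#' @param beta soft-thresholding power (default 6); set to `"auto"` to use
#'   [pick_soft_threshold()].
#' @param r_threshold eigengene merge threshold (default 0.5).
#' @param min_size minimum module size (default 3).
#' @param cut_height static dendrogram cut height (default 0.99).
#' @param method correlation method, see [correlation_matrix()].
#' @return a `module_set` (see [merge_modules()]) with an extra `params`
#'   element recording the choices.
#' @export
cooccurrence_modules <- function(table, min_prevalence = 0.10, beta = 6,
                                 r_threshold = 0.5, min_size = 3,
                                 cut_height = 0.99,
                                 method = "pearson") {
  tab <- prevalence_filter(table, min_prevalence)
  clr <- clr_transform(tab)
  keep <- apply(clr, 2, stats::sd) > 0
  clr <- clr[, keep, drop = FALSE]
  corr <- correlation_matrix(clr, method = method)
  if (identical(beta, "auto")) beta <- pick_soft_threshold(corr)
  adj <- soft_threshold(corr, beta)
  tm <- tom(adj)
  ms <- detect_modules(tm, min_size = min_size, cut_height = cut_height)
  if (!any(ms$assignment > 0)) {
    ms$params <- list(beta = beta, r_threshold = r_threshold,
                      min_size = min_size, cut_height = cut_height)
    return(ms)
  }
  out <- merge_modules(ms, clr, r_threshold = r_threshold, min_size = min_size)
  out$params <- list(beta = beta, r_threshold = r_threshold,
                     min_size = min_size, cut_height = cut_height)
  out
}
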