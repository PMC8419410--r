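#' Bias-corrected Chao1 richness
#'
#' \eqn{S_{obs} + F_1(F_1-1) / (2(F_2+1))} where \eqn{F_1} and \eqn{F_2}
#' are the numbers of singleton and doubleton ASVs.
#'
#' @param counts non-negative integer vector of per-ASV counts.
#' @return richness estimate (>= observed richness); `NA` with a warning
#'   for an all-zero sample.
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("counts must be non-negative integers")
  s_obs <- sum(counts > 0)
  if (s_obs == 0) { warning("all-zero sample: Chao1 undefined"); return(NA_real_) }
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Pielou evenness
#'
#' Shannon entropy (natural log) divided by log observed richness; lies in
#' \[0, 1\].  Undefined (NA, with a warning) for samples with a single
#' taxon or no reads.
#'
#' @param counts non-negative numeric vector.
#' @return evenness in \[0, 1\] or `NA`.
#' @export
pielou <- function(counts) {
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  pos <- counts[counts > 0]
  if (!length(pos)) { warning("all-zero sample: evenness undefined"); return(NA_real_) }
  if (length(pos) == 1L) { warning("single taxon: evenness undefined"); return(NA_real_) }
  p <- pos / sum(pos)
  -sum(p * log(p)) / log(length(pos))
}

# per-edge descendant profile: value[edge, sample] = sum over descendant
# tips of the per-sample value (counts, proportions or presence)
edge_profile <- function(tree, mat) {
  # mat: samples x tips (named); returns n_edge x n_samples
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  vals <- matrix(0, n_node, nrow(mat))
  miss <- setdiff(colnames(mat), tr$tip.label)
  if (length(miss))
    stop_invalid("taxa missing from tree: ", paste(utils::head(miss, 5), collapse = ", "))
  vals[match(colnames(mat), tr$tip.label), ] <- t(mat)
  E <- matrix(0, nrow(tr$edge), nrow(mat))
  for (e in seq_len(nrow(tr$edge))) {     # postorder: children before parents
    child <- tr$edge[e, 2]
    E[e, ] <- vals[child, ]
    vals[tr$edge[e, 1], ] <- vals[tr$edge[e, 1], ] + vals[child, ]
  }
  list(E = E, lengths = tr$edge.length, tree = tr)
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths spanned by the union of root-to-tip paths of the
#' present taxa.  With `include_root_path = FALSE` the path from the root
#' down to the most recent common ancestor of the present set is excluded.
#'
#' @param presence named logical/0-1 vector over ASVs, or a character
#'   vector of present ASV ids.
#' @param tree rooted `phylo` with branch lengths; tips = ASV ids.
#' @param include_root_path include the MRCA-to-root path (default TRUE,
#'   matching common implementations).
#' @return total branch length.
#' @export
faith_pd <- function(presence, tree, include_root_path = TRUE) {
  if (is.character(presence)) {
    ids <- presence
  } else {
    if (is.null(names(presence))) stop_invalid("presence vector must be named")
    ids <- names(presence)[presence > 0]
  }
  if (!length(ids)) stop_invalid("at least one taxon must be present")
  miss <- setdiff(ids, tree$tip.label)
  if (length(miss))
    stop_invalid("taxa missing from tree: ", paste(miss, collapse = ", "))
  m <- matrix(1, 1, length(ids), dimnames = list("s", ids))
  ep <- edge_profile(tree, m)
  on_path <- ep$E[, 1] > 0
  pd <- sum(ep$lengths[on_path])
  if (!include_root_path && length(ids) >= 1) {
    # subtract edges from the root down to the MRCA of the present set:
    # those are the edges whose descendant set contains ALL present tips
    full <- ep$E[, 1] == length(ids)
    # the MRCA's own subtree retains internal edges; edges above the MRCA
    # have the complete set below them
    pd <- pd - sum(ep$lengths[full & on_path])
    if (length(ids) == 1) pd <- 0
  }
  pd
}

#' UniFrac distance between two samples
#'
#' Unweighted UniFrac is the fraction of branch length unique to one
#' sample's taxon set out of the branch length in either set.  Weighted
#' UniFrac is \eqn{\sum_i b_i |p_{Ai} - p_{Bi}|} over branches, with
#' \eqn{p} the proportion of a sample's reads descending from branch
#' \eqn{i}; when `normalized`, divided by \eqn{\sum_i b_i (p_{Ai}+p_{Bi})}
#' so the result lies in \[0, 1\].
#'
#' @param sample_a,sample_b named count vectors over the same ASV ids.
#' @param tree rooted `phylo`, tips covering the ASV ids.
#' @param weighted logical.
#' @param normalized normalize weighted UniFrac (default TRUE).
#' @return distance.
#' @export
unifrac <- function(sample_a, sample_b, tree, weighted = FALSE,
                    normalized = TRUE) {
  m <- rbind(a = sample_a, b = sample_b)
  if (all(rowSums(m) == 0)) stop_invalid("both samples are empty")
  d <- unifrac_matrix(m, tree, weighted = weighted, normalized = normalized)
  d[1, 2]
}

#' Pairwise UniFrac distance matrix
#'
#' @param table samples-by-ASVs count matrix or [asv_table()].
#' @param tree rooted `phylo`.
#' @param weighted,normalized see [unifrac()].
#' @return symmetric distance matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
unifrac_matrix <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  counts <- counts_of(table)
  n <- nrow(counts)
  if (weighted) {
    tot <- rowSums(counts)
    prop <- counts / ifelse(tot == 0, 1, tot)
    ep <- edge_profile(tree, prop)
  } else {
    ep <- edge_profile(tree, (counts > 0) * 1)
  }
  E <- ep$E
  b <- ep$lengths
  D <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (weighted) {
      num <- sum(b * abs(E[, i] - E[, j]))
      D[i, j] <- D[j, i] <- if (normalized) {
        den <- sum(b * (E[, i] + E[, j]))
        if (den == 0) NA_real_ else num / den
      } else num
    } else {
      pa <- E[, i] > 0; pb <- E[, j] > 0
      either <- sum(b[pa | pb])
      D[i, j] <- D[j, i] <- if (either == 0) NA_real_ else
        sum(b[xor(pa, pb)]) / either
    }
  }
  D
}

#' Per-sample alpha-diversity table
#'
#' Chao1, Faith's phylogenetic diversity and Pielou evenness for every
#' sample of a (normally rarefied) count table.
#'
#' @param table [asv_table()] or count matrix.
#' @param tree rooted `phylo` covering the table's ASVs.
#' @return data.frame with columns `sample`, `chao1`, `faith_pd`,
#'   `pielou`.
#' @export
alpha_diversity <- function(table, tree) {
  counts <- counts_of(table)
  data.frame(
    sample = rownames(counts),
    chao1 = apply(counts, 1, chao1),
    faith_pd = apply(counts, 1, function(x) {
      pres <- x > 0
      names(pres) <- colnames(counts)
      faith_pd(pres, tree)
    }),
    pielou = apply(counts, 1, pielou),
    row.names = NULL
  )
}

#' Covariate-adjusted PERMANOVA for a binary outcome
#'
#' Permutational multivariate analysis of variance on a distance matrix,
#' with sequential (order-of-entry) sums of squares: covariates are
#' entered first and the binary outcome last, so the outcome term is
#' adjusted for the covariates.  The pseudo-F for the outcome is compared
#' with its distribution under free permutation of the outcome labels;
#' `p = (1 + #\{F* >= F\}) / (1 + n_perm)`.
#'
#' @param D symmetric distance matrix (sample ids as dimnames).
#' @param covariates data.frame of adjustment covariates (rows aligned
#'   with `D`), or NULL.
#' @param outcome binary vector (two distinct values), aligned with `D`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return object of class `permanova_result`: data.frame of terms with
#'   `df`, `ss`, `r2`, `f`, `p` (p only for the outcome term), plus
#'   attributes `n_perm` and `seed`.
#' @export
permanova <- function(D, covariates = NULL, outcome, n_perm = 999, seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop_invalid("distance matrix must be symmetric")
  if (length(outcome) != n) stop_invalid("outcome length must match D")
  if (length(unique(outcome)) != 2)
    stop_invalid("outcome must be binary and non-constant")
  y <- as.numeric(factor(outcome)) - 1

  # Gower-centered inner-product matrix
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ss_tot <- sum(diag(G))

  Xcov <- if (is.null(covariates) || !length(covariates)) NULL else
    stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  one <- matrix(1, n, 1)
  hat <- function(X) { q <- qr(X); Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]; tcrossprod(Q) }

  H0 <- hat(one)
  terms <- list(); ss <- c(); dfs <- c()
  Xacc <- one
  if (!is.null(Xcov)) {
    for (k in seq_len(ncol(Xcov))) {
      Xnew <- cbind(Xacc, Xcov[, k])
      Hnew <- hat(Xnew); Hold <- hat(Xacc)
      ss <- c(ss, sum(diag((Hnew - Hold) %*% G)))
      dfs <- c(dfs, qr(Xnew)$rank - qr(Xacc)$rank)
      terms <- c(terms, colnames(Xcov)[k])
      Xacc <- Xnew
    }
  }
  H_cov <- hat(Xacc)
  ss_stat <- function(yv) {
    Hf <- hat(cbind(Xacc, yv))
    ss_out <- sum(diag((Hf - H_cov) %*% G))
    ss_res <- ss_tot - sum(diag(Hf %*% G))
    c(ss_out, ss_res)
  }
  obs <- ss_stat(y)
  df_out <- 1
  df_res <- n - qr(cbind(Xacc, y))$rank
  f_obs <- (obs[1] / df_out) / (obs[2] / df_res)

  set.seed(as.integer(seed))
  f_perm <- replicate(n_perm, {
    s <- ss_stat(y[sample.int(n)])
    (s[1] / df_out) / (s[2] / df_res)
  })
  pval <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)

  out <- data.frame(
    term = c(unlist(terms), "outcome", "residual", "total"),
    df = c(dfs, df_out, df_res, n - 1),
    ss = c(ss, obs[1], obs[2], ss_tot),
    r2 = c(ss, obs[1], obs[2], ss_tot) / ss_tot,
    f = c(rep(NA_real_, length(ss)), f_obs, NA, NA),
    p = c(rep(NA_real_, length(ss)), pval, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("permanova_result", "data.frame"),
            n_perm = n_perm, seed = seed)
}
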