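test_that("clr transform centers every sample at zero", {
  expect_equal(unname(clr_transform(rbind(s = c(A = 1, B = 1, C = 1, D = 1)))[1, ]),
               rep(0, 4))
  v <- clr_transform(rbind(s = c(A = 10, B = 1)), pseudocount = 1)
  expect_equal(unname(v[1, ]), c(0.5, -0.5) * log(11 / 2), tolerance = 1e-12)
  tab <- toy_table(8, 5, seed = 2)
  expect_true(all(abs(rowSums(clr_transform(tab))) < 1e-10))
})

test_that("correlation matrix matches the direct Pearson formula", {
  set.seed(4)
  x <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("A", 1:4)))
  r <- correlation_matrix(x)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    a <- x[, i] - mean(x[, i]); b <- x[, j] - mean(x[, j])
    oracle[i, j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  expect_equal(unname(r), oracle, tolerance = 1e-12)
  # duplicated / negated columns hit the bounds
  x2 <- cbind(x, A5 = x[, 1], A6 = -x[, 1])
  r2 <- correlation_matrix(x2)
  expect_equal(r2["A1", "A5"], 1)
  expect_equal(r2["A1", "A6"], -1)
  x3 <- cbind(x, A7 = 1)
  expect_error(correlation_matrix(x3), "zero-variance")
})

test_that("sparse selection masks weak edges but keeps strong ones", {
  skip_if_not_installed("glmnet")
  set.seed(23)
  n <- 60
  f <- rnorm(n)
  x <- cbind(a = f + rnorm(n, 0, 0.2), b = f + rnorm(n, 0, 0.2),
             c = rnorm(n), d = rnorm(n), e = rnorm(n))
  r <- correlation_matrix(x, method = "sparse_selection")
  expect_gt(abs(r["a", "b"]), 0.8)              # strong edge survives
  expect_equal(diag(r), rep(1, 5), ignore_attr = TRUE)
  expect_true(isSymmetric(unname(r) * (unname(r) != 0)))
  full <- correlation_matrix(x)
  expect_gte(sum(r == 0), sum(full == 0))       # masking only removes edges
})

test_that("soft threshold is |r|^beta with unit diagonal", {
  r <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(soft_threshold(r, 2)[1, 2], 0.25)
  expect_equal(soft_threshold(r, 1)[1, 2], 0.5)
  expect_equal(soft_threshold(matrix(c(1, 0.9, 0.9, 1), 2), 6)[1, 2],
               0.531441, tolerance = 1e-12)
  expect_equal(diag(soft_threshold(r, 3)), c(1, 1))
})

test_that("soft-threshold power selection prefers the smallest passing power", {
  set.seed(6)
  # heavy-tailed connectivity: block structure gives a passable fit
  x <- matrix(rnorm(300), 30, 10)
  x[, 2:4] <- x[, 1] + matrix(rnorm(90, 0, 0.3), 30, 3)
  r <- correlation_matrix(x)
  p <- pick_soft_threshold(r, powers = c(2, 4, 6, 8))
  expect_true(p %in% c(2, 4, 6, 8))
  # degenerate: all correlations equal -> fallback with warning
  r0 <- matrix(0.5, 4, 4); diag(r0) <- 1
  expect_warning(p0 <- pick_soft_threshold(r0, powers = c(2, 4)), "degenerate")
  expect_equal(p0, 6)
})

test_that("tom matches the brute-force triple loop and its boundary cases", {
  a1 <- matrix(1, 3, 3)
  expect_equal(unname(tom(a1)), matrix(1, 3, 3))
  a0 <- diag(4)
  expect_equal(unname(tom(a0)), diag(4))
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    a <- abs(matrix(rnorm(n^2), n)); a <- (a + t(a)) / 2
    a <- a / (max(a) + 0.1); diag(a) <- 1
    tm <- tom(a)
    brute <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) { brute[i, j] <- 1; next }
      s <- 0
      for (u in seq_len(n)[-c(i, j)]) s <- s + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      brute[i, j] <- (s + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
    expect_equal(unname(tm), brute, tolerance = 1e-12)
    expect_true(all(tm >= 0 & tm <= 1 + 1e-12))
    expect_equal(tm, t(tm))
  }
})

test_that("module detection separates perfect blocks and keeps constant-TOM together", {
  ids <- sprintf("A%02d", 1:9)
  tm <- matrix(0, 9, 9, dimnames = list(ids, ids))
  tm[1:4, 1:4] <- 1; tm[5:9, 5:9] <- 1
  ms <- detect_modules(tm)
  expect_equal(length(unique(ms$assignment[ms$assignment > 0])), 2)
  expect_equal(unname(ms$assignment[1:4]), rep(2L, 4))   # smaller block = M2
  expect_equal(unname(ms$assignment[5:9]), rep(1L, 4 + 1))

  # all pairwise TOM equal: one module containing everything
  ids10 <- sprintf("B%02d", 1:10)
  tmc <- matrix(0.5, 10, 10, dimnames = list(ids10, ids10)); diag(tmc) <- 1
  msc <- detect_modules(tmc, min_size = 3)
  expect_equal(unname(msc$assignment), rep(1L, 10))

  # clusters below min_size stay unassigned
  tm2 <- diag(5); dimnames(tm2) <- list(sprintf("C%d", 1:5), sprintf("C%d", 1:5))
  ms2 <- detect_modules(tm2, min_size = 3)
  expect_true(all(ms2$assignment == 0))
})

test_that("eigengene has the documented rank-1, isotropic and oracle behavior", {
  set.seed(14)
  base <- rnorm(20)
  # two identical standardized columns: eigengene is that column, VE = 1
  m1 <- cbind(a = base, b = base)
  rownames(m1) <- paste0("s", 1:20)
  e1 <- eigengene(m1)
  expect_equal(e1$variance_explained, 1.0, tolerance = 1e-12)
  expect_equal(abs(cor(e1$eigengene, base)), 1, tolerance = 1e-12)
  expect_equal(sd(e1$eigengene), 1, tolerance = 1e-12)
  expect_gt(cor(e1$eigengene, base), 0)   # sign oriented with members

  # exactly orthogonal, mean-zero, equal-variance columns: VE = 1/m
  m2 <- qr.Q(qr(scale(matrix(rnorm(20 * 3), 20), scale = FALSE)))
  rownames(m2) <- paste0("s", 1:20); colnames(m2) <- c("a", "b", "c")
  e2 <- eigengene(m2)
  expect_equal(e2$variance_explained, 1 / 3, tolerance = 1e-10)

  # eigendecomposition oracle on a random module
  m3 <- matrix(rnorm(20 * 4), 20, dimnames = list(paste0("s", 1:20), paste0("x", 1:4)))
  e3 <- eigengene(m3)
  z <- scale(m3)
  ev <- eigen(cov(z))
  proj <- drop(z %*% ev$vectors[, 1]); proj <- proj / sd(proj)
  expect_equal(abs(cor(e3$eigengene, proj)), 1, tolerance = 1e-10)
  expect_equal(e3$variance_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-10)
  # no member column explains more standardized variance than the eigengene
  expect_gte(e3$variance_explained,
             max(apply(z, 2, function(col) mean(cor(col, z)^2))) - 1e-10)
})

test_that("module merging is driven by eigengene correlation and converges", {
  set.seed(17)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f, k, noise) sapply(1:k, function(i) f + rnorm(n, 0, noise))
  # two modules generated from one latent factor: merged
  ab <- cbind(mk(f1, 3, 0.2), mk(f1, 3, 0.2), mk(f2, 3, 0.2))
  colnames(ab) <- sprintf("A%02d", 1:9)
  rownames(ab) <- paste0("s", 1:n)
  cl <- structure(list(assignment = setNames(c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
                                             colnames(ab)),
                       eigengenes = NULL, variance_explained = NULL,
                       sizes = c(3L, 3L, 3L)), class = "module_set")
  out <- merge_modules(cl, ab, r_threshold = 0.5)
  labs <- out$assignment
  expect_equal(length(unique(labs[labs > 0])), 2)
  expect_equal(length(unique(labs[1:6])), 1)      # factor-1 modules merged
  # post-merge invariant
  expect_lt(max(cor(out$eigengenes)[upper.tri(diag(2))]), 0.5)

  # independent factors stay apart
  cl2 <- cl
  ab2 <- cbind(mk(f1, 3, 0.2), mk(f2, 3, 0.2), mk(rnorm(n), 3, 0.2))
  dimnames(ab2) <- dimnames(ab)
  out2 <- merge_modules(cl2, ab2, r_threshold = 0.5)
  expect_equal(length(unique(out2$assignment[out2$assignment > 0])), 3)

  # three mutually correlated modules collapse to one
  ab3 <- cbind(mk(f1, 3, 0.1), mk(f1, 3, 0.1), mk(f1, 3, 0.1))
  dimnames(ab3) <- dimnames(ab)
  out3 <- merge_modules(cl, ab3, r_threshold = 0.5)
  expect_equal(length(unique(out3$assignment[out3$assignment > 0])), 1)
})

test_that("planted blocks are recovered from compositional counts", {
  aris <- vapply(1:5, function(s) {
    cfg <- sim_config(n_subjects = 100, n_asvs = 40,
                      module_spec = list(c(8, 0.7), c(6, 0.7), c(5, 0.7)),
                      sequencing_depth_mean = 20000, depth_min = 15000,
                      seed = s)
    sim <- simulate_counts(cfg)
    ms <- cooccurrence_modules(sim$table, min_prevalence = 0.1)
    truth <- sim$truth$modules[names(ms$assignment)]
    ari(ms$assignment, truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})
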