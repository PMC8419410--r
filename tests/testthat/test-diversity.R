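test_that("chao1 matches hand values and never drops below observed richness", {
  expect_equal(chao1(c(5, 3, 2)), 3.0)
  expect_equal(chao1(c(1, 1, 2, 3)), 4.5)      # 4 + 2*1/(2*2)
  expect_equal(chao1(c(1)), 1.0)
  expect_warning(expect_true(is.na(chao1(c(0, 0)))))
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(30, 1)
    if (!any(x > 0)) next
    expect_gte(chao1(x), sum(x > 0))
  }
})

test_that("pielou matches hand values and lies in [0, 1]", {
  expect_equal(pielou(c(10, 10, 10, 10)), 1.0)
  expect_equal(pielou(c(3, 1)), 0.8113, tolerance = 1e-4)
  expect_warning(expect_true(is.na(pielou(c(4)))))
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(20, 3) + c(1, rep(0, 19))
    if (sum(x > 0) < 2) next
    e <- pielou(x)
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("faith_pd handles star trees and matches an edge-union oracle", {
  star <- ape::stree(3, "star")
  star$edge.length <- rep(1, 3)
  star$tip.label <- c("A", "B", "C")
  expect_equal(faith_pd(c("A", "B"), star), 2.0)
  expect_equal(faith_pd(c("A", "B", "C"), star), sum(star$edge.length))

  skip_if_not_installed("picante")
  set.seed(12)
  tr <- simulate_tree(12, 8)
  for (i in 1:10) {
    pres <- rbinom(12, 1, 0.5)
    names(pres) <- tr$tip.label
    if (!any(pres > 0)) next
    comm <- matrix(pres, 1, dimnames = list("s", tr$tip.label))
    expect_equal(faith_pd(pres, tr),
                 picante::pd(comm, tr, include.root = TRUE)$PD,
                 tolerance = 1e-10)
  }
  expect_error(faith_pd(c("NOPE"), tr), "missing from tree")
})

test_that("unifrac matches brute-force per-branch oracles", {
  set.seed(5)
  tr <- simulate_tree(10, 4)
  cnt <- matrix(rpois(3 * 10, 2), 3, 10,
                dimnames = list(c("a", "b", "c"), tr$tip.label))
  cnt[rowSums(cnt) == 0, 1] <- 1L

  # independent edge-walk oracle over explicit descendant tip sets
  tre <- stats::reorder(tr, "postorder")
  nt <- length(tre$tip.label)
  sets <- c(as.list(seq_len(nt)), rep(list(integer(0)), tre$Nnode))
  for (e in seq_len(nrow(tre$edge)))
    sets[[tre$edge[e, 1]]] <- c(sets[[tre$edge[e, 1]]], sets[[tre$edge[e, 2]]])
  edge_sets <- lapply(seq_len(nrow(tre$edge)),
                      function(e) tre$tip.label[unique(sets[[tre$edge[e, 2]]])])
  oracle <- function(x, y, weighted) {
    px <- x / sum(x); py <- y / sum(y)
    num <- den <- 0
    for (e in seq_along(edge_sets)) {
      bl <- tre$edge.length[e]
      qa <- sum(px[edge_sets[[e]]]); qb <- sum(py[edge_sets[[e]]])
      if (weighted) {
        num <- num + bl * abs(qa - qb); den <- den + bl * (qa + qb)
      } else {
        pa <- any(x[edge_sets[[e]]] > 0); pb <- any(y[edge_sets[[e]]] > 0)
        num <- num + bl * xor(pa, pb); den <- den + bl * (pa || pb)
      }
    }
    num / den
  }
  Du <- unifrac_matrix(cnt, tr, weighted = FALSE)
  Dw <- unifrac_matrix(cnt, tr, weighted = TRUE)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(Du[i, j], oracle(cnt[i, ], cnt[j, ], FALSE), tolerance = 1e-12)
    expect_equal(Dw[i, j], oracle(cnt[i, ], cnt[j, ], TRUE), tolerance = 1e-12)
  }
  expect_equal(unname(diag(Du)), rep(0, 3))
  expect_equal(Du, t(Du))

  # identical samples are at distance zero in all modes
  same <- rbind(s1 = cnt[1, ], s2 = cnt[1, ])
  expect_equal(unifrac(cnt[1, ], cnt[1, ], tr, weighted = TRUE), 0)
  expect_equal(unifrac(cnt[1, ], cnt[1, ], tr, weighted = FALSE), 0)

  # disjoint tips on a star tree are maximally distant
  star <- ape::stree(3, "star"); star$edge.length <- rep(1, 3)
  star$tip.label <- c("t1", "t2", "t3")
  a <- c(t1 = 5, t2 = 0, t3 = 0); b <- c(t1 = 0, t2 = 5, t3 = 0)
  expect_equal(unifrac(a, b, star, weighted = FALSE), 1.0)
})

test_that("unweighted unifrac satisfies the triangle inequality on random instances", {
  set.seed(19)
  for (s in 1:5) {
    tr <- simulate_tree(8, s + 100)
    cnt <- matrix(rbinom(5 * 8, 4, 0.4), 5, 8,
                  dimnames = list(paste0("s", 1:5), tr$tip.label))
    cnt[rowSums(cnt) == 0, 1] <- 1L
    D <- unifrac_matrix(cnt, tr, weighted = FALSE)
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("permanova recovers the between-group SS fraction of a Euclidean embedding", {
  x <- c(0, 0, 1, 1)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- c(0, 0, 1, 1)
  pm <- permanova(D, NULL, g, n_perm = 99, seed = 1)
  ss_tot <- sum((x - mean(x))^2)
  ss_between <- sum(tapply(x, g, length) * (tapply(x, g, mean) - mean(x))^2)
  expect_equal(pm$r2[pm$term == "outcome"], ss_between / ss_tot,
               tolerance = 1e-10)
  expect_equal(sum(pm$r2[pm$term != "total"]), 1, tolerance = 1e-10)
})

test_that("permanova matches adonis2 term-wise on a covariate-adjusted model", {
  skip_if_not_installed("vegan")
  set.seed(8)
  n <- 18
  coords <- matrix(rnorm(n * 3), n)
  D <- as.matrix(dist(coords))
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  cov <- data.frame(age = rnorm(n), sexf = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.5)
  pm <- permanova(D, cov, y, n_perm = 49, seed = 2)
  ad <- vegan::adonis2(as.dist(D) ~ age + sexf + y,
                       data = cbind(cov, y = y), by = "terms",
                       permutations = 49)
  expect_equal(pm$ss[1:4], ad$SumOfSqs[1:4], tolerance = 1e-8)
  expect_equal(pm$f[pm$term == "outcome"], ad$F[3], tolerance = 1e-8)
})

test_that("permanova rejects degenerate outcomes and is permutation-equivariant", {
  set.seed(61)
  D <- as.matrix(dist(rnorm(6)))
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  expect_error(permanova(D, NULL, rep(1, 6), n_perm = 9), "binary")
  y <- c(0, 0, 0, 1, 1, 1)
  pm1 <- permanova(D, NULL, y, n_perm = 49, seed = 3)
  perm <- c(4, 5, 6, 1, 2, 3)
  pm2 <- permanova(D[perm, perm], NULL, y[perm], n_perm = 49, seed = 3)
  expect_equal(pm1$f[pm1$term == "outcome"], pm2$f[pm2$term == "outcome"],
               tolerance = 1e-10)
  expect_equal(pm1$r2, pm2$r2, tolerance = 1e-10)
})
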