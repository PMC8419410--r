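# brute-force oracles shared by the acceptance checks

tom_brute <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { out[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)[-c(i, j)]) s <- s + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (s + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# explicit edge-walk UniFrac over enumerated descendant tip sets
unifrac_brute <- function(x, y, tree, weighted) {
  tre <- stats::reorder(tree, "postorder")
  nt <- length(tre$tip.label)
  sets <- c(as.list(seq_len(nt)), rep(list(integer(0)), tre$Nnode))
  for (e in seq_len(nrow(tre$edge)))
    sets[[tre$edge[e, 1]]] <- c(sets[[tre$edge[e, 1]]], sets[[tre$edge[e, 2]]])
  px <- x / sum(x); py <- y / sum(y)
  num <- den <- 0
  for (e in seq_len(nrow(tre$edge))) {
    tips <- tre$tip.label[sets[[tre$edge[e, 2]]]]
    bl <- tre$edge.length[e]
    if (weighted) {
      qa <- sum(px[tips]); qb <- sum(py[tips])
      num <- num + bl * abs(qa - qb); den <- den + bl * (qa + qb)
    } else {
      pa <- any(x[tips] > 0); pb <- any(y[tips] > 0)
      num <- num + bl * xor(pa, pb); den <- den + bl * (pa || pb)
    }
  }
  num / den
}
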