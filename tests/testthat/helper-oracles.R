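# Independent oracles used across the suite.  These deliberately
# reimplement the rules by brute force and must stay independent of the
# package's code paths.

# BH step-up computed literally from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# C3NET by exhaustive rule application: permutation p-values, BH,
# then every node's maximum-MI significant partner, union of edges.
c3net_oracle <- function(mi, null_mi, alpha = 0.05) {
  p <- nrow(mi)
  nodes <- rownames(mi)
  pv <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    pv[i, j] <- (sum(null_mi >= mi[i, j]) + 1) / (length(null_mi) + 1)
  ut <- which(upper.tri(mi), arr.ind = TRUE)
  qv <- bh_oracle(pv[ut])
  sig <- matrix(FALSE, p, p)
  sig[ut] <- qv < alpha
  sig <- sig | t(sig)
  keys <- character(0)
  for (i in seq_len(p)) {
    cand <- which(sig[i, ])
    if (length(cand) == 0) next
    best <- cand[which.max(mi[i, cand])]
    keys <- c(keys, paste(nodes[min(i, best)], nodes[max(i, best)]))
  }
  sort(unique(keys))
}

# minimum spanning-tree weight by enumeration over all spanning trees
# (connected graphs only, n <= 6)
mst_weight_oracle <- function(u, v, d, nodes) {
  ne <- length(u)
  n <- length(nodes)
  best <- Inf
  for (sel in utils::combn(ne, n - 1, simplify = FALSE)) {
    # spanning + acyclic check via union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in sel) {
      ru <- find(match(u[e], nodes)); rv <- find(match(v[e], nodes))
      if (ru == rv) { ok <- FALSE; break }
      parent[ru] <- rv
    }
    if (ok) best <- min(best, sum(d[sel]))
  }
  best
}

# fraction of within-module pairs present in an edge list
module_pair_recovery <- function(edges, members) {
  if (length(members) < 2) return(NA_real_)
  pr <- utils::combn(sort(members), 2)
  hit <- vapply(seq_len(ncol(pr)), function(k) {
    any((edges$u == pr[1, k] & edges$v == pr[2, k]) |
        (edges$u == pr[2, k] & edges$v == pr[1, k]))
  }, logical(1))
  mean(hit)
}

# small hand-built spectral-count fixture
toy_spc <- function(counts, lengths, phenotype) {
  spectral_count_matrix(counts, lengths, phenotype)
}
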