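test_that("PT moment fit: degenerate, simulated and rescaled cases", {
  # zero variance -> Poisson limit
  f <- fit_pt_moments(c(5L, 5L, 5L, 5L))
  expect_equal(f$mu, 5)
  expect_equal(f$phi, 1)
  expect_equal(f$a, 1)
  # NB simulation: moment consistency and shape identification
  x <- sample_pt_counts(10, 4, 0, 1e4, seed = 5)
  fnb <- fit_pt_moments(x)
  expect_lt(abs(fnb$mu - 10) / 10, 0.02)
  expect_lt(abs(fnb$phi - 4) / 4, 0.10)
  expect_equal(fnb$a, 0)
  # PIG simulation is recognized as PIG
  y <- sample_pt_counts(10, 6, 0.5, 1e4, seed = 6)
  expect_equal(fit_pt_moments(y)$a, 0.5)
  # rescaling counts and factors together leaves phi and a unchanged
  fac <- rep(2, length(x))
  f2 <- fit_pt_moments(as.integer(2 * x), norm_factors = fac)
  expect_equal(f2$mu, fnb$mu)
  expect_equal(f2$phi, fnb$phi)
  expect_equal(f2$a, fnb$a)
  # all-zero group is flagged, not fitted
  fz <- fit_pt_moments(c(0L, 0L, 0L))
  expect_false(fz$fitted)
  expect_error(fit_pt_moments(3L), "at least 2")
})

test_that("two-sample PT test: symmetry, degenerate inputs, zeros", {
  a <- c(12L, 15L, 9L, 14L)
  b <- c(30L, 25L, 40L, 33L)
  t1 <- pt_two_sample_test(a, b)
  t2 <- pt_two_sample_test(b, a)
  expect_equal(t1$z, -t2$z)
  expect_equal(t1$p, t2$p)
  # identical groups
  expect_equal(pt_two_sample_test(a, a), list(z = 0, p = 1))
  # both all-zero
  z4 <- rep(0L, 4)
  expect_equal(pt_two_sample_test(z4, z4), list(z = 0, p = 1))
  # one group all-zero still yields a finite test
  t3 <- pt_two_sample_test(z4, b)
  expect_true(is.finite(t3$z) && t3$p < 0.05)
  expect_error(pt_two_sample_test(1L, a), "at least 2")
})

test_that("BH adjustment equals the hand-evaluated step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  # random vectors against the literal step-up oracle; permutation
  # invariance; q >= p
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-12))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("pairwise DA emits all six comparisons with coherent flags", {
  sim <- generate_metaproteome(synthetic_config(n_taxa = 30, seed = 17))
  tc <- filter_low_counts(aggregate_to_taxa(sim$counts, sim$taxonomy))
  nm <- tmm_normalize(tc)
  da <- run_pairwise_da(tc, nm)
  expect_length(da$comparisons, 6)
  expect_equal(nrow(da$table), 6 * nrow(tc$counts))
  expect_true(all(da$table$q >= da$table$p - 1e-12))
  expect_identical(da$table$significant, da$table$q < 0.05)
  expect_setequal(da$union_da,
                  unique(da$table$taxon[da$table$significant]))
  # within each comparison q is monotone in p
  for (cmp in da$comparisons) {
    sub <- da$table[da$table$comparison == cmp, ]
    o <- order(sub$p)
    expect_true(all(diff(sub$q[o]) >= -1e-12))
  }
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  bg <- paste0("t", 1:100)
  da <- paste0("t", 1:10)
  amap <- data.frame(
    id = c(paste0("t", 1:5), paste0("t", 11:15),   # termA: 5/10 in DA
           bg),                                     # termB: everything
    term = c(rep("termA", 10), rep("termB", 100)),
    stringsAsFactors = FALSE)
  res <- fisher_enrichment(da, bg, amap)
  # oracle: upper hypergeometric tail, k >= 5 of K = 10, n = 10, N = 100
  oracle <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(res$p[res$term == "termA"], oracle)
  expect_equal(res$p[res$term == "termB"], 1)
  expect_true(res$enriched[res$term == "termA"])
  expect_false(res$enriched[res$term == "termB"])
  # cross-check against fisher.test's one-sided p
  ft <- fisher.test(matrix(c(5, 5, 5, 85), 2,
                           dimnames = list(c("da", "not"),
                                           c("in", "out"))),
                    alternative = "greater")
  expect_equal(res$p[res$term == "termA"], ft$p.value)
  # empty DA set -> nothing enriched
  res0 <- fisher_enrichment(character(0), bg, amap)
  expect_false(any(res0$enriched))
  # term with no background members is skipped with a warning
  amap2 <- rbind(amap, data.frame(id = "zzz", term = "ghost"))
  expect_warning(r2 <- fisher_enrichment(da, bg, amap2), "ghost")
  expect_false("ghost" %in% r2$term)
  expect_error(fisher_enrichment("nope", bg, amap), "subset")
})

test_that("hub t-tests match the closed-form Welch statistic", {
  m <- rbind(hub1 = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
             hub2 = c(4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L))
  colnames(m) <- paste0("s", 1:8)
  tc <- taxon_count_matrix(m, rep("species", 2),
                           rep(c("A", "B"), each = 4))
  tt <- hub_ttest(tc, c("hub1", "hub2"))
  # closed-form Welch for [1,2,3,4] vs [5,6,7,8]
  va <- var(1:4); vb <- var(5:8)
  se <- sqrt(va / 4 + vb / 4)
  tstat <- (mean(1:4) - mean(5:8)) / se
  df <- (va / 4 + vb / 4)^2 /
    ((va / 4)^2 / 3 + (vb / 4)^2 / 3)
  p_oracle <- 2 * pt(-abs(tstat), df)
  r1 <- tt[tt$taxon == "hub1" & tt$comparison == "A_vs_B", ]
  expect_equal(r1$t, tstat)
  expect_equal(r1$p, p_oracle)
  # identical group vectors -> p = 1
  r2 <- tt[tt$taxon == "hub2", ]
  expect_equal(r2$p, 1)
  # label exchange preserves p
  tc_sw <- taxon_count_matrix(m, rep("species", 2),
                              rep(c("B", "A"), each = 4))
  tt_sw <- hub_ttest(tc_sw, "hub1")
  expect_equal(tt_sw$p, r1$p)
  expect_error(hub_ttest(tc, "absent"), "absent")
})

test_that("hierarchical clustering recovers planted separation and is
           order-invariant", {
  set.seed(14)
  # duplicated sample merges at height 0
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
  m <- cbind(m, s5 = m[, 4])
  hc <- hierarchical_cluster(m, "columns", scale_rows = FALSE)
  expect_equal(min(hc$hclust$height), 0)
  # strong 2-group separation: k = 2 recovers the partition, every seed
  for (seed in 1:5) {
    set.seed(seed)
    g1 <- matrix(rnorm(20 * 6, 0), 20, 6)
    g2 <- matrix(rnorm(20 * 6, 8), 20, 6)
    x <- cbind(g1, g2)
    colnames(x) <- paste0("s", 1:12)
    rownames(x) <- paste0("f", 1:20)
    cl <- hierarchical_cluster(x, "columns", k = 2)
    expect_equal(length(unique(cl$labels[1:6])), 1)
    expect_equal(length(unique(cl$labels[7:12])), 1)
    expect_false(cl$labels[1] == cl$labels[7])
    # column-permutation invariance of the partition
    perm <- sample(12)
    cl2 <- hierarchical_cluster(x[, perm], "columns", k = 2)
    l2 <- cl2$labels[names(cl$labels)]
    expect_equal(outer(cl$labels, cl$labels, "=="),
                 outer(l2, l2, "=="))
  }
  # constant row dropped with warning
  xc <- rbind(x, const = rep(1, 12))
  expect_warning(hc3 <- hierarchical_cluster(xc, "columns"), "const")
  expect_equal(hc3$dropped, "const")
})

test_that("the PT test holds its nominal size at small n", {
  set.seed(271828)
  p_nb <- replicate(2000, {
    a <- sample_pt_counts(20, 3, 0, 4)
    b <- sample_pt_counts(20, 3, 0, 4)
    pt_two_sample_test(a, b)$p
  })
  t1 <- mean(p_nb < 0.05)
  expect_gte(t1, 0.03)
  expect_lte(t1, 0.08)
  # Poisson null: conservative (the variance floor at the mean biases
  # the denominator upward when var < mean), never anticonservative
  p_po <- replicate(2000, {
    a <- sample_pt_counts(20, 1, 1, 4)
    b <- sample_pt_counts(20, 1, 1, 4)
    pt_two_sample_test(a, b)$p
  })
  expect_lte(mean(p_po < 0.05), 0.08)
})
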