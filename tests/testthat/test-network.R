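test_that("MI estimator: self-information, null level, symmetry", {
  set.seed(2)
  x <- rnorm(1e4)
  # I(X;X) = H(X) = log2(bins) under equal-frequency occupancy
  expect_equal(estimate_mi(x, x, bins = 4), 2, tolerance = 0.01)
  expect_equal(estimate_mi(x, x, bins = 8), 3, tolerance = 0.01)
  # independent permutation: bias-corrected MI near zero in the dense
  # regime (n >> bins^2)
  y <- sample(x)
  expect_lte(estimate_mi(x, y, bins = 10), 0.02)
  # exact symmetry
  z <- rnorm(100)
  w <- z + rnorm(100)
  expect_identical(estimate_mi(z, w), estimate_mi(w, z))
  expect_true(estimate_mi(z, w) > estimate_mi(z, sample(w)))
  # constant input
  expect_warning(m0 <- estimate_mi(rep(1, 50), rnorm(50)), "constant")
  expect_equal(m0, 0)
})

test_that("MI matrix is symmetric, nonnegative, invariant to monotone
           transforms", {
  set.seed(3)
  d <- matrix(rnorm(6 * 30), 6, 30,
              dimnames = list(paste0("t", 1:6), NULL))
  mi <- mi_matrix(d)
  expect_equal(mi, t(mi))
  expect_true(all(mi >= 0))
  expect_equal(unname(diag(mi)), rep(0, 6))
  # equal-frequency binning sees only ranks
  expect_equal(mi_matrix(2^d), mi, ignore_attr = TRUE)
})

test_that("c3net reproduces the spec's 3-node worked example", {
  mi <- matrix(0, 3, 3, dimnames = list(c("n1", "n2", "n3"),
                                        c("n1", "n2", "n3")))
  mi["n1", "n2"] <- mi["n2", "n1"] <- 0.9
  mi["n1", "n3"] <- mi["n3", "n1"] <- 0.2
  mi["n2", "n3"] <- mi["n3", "n2"] <- 0.5
  # null chosen so 0.9 and 0.5 are significant and 0.2 is not
  null_mi <- runif(2000, 0.25, 0.45)
  ed <- c3net(mi, null_mi, alpha = 0.05)
  expect_equal(paste(ed$u, ed$v), c("n1 n2", "n2 n3"))
  # no significant pairs -> empty network
  expect_equal(nrow(c3net(mi, runif(2000, 1, 2))), 0)
})

test_that("c3net equals the brute-force rule on random instances and
           never exceeds one edge per node", {
  set.seed(20)
  for (i in 1:100) {
    p <- sample(3:5, 1)
    nodes <- paste0("n", seq_len(p))
    mi <- matrix(0, p, p, dimnames = list(nodes, nodes))
    vals <- runif(p * (p - 1) / 2, 0, 1)
    mi[upper.tri(mi)] <- vals
    mi <- mi + t(mi)
    null_mi <- runif(1000, 0, 0.8)
    ed <- c3net(mi, null_mi, alpha = 0.1)
    expect_lte(nrow(ed), p)
    got <- sort(paste(ed$u, ed$v))
    expect_equal(got, c3net_oracle(mi, null_mi, alpha = 0.1))
  }
})

test_that("bc3net: degenerate config equals c3net, seeded determinism,
           planted dependence recovered", {
  set.seed(7)
  n <- 16
  latent <- rnorm(n)
  d <- rbind(a = latent + 0.3 * rnorm(n),
             b = latent + 0.3 * rnorm(n),
             c = rnorm(n),
             e = rnorm(n))
  # B = 1 without bootstrap reduces to c3net on the original data up to
  # the ensemble significance test, so the surviving edges must be a
  # subset with identical support
  net1 <- bc3net(d, B = 1, bootstrap = FALSE, seed = 1)
  mi <- mi_matrix(d)
  set.seed(1)                       # same RNG stream as inside bc3net
  nullv <- mi_null(d, n_null = 1000)
  ed <- c3net(mi, nullv, alpha = 0.05)
  expect_true(all(paste(net1$edges$u, net1$edges$v) %in%
                    paste(ed$u, ed$v)))
  # determinism
  n2 <- bc3net(d, B = 25, seed = 9)
  n3 <- bc3net(d, B = 25, seed = 9)
  expect_identical(n2$edges, n3$edges)
  # handshake lemma
  expect_equal(sum(n2$degree), 2 * nrow(n2$edges))
  # strongly coupled pair recovered
  expect_true(any((n2$edges$u == "a" & n2$edges$v == "b")))
})

test_that("MST2: worked small cases and the spanning/weight oracle", {
  # input already a tree -> MST2 = input, second tree empty
  tree <- data.frame(u = c("a", "b"), v = c("b", "c"),
                     weight = c(0.9, 0.4))
  net <- as_coab_network(tree)
  m <- mst2_reduce(net)
  expect_true(all(m$edges$in_mst1))
  expect_true(all(m$edges$in_mst2))
  # triangle with distinct weights: MST1 = two highest-MI edges
  # (lightest distances), MST2 = all three
  tri <- data.frame(u = c("a", "a", "b"), v = c("b", "c", "c"),
                    weight = c(0.9, 0.5, 0.7))
  mt <- mst2_reduce(as_coab_network(tri))
  expect_setequal(paste(mt$edges$u, mt$edges$v)[mt$edges$in_mst1],
                  c("a b", "b c"))
  expect_true(all(mt$edges$in_mst2))
  # random graphs: MST1 distance-weight equals brute force over all
  # spanning trees; MST2 spans and respects the 2(n-1) bound
  set.seed(30)
  for (i in 1:100) {
    p <- sample(4:6, 1)
    nodes <- paste0("n", seq_len(p))
    full <- t(combn(nodes, 2))
    keep <- runif(nrow(full)) < 0.8
    if (sum(keep) < p - 1) next
    ed <- data.frame(u = full[keep, 1], v = full[keep, 2],
                     weight = round(runif(sum(keep)), 2))
    g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                       vertices = data.frame(
                                         name = nodes))
    if (igraph::components(g)$no > 1) next  # keep the oracle simple
    net <- as_coab_network(ed, nodes = nodes)
    m2 <- mst2_reduce(net)
    wmax <- max(ed$weight)
    dd <- wmax - ed$weight
    expect_equal(sum(dd[m2$edges$in_mst1]),
                 mst_weight_oracle(ed$u, ed$v, dd, nodes))
    expect_equal(sum(m2$edges$in_mst1), p - 1)
    expect_lte(sum(m2$edges$in_mst2), 2 * (p - 1))
    # MST2 connects every node of the component
    expect_equal(igraph::components(m2$graph)$no, 1)
    # igraph cross-check of MST1 minimality
    igraph::E(g)$d <- dd
    gm <- igraph::mst(g, weights = igraph::E(g)$d)
    expect_equal(sum(dd[m2$edges$in_mst1]), sum(igraph::E(gm)$d))
    # edge-subset property
    expect_true(all(igraph::degree(m2$graph) <= net$degree))
  }
})

test_that("network statistics follow their definitions", {
  # path a-b-c: betweenness (0, 1, 0), average 1/3
  path <- as_coab_network(data.frame(u = c("a", "b"), v = c("b", "c"),
                                     weight = c(1, 1)))
  s <- network_stats(path)
  expect_equal(unname(path$betweenness[c("a", "b", "c")]), c(0, 1, 0))
  expect_equal(s$avg_betweenness, 1 / 3)
  expect_equal(s$avg_degree, 2 * 2 / 3)
  expect_equal(s$n_isolated, 0)
  # isolated nodes counted against the giant component
  withiso <- as_coab_network(data.frame(u = "a", v = "b", weight = 1),
                             nodes = c("a", "b", "c", "d"))
  s2 <- network_stats(withiso)
  expect_equal(s2$giant_size, 2)
  expect_equal(s2$n_isolated, 2)
  expect_equal(s2$avg_degree, 1)
  # empty graph
  s0 <- network_stats(as_coab_network(
    data.frame(u = character(0), v = character(0),
               weight = numeric(0)), nodes = character(0)))
  expect_equal(s0$n_nodes, 0)
  expect_equal(s0$avg_degree, 0)
})

test_that("hub selection applies the strict interpolated-percentile
           rule", {
  # all degrees equal -> no hubs (strict inequality)
  ring <- data.frame(u = c("a", "b", "c"), v = c("b", "c", "a"),
                     weight = 1)
  expect_equal(nrow(select_hubs(as_coab_network(ring))$hubs), 0)
  # one node of degree 50 among 19 of degree 1: sole hub above the
  # interpolated threshold
  star <- data.frame(u = "hub", v = paste0("leaf", 1:50), weight = 1)
  extra <- data.frame(u = paste0("x", 1:9), v = paste0("y", 1:9),
                      weight = 1)
  net <- as_coab_network(rbind(star, extra))
  h <- select_hubs(net)
  deg <- net$degree
  thr_oracle <- unname(quantile(deg, 0.95, type = 7))
  expect_equal(h$threshold, thr_oracle)
  expect_setequal(h$hubs$taxon, names(deg)[deg > thr_oracle])
  expect_true("hub" %in% h$hubs$taxon)
  # hub set invariant under node relabeling
  relab <- rbind(star, extra)
  relab$u <- chartr("abcdefghijklmnopqrstuvwxyz",
                    "ABCDEFGHIJKLMNOPQRSTUVWXYZ", relab$u)
  relab$v <- chartr("abcdefghijklmnopqrstuvwxyz",
                    "ABCDEFGHIJKLMNOPQRSTUVWXYZ", relab$v)
  h2 <- select_hubs(as_coab_network(relab))
  expect_setequal(tolower(h2$hubs$taxon), tolower(h$hubs$taxon))
})
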