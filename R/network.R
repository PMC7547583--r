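#' Mutual information between two abundance profiles
#'
#' Plug-in mutual information (in bits) after equal-frequency
#' discretization, with the Miller-Madow bias correction and clamping
#' at zero.  Equal-frequency binning makes the estimate invariant to
#' monotone transforms of either profile, so raw, rescaled and
#' log-transformed abundances give identical values.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @param bins number of bins per variable; default the square-root
#'   rule \code{ceiling(sqrt(n))}.
#' @return nonnegative MI estimate in bits; a constant input gives 0
#'   with a warning.
#' @export
estimate_mi <- function(x, y, bins = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4)
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant vector: MI set to 0")
    return(0)
  }
  .mi_bits(.bin_ef(x, bins), .bin_ef(y, bins), bins, n)
}

# equal-frequency bin assignment; ties broken by original order so the
# result is deterministic
.bin_ef <- function(x, bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

# Miller-Madow corrected plug-in MI in bits from bin assignments
.mi_bits <- function(bx, by, bins, n) {
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins)
  px <- tabulate(bx, nbins = bins) / n
  py <- tabulate(by, nbins = bins) / n
  pj <- joint / n
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- H(px) + H(py) - H(pj)                      # nats
  kx <- sum(px > 0); ky <- sum(py > 0); kj <- sum(pj > 0)
  mm <- ((kx - 1) + (ky - 1) - (kj - 1)) / (2 * n) # Miller-Madow
  max(0, (mi + mm) / log(2))
}

#' Pairwise mutual-information matrix
#'
#' @param data numeric matrix, features (taxa) x samples.
#' @param bins bins per variable; default \code{ceiling(sqrt(n))}.
#' @return symmetric nonnegative matrix of MI in bits, zero diagonal,
#'   with \code{bins} attached as an attribute.
#' @export
mi_matrix <- function(data, bins = NULL) {
  stopifnot(is.matrix(data), ncol(data) >= 4)
  n <- ncol(data)
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  p <- nrow(data)
  binned <- t(apply(data, 1, .bin_ef, bins = bins))
  mi <- matrix(0, p, p, dimnames = list(rownames(data), rownames(data)))
  if (p >= 2) {
    for (i in 1:(p - 1)) {
      for (j in (i + 1):p) {
        mi[i, j] <- mi[j, i] <- .mi_bits(binned[i, ], binned[j, ], bins, n)
      }
    }
  }
  attr(mi, "bins") <- bins
  mi
}

#' Permutation null MI sample
#'
#' Pooled null distribution of the MI estimator at the data's
#' dimensions: for each draw, a random pair of feature rows is taken
#' and one member is permuted across samples before MI is estimated.
#'
#' @param data features x samples matrix.
#' @param n_null number of null draws (>= 1000 recommended).
#' @param bins bins per variable, matched to \code{\link{mi_matrix}}.
#' @return numeric vector of null MI values (bits).
#' @export
mi_null <- function(data, n_null = 1000, bins = NULL) {
  stopifnot(is.matrix(data), nrow(data) >= 2)
  n <- ncol(data)
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  p <- nrow(data)
  binned <- t(apply(data, 1, .bin_ef, bins = bins))
  vapply(seq_len(n_null), function(k) {
    ij <- sample.int(p, 2)
    .mi_bits(binned[ij[1], ], binned[ij[2], ][sample.int(n)], bins, n)
  }, numeric(1))
}

#' C3NET edge selection
#'
#' The conservative-causal-core rule: (1) every pair is assigned a
#' permutation p-value against the pooled null, Benjamini-Hochberg
#' corrected over all pairs; (2) each node contributes the edge to its
#' maximum-MI partner among its significant pairs (lexicographically
#' first partner on MI ties); (3) the union of contributed edges,
#' deduplicated, is the network.  At most one contribution per node, so
#' the edge count never exceeds the node count.
#'
#' @param mi symmetric MI matrix with dimnames.
#' @param null_mi pooled permutation null MI sample (same estimator and
#'   dimensions; >= 1000 draws recommended).
#' @param alpha FDR level for pair significance.
#' @return data frame of undirected edges (u, v, weight = MI), u < v;
#'   zero rows when no pair is significant.
#' @export
c3net <- function(mi, null_mi, alpha = 0.05) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi),
            !is.null(rownames(mi)), length(null_mi) >= 1)
  p <- nrow(mi)
  nodes <- rownames(mi)
  if (p < 2) return(.empty_edges())
  ut <- which(upper.tri(mi), arr.ind = TRUE)
  miv <- mi[ut]
  # permutation p-value with add-one smoothing
  nn <- length(null_mi)
  snull <- sort(null_mi)
  pvals <- (nn - findInterval(miv, snull, left.open = TRUE) + 1) / (nn + 1)
  qvals <- bh_adjust(pvals)
  sig <- matrix(FALSE, p, p)
  sig[ut] <- qvals < alpha
  sig <- sig | t(sig)
  edges <- character(0)
  us <- vs <- character(0); ws <- numeric(0)
  for (i in seq_len(p)) {
    cand <- which(sig[i, ])
    if (length(cand) == 0) next
    best <- cand[which.max(mi[i, cand])]   # which.max: first index on ties
    a <- min(i, best); b <- max(i, best)
    key <- paste(a, b)
    if (!key %in% edges) {
      edges <- c(edges, key)
      us <- c(us, nodes[a]); vs <- c(vs, nodes[b]); ws <- c(ws, mi[a, b])
    }
  }
  out <- data.frame(u = us, v = vs, weight = ws, stringsAsFactors = FALSE)
  out[order(out$u, out$v), , drop = FALSE]
}

.empty_edges <- function() {
  data.frame(u = character(0), v = character(0), weight = numeric(0),
             stringsAsFactors = FALSE)
}

#' BC3NET bagged co-abundance network
#'
#' Bagging ensemble of C3NET: the sample columns are bootstrap-resampled
#' B times, C3NET is run on each resample (with its own permutation
#' null), and an edge's ensemble support count is tested against
#' Binomial(B, p0) with p0 = 1/(number of node pairs), the expected
#' null edge rate; surviving edges (BH at \code{alpha_ens}) are weighted
#' by their support fraction.
#'
#' @param data numeric matrix, taxa x samples (>= 3 taxa, >= 4
#'   samples).
#' @param B number of bootstrap resamples.
#' @param alpha_ind FDR level inside each C3NET run.
#' @param alpha_ens FDR level of the ensemble binomial test.
#' @param n_null permutation null draws per C3NET run.
#' @param bins MI bins; default \code{ceiling(sqrt(n))}.
#' @param seed integer seed; identical seed gives an identical network.
#' @param bootstrap diagnostic flag; \code{FALSE} with \code{B = 1}
#'   reduces to plain C3NET on the original data.
#' @return a \code{coab_network} (see
#'   \code{\link{as_coab_network}}) over all input taxa, including
#'   nodes left unconnected.
#' @export
bc3net <- function(data, B = 100, alpha_ind = 0.05, alpha_ens = 0.05,
                   n_null = 1000, bins = NULL, seed = NULL,
                   bootstrap = TRUE) {
  stopifnot(is.matrix(data), nrow(data) >= 3, ncol(data) >= 4)
  if (B < 1) stop("B must be >= 1")
  if (is.null(rownames(data)))
    rownames(data) <- paste0("t", seq_len(nrow(data)))
  n <- ncol(data)
  p <- nrow(data)
  with_seed(seed, {
    support <- new.env(hash = TRUE)
    for (b in seq_len(B)) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE)
             else seq_len(n)
      d <- data[, idx, drop = FALSE]
      mi <- mi_matrix(d, bins = bins)
      nullv <- mi_null(d, n_null = n_null, bins = bins)
      ed <- c3net(mi, nullv, alpha = alpha_ind)
      if (nrow(ed) == 0) next
      for (r in seq_len(nrow(ed))) {
        key <- paste(ed$u[r], ed$v[r], sep = "\r")
        support[[key]] <- if (is.null(support[[key]])) 1L
                          else support[[key]] + 1L
      }
    }
    keys <- ls(support)
    if (length(keys) == 0)
      return(as_coab_network(.empty_edges(), nodes = rownames(data)))
    counts <- vapply(keys, function(k) support[[k]], integer(1))
    p0 <- 1 / (p * (p - 1) / 2)
    pb <- stats::pbinom(counts - 1L, size = B, prob = p0,
                        lower.tail = FALSE)
    qb <- bh_adjust(pb)
    keep <- qb < alpha_ens
    uv <- do.call(rbind, strsplit(keys[keep], "\r", fixed = TRUE))
    ed <- if (sum(keep) == 0) .empty_edges()
          else data.frame(u = uv[, 1], v = uv[, 2],
                          weight = counts[keep] / B,
                          stringsAsFactors = FALSE)
    ed <- ed[order(ed$u, ed$v), , drop = FALSE]
    as_coab_network(ed, nodes = rownames(data))
  })
}

#' Build a co-abundance network object
#'
#' Wraps an undirected weighted edge list plus the full node set
#' (isolated nodes included) in an igraph graph with per-node degree
#' and betweenness.
#'
#' @param edges data frame with columns u, v, weight; no self loops or
#'   duplicates.
#' @param nodes character vector of all node names (superset of edge
#'   endpoints).
#' @return object of class \code{coab_network}: \code{graph} (igraph),
#'   \code{edges}, \code{nodes}, \code{degree}, \code{betweenness}
#'   (unweighted shortest paths, endpoints excluded).
#' @export
as_coab_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("u", "v", "weight") %in% names(edges)))
  if (any(edges$u == edges$v)) stop("self-loops are not allowed")
  key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v))
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$u, edges$v)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = FALSE)
  structure(list(graph = g, edges = edges, nodes = nodes,
                 degree = deg, betweenness = btw),
            class = "coab_network")
}

#' @export
print.coab_network <- function(x, ...) {
  s <- network_stats(x)
  cat("Co-abundance network:", s$n_nodes, "nodes,", s$n_edges, "edges\n")
  cat(sprintf("Giant component: %d nodes (%d unconnected); mean degree %.2f, mean betweenness %.1f\n",
              s$giant_size, s$n_isolated, s$avg_degree,
              s$avg_betweenness))
  invisible(x)
}

#' MST2 backbone of a weighted network
#'
#' Reduces each connected component to the union of its minimum
#' spanning tree (on distance d = w_max - w, where w is the MI or
#' ensemble-support weight) and the minimum spanning forest of the
#' component with those edges removed.  Ties are broken by
#' lexicographic node-pair order, so the reduction is deterministic.
#'
#' @param net a \code{coab_network}.
#' @return object of class \code{mst2_tree}: \code{edges} (u, v,
#'   weight, in_mst1, in_mst2) covering the full parent edge list, and
#'   \code{graph}, the igraph of the MST2 edge subset over all parent
#'   nodes.
#' @export
mst2_reduce <- function(net) {
  stopifnot(inherits(net, "coab_network"))
  ed <- net$edges
  if (nrow(ed) == 0) {
    out <- cbind(ed, in_mst1 = logical(0), in_mst2 = logical(0))
    g <- igraph::graph_from_data_frame(
      out, directed = FALSE, vertices = data.frame(name = net$nodes))
    return(structure(list(edges = out, graph = g), class = "mst2_tree"))
  }
  wmax <- max(ed$weight)
  dd <- wmax - ed$weight
  ord <- order(dd, pmin(ed$u, ed$v), pmax(ed$u, ed$v))
  in1 <- .kruskal(ed$u, ed$v, ord, net$nodes)
  # second tree: same rule on the remaining edges
  ord2 <- ord[!in1[ord]]
  in2 <- .kruskal(ed$u, ed$v, ord2, net$nodes)
  out <- cbind(ed, in_mst1 = in1, in_mst2 = in1 | in2)
  g <- igraph::graph_from_data_frame(
    out[out$in_mst2, c("u", "v", "weight")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  structure(list(edges = out, graph = g), class = "mst2_tree")
}

# Kruskal forest over edges visited in the given order; returns a
# logical vector (over the full edge list) marking accepted edges.
.kruskal <- function(u, v, ord, nodes) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  acc <- logical(length(u))
  for (e in ord) {
    ru <- find(match(u[e], nodes))
    rv <- find(match(v[e], nodes))
    if (ru != rv) {
      parent[ru] <- rv
      acc[e] <- TRUE
    }
  }
  acc
}

#' Topology statistics of a co-abundance network
#'
#' Degree and betweenness summaries on the giant component: average
#' degree is 2E/N over the giant component's nodes and edges;
#' betweenness is the unnormalized number of unweighted shortest paths
#' through a node (endpoints excluded), averaged over giant-component
#' nodes.  Nodes outside the giant component are counted as
#' unconnected.
#'
#' @param net a \code{coab_network} (or \code{mst2_tree}).
#' @return list: n_nodes, n_edges, giant_size, n_isolated, avg_degree,
#'   avg_betweenness.
#' @export
network_stats <- function(net) {
  g <- if (inherits(net, "coab_network") || inherits(net, "mst2_tree"))
         net$graph else net
  n_nodes <- igraph::vcount(g)
  n_edges <- igraph::ecount(g)
  if (n_nodes == 0 || n_edges == 0)
    return(list(n_nodes = n_nodes, n_edges = n_edges, giant_size = 0,
                n_isolated = n_nodes, avg_degree = 0,
                avg_betweenness = 0))
  comp <- igraph::components(g)
  giant_id <- which.max(comp$csize)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == giant_id))
  gn <- igraph::vcount(giant)
  ge <- igraph::ecount(giant)
  btw <- igraph::betweenness(giant, directed = FALSE, weights = NA,
                             normalized = FALSE)
  list(n_nodes = n_nodes,
       n_edges = n_edges,
       giant_size = gn,
       n_isolated = n_nodes - gn,
       avg_degree = 2 * ge / gn,
       avg_betweenness = mean(btw))
}

#' Percentile-rule hub detection
#'
#' The degree threshold is the linear-interpolation percentile of the
#' degree sequence over all nodes (isolated nodes included, at degree
#' 0); hubs are the nodes whose degree strictly exceeds it.
#'
#' @param net a \code{coab_network}.
#' @param percentile percentile of the degree distribution (default
#'   95).
#' @return object of class \code{hub_report}: \code{threshold} (may be
#'   non-integer), \code{percentile}, and \code{hubs}, a data frame
#'   (taxon, degree, betweenness) sorted by decreasing degree.
#' @export
select_hubs <- function(net, percentile = 95) {
  stopifnot(inherits(net, "coab_network"))
  if (length(net$nodes) == 0) stop("empty network")
  deg <- net$degree
  thr <- unname(stats::quantile(deg, percentile / 100, type = 7))
  hub <- deg > thr
  hubs <- data.frame(taxon = names(deg)[hub],
                     degree = unname(deg[hub]),
                     betweenness = unname(net$betweenness[hub]),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$degree, hubs$taxon), , drop = FALSE]
  rownames(hubs) <- NULL
  structure(list(threshold = thr, percentile = percentile, hubs = hubs),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("Hubs: degree > %.2f (%gth percentile)\n", x$threshold,
              x$percentile))
  print(x$hubs)
  invisible(x)
}
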