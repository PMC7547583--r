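#' Moment fit of the Poisson-Tweedie family to one group's counts
#'
#' Fits mean \code{mu} and dispersion \code{phi} by the method of
#' moments on normalization-rescaled counts, then picks the shape
#' \code{a} among the family's named special cases (Poisson, negative
#' binomial, Poisson-inverse-Gaussian) by maximizing the corresponding
#' closed-form likelihood; ties go to the negative binomial.  Zero
#' empirical overdispersion fixes the Poisson shape directly.
#'
#' @param counts integer vector of one taxon's counts in one group.
#' @param norm_factors optional per-sample scaling factors, same length
#'   as \code{counts}; counts are divided by them before fitting.
#' @param group optional group label carried into the result.
#' @return object of class \code{pt_fit}: \code{mu}, \code{phi} (>= 1),
#'   \code{a}, \code{n}, \code{group}, \code{fitted}.  An all-zero
#'   vector is flagged (\code{fitted = FALSE}) and not fitted.
#' @export
fit_pt_moments <- function(counts, norm_factors = NULL, group = NA) {
  n <- length(counts)
  if (n < 2) stop("need at least 2 observations")
  x <- if (is.null(norm_factors)) as.numeric(counts)
       else as.numeric(counts) / norm_factors
  if (all(counts == 0)) {
    return(structure(list(mu = 0, phi = NA_real_, a = NA_real_, n = n,
                          group = group, fitted = FALSE),
                     class = "pt_fit"))
  }
  mu <- mean(x)
  phi <- max(1, stats::var(x) / mu)
  if (phi <= 1) {
    a <- 1
  } else {
    # shape selection on integerized rescaled counts
    k <- round(x)
    ll_nb <- sum(dnb_log(k, mu, phi))
    ll_pig <- sum(dpig_log(k, mu, phi))
    a <- if (ll_pig > ll_nb) 0.5 else 0
  }
  structure(list(mu = mu, phi = phi, a = a, n = n, group = group,
                 fitted = TRUE),
            class = "pt_fit")
}

#' @export
print.pt_fit <- function(x, ...) {
  cat(sprintf("PT moment fit: mu = %.3f, phi = %.3f, a = %s (n = %d)\n",
              x$mu, x$phi, format(x$a), x$n))
  invisible(x)
}

#' Two-sample Poisson-Tweedie test on group means
#'
#' Tests equality of the two group means with a moment-based Gaussian z
#' statistic whose variance plugs in the per-group Poisson-Tweedie
#' moment fits:
#' \deqn{z = (\hat m_A - \hat m_B) /
#'   \sqrt{\hat\phi_A \hat m_A / n_A + \hat\phi_B \hat m_B / n_B}.}
#' Counts are rescaled by the normalization factors first.  Because the
#' plug-in variance is itself noisy at the small group sizes typical of
#' animal studies, the two-sided p-value is taken from a Student t
#' reference with nA + nB - 2 degrees of freedom rather than the
#' standard-normal tail; the two coincide as group sizes grow, and the
#' t reference keeps the empirical type-I error near its nominal level
#' at n = 4 per group.  A taxon all-zero in both groups returns p = 1;
#' all-zero in exactly one group gets a variance floor of one count so
#' the test is still defined.
#'
#' @param countsA,countsB integer count vectors for the two groups.
#' @param factorsA,factorsB optional normalization factors per sample.
#' @return list with \code{z} and two-sided \code{p}.
#' @export
pt_two_sample_test <- function(countsA, countsB,
                               factorsA = NULL, factorsB = NULL) {
  nA <- length(countsA); nB <- length(countsB)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 samples")
  xA <- if (is.null(factorsA)) as.numeric(countsA)
        else as.numeric(countsA) / factorsA
  xB <- if (is.null(factorsB)) as.numeric(countsB)
        else as.numeric(countsB) / factorsB
  if (all(countsA == 0) && all(countsB == 0))
    return(list(z = 0, p = 1))
  mA <- mean(xA); mB <- mean(xB)
  # phi*mu plug-in = max(sample variance, mean): dispersion clamped >= 1
  vA <- max(stats::var(xA), mA)
  vB <- max(stats::var(xB), mB)
  if (all(countsA == 0)) vA <- max(vA, 1)   # variance floor of 1 count
  if (all(countsB == 0)) vB <- max(vB, 1)
  se <- sqrt(vA / nA + vB / nB)
  if (se == 0) return(list(z = 0, p = 1))
  z <- (mA - mB) / se
  list(z = z, p = 2 * stats::pt(-abs(z), df = nA + nB - 2))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Maps p-values to BH-adjusted q-values,
#' \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j} capped at 1 and
#' returned in the input order.
#'
#' @param pvalues numeric vector in [0, 1] (NAs propagate).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' All pairwise differential-abundance comparisons
#'
#' Runs the two-sample Poisson-Tweedie test for every retained taxon in
#' each unordered pair of phenotype groups (six comparisons for four
#' groups), adjusts p-values by Benjamini-Hochberg within each
#' comparison, and flags taxa at \code{q < alpha}.  The union of taxa
#' significant in at least one comparison is the node set handed to the
#' co-abundance network stage.
#'
#' @param taxa a \code{\link{taxon_count_matrix}}.
#' @param norm optional \code{tmm_norm}; defaults to factors attached to
#'   \code{taxa}, or no rescaling if none.
#' @param alpha FDR threshold.
#' @return object of class \code{da_result}: \code{table} (data frame:
#'   taxon, comparison, z, p, q, log2fc, significant),
#'   \code{comparisons}, \code{union_da}, \code{alpha}.
#' @export
run_pairwise_da <- function(taxa, norm = NULL, alpha = 0.05) {
  stopifnot(inherits(taxa, "taxon_counts"))
  groups <- unique(taxa$phenotype)
  if (length(groups) < 2) stop("need at least 2 phenotype groups")
  f <- if (!is.null(norm)) norm$factors
       else if (!is.null(taxa$norm_factors)) taxa$norm_factors
       else stats::setNames(rep(1, ncol(taxa$counts)),
                            colnames(taxa$counts))
  f <- f[colnames(taxa$counts)]
  x <- taxa$counts
  pairs <- utils::combn(groups, 2)
  res <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    gA <- pairs[1, k]; gB <- pairs[2, k]
    cmp <- paste(gA, gB, sep = "_vs_")
    jA <- which(taxa$phenotype == gA)
    jB <- which(taxa$phenotype == gB)
    if (length(jA) < 2 || length(jB) < 2)
      stop("group with fewer than 2 samples: ", gA, " vs ", gB)
    zs <- ps <- fc <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      tt <- pt_two_sample_test(x[i, jA], x[i, jB], f[jA], f[jB])
      zs[i] <- tt$z; ps[i] <- tt$p
      mA <- mean(x[i, jA] / f[jA]); mB <- mean(x[i, jB] / f[jB])
      fc[i] <- log2((mA + 0.5) / (mB + 0.5))
    }
    qs <- bh_adjust(ps)
    res[[k]] <- data.frame(taxon = rownames(x), comparison = cmp,
                           z = zs, p = ps, q = qs, log2fc = fc,
                           significant = qs < alpha,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 comparisons = unique(tab$comparison),
                 union_da = sort(unique(tab$taxon[tab$significant])),
                 alpha = alpha),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat("Differential abundance:", length(x$comparisons), "comparisons,",
      length(unique(x$table$taxon)), "taxa\n")
  sig <- tapply(x$table$significant, x$table$comparison, sum)
  for (cmp in x$comparisons)
    cat(sprintf("  %-20s %d significant (q < %.2g)\n", cmp, sig[[cmp]],
                x$alpha))
  cat("Union of DA taxa:", length(x$union_da), "\n")
  invisible(x)
}

#' Fisher exact enrichment of annotation terms in a DA set
#'
#' One-sided hypergeometric test per term on the 2x2 table of
#' DA-membership against term-membership over a background universe.
#' Raw p-values are reported and thresholded (no multiplicity
#' correction, matching common practice for GO term screens at
#' p < 0.01).
#'
#' @param da_ids differentially abundant identifiers (subset of
#'   background).
#' @param background_ids the tested universe.
#' @param annotation_map data frame with columns \code{id} and
#'   \code{term} (flat term sets; one row per assignment).
#' @param alpha p-value threshold for the \code{enriched} flag.
#' @return data frame: term, n_da_in_term, n_term, n_da, n_background,
#'   p, enriched; sorted by p.
#' @export
fisher_enrichment <- function(da_ids, background_ids, annotation_map,
                              alpha = 0.01) {
  stopifnot(all(c("id", "term") %in% names(annotation_map)))
  da_ids <- unique(da_ids); background_ids <- unique(background_ids)
  if (!all(da_ids %in% background_ids))
    stop("da_ids must be a subset of background_ids")
  amap <- annotation_map[annotation_map$id %in% background_ids, ]
  skipped <- setdiff(unique(annotation_map$term), unique(amap$term))
  if (length(skipped) > 0)
    warning("term(s) with zero background members skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  N <- length(background_ids)
  n <- length(da_ids)
  terms <- sort(unique(amap$term))
  rows <- lapply(terms, function(tm) {
    members <- unique(amap$id[amap$term == tm])
    K <- length(members)
    k <- sum(da_ids %in% members)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_da_in_term = k, n_term = K, n_da = n,
               n_background = N, p = p, enriched = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Welch t-tests of hub abundances across all comparisons
#'
#' For each hub taxon and each unordered pair of phenotype groups, a
#' two-sided Welch two-sample t-test on (rescaled) abundances.
#'
#' @param taxa a \code{\link{taxon_count_matrix}} containing the hub
#'   rows.
#' @param hub_ids taxon identifiers to test.
#' @param norm optional \code{tmm_norm} for rescaling.
#' @return data frame: taxon, comparison, t, p.
#' @export
hub_ttest <- function(taxa, hub_ids, norm = NULL) {
  stopifnot(inherits(taxa, "taxon_counts"))
  missing_ids <- setdiff(hub_ids, rownames(taxa$counts))
  if (length(missing_ids) > 0)
    stop("hub taxa absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  f <- if (!is.null(norm)) norm$factors[colnames(taxa$counts)]
       else if (!is.null(taxa$norm_factors))
         taxa$norm_factors[colnames(taxa$counts)]
       else rep(1, ncol(taxa$counts))
  x <- sweep(taxa$counts[hub_ids, , drop = FALSE], 2, f, `/`)
  groups <- unique(taxa$phenotype)
  pairs <- utils::combn(groups, 2)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    jA <- taxa$phenotype == pairs[1, k]
    jB <- taxa$phenotype == pairs[2, k]
    if (sum(jA) < 2 || sum(jB) < 2)
      stop("each group needs at least 2 samples")
    cmp <- paste(pairs[1, k], pairs[2, k], sep = "_vs_")
    for (h in hub_ids) {
      a <- x[h, jA]; b <- x[h, jB]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        tt <- list(statistic = 0, p.value = if (mean(a) == mean(b)) 1
                   else 0)
      } else {
        tt <- stats::t.test(a, b)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(taxon = h, comparison = cmp,
                   t = unname(tt$statistic), p = tt$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Hierarchical clustering of abundance profiles
#'
#' Agglomerative clustering with Euclidean distance and complete
#' linkage after per-row z-scaling (the usual heatmap convention).
#' Constant rows, which cannot be scaled, are dropped with a warning.
#'
#' @param mat numeric matrix (features x samples).
#' @param axis cluster \code{"columns"} (samples) or \code{"rows"}
#'   (features).
#' @param k optional number of clusters to cut the tree into.
#' @param scale_rows z-score rows before distances are computed.
#' @return list: \code{hclust} (merge tree), \code{labels} (k-cut
#'   assignment, NULL if \code{k} missing), \code{dropped} (constant
#'   row names).
#' @export
hierarchical_cluster <- function(mat, axis = c("columns", "rows"),
                                 k = NULL, scale_rows = TRUE) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(mat))
  dropped <- character(0)
  if (scale_rows) {
    sds <- apply(mat, 1, stats::sd)
    if (any(sds == 0)) {
      dropped <- rownames(mat)[sds == 0]
      warning("constant row(s) dropped before scaling: ",
              paste(utils::head(dropped, 5), collapse = ", "))
      mat <- mat[sds > 0, , drop = FALSE]
    }
    mat <- t(scale(t(mat)))
  }
  items <- if (axis == "columns") t(mat) else mat
  if (nrow(items) < 2) stop("need at least 2 items to cluster")
  hc <- stats::hclust(stats::dist(items, method = "euclidean"),
                      method = "complete")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels, dropped = dropped)
}
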