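#' NSAF protein quantification
#'
#' Converts spectral counts to normalized spectral abundance factors:
#' each protein's count is divided by its length and the result is
#' rescaled so every sample column sums to one,
#' \deqn{NSAF_{ij} = \frac{SpC_{ij}/L_i}{\sum_k SpC_{kj}/L_k}.}
#'
#' @param counts a \code{\link{spectral_count_matrix}}.
#' @return numeric matrix of NSAF values with the same dimnames; a
#'   sample with no identified spectra yields an all-zero column with a
#'   warning.
#' @export
compute_nsaf <- function(counts) {
  stopifnot(inherits(counts, "spc_matrix"))
  saf <- counts$counts / counts$lengths
  colsum <- colSums(saf)
  zero <- colsum == 0
  if (any(zero)) {
    warning("sample(s) with all-zero counts: ",
            paste(colnames(counts$counts)[zero], collapse = ", "))
    colsum[zero] <- 1
  }
  sweep(saf, 2, colsum, `/`)
}

#' Log2 transform with downshifted-Gaussian imputation
#'
#' Observed (nonzero) NSAF entries are log2 transformed; zeros are
#' treated as missing and imputed per sample from a Gaussian shifted
#' below the sample's observed distribution, the standard
#' detection-limit imputation for label-free proteomics intensities:
#' imputed values are drawn from
#' N(mean - downshift * SD, (width * SD)^2), with mean and SD taken
#' over the sample's observed log2 values.
#'
#' @param nsaf numeric NSAF matrix (proteins x samples).
#' @param downshift distance of the imputation distribution below the
#'   observed mean, in observed-SD units.
#' @param width SD of the imputation distribution, in observed-SD
#'   units.
#' @param seed optional integer seed for reproducible imputation.
#' @return numeric matrix of log2 abundances, no missing values.
#' @export
log2_transform_impute <- function(nsaf, downshift = 1.8, width = 0.3,
                                  seed = NULL) {
  stopifnot(is.matrix(nsaf), downshift >= 0, width > 0)
  obs <- nsaf > 0 & !is.na(nsaf)
  n_obs <- colSums(obs)
  if (any(n_obs < 3))
    stop("sample(s) with fewer than 3 observed values: ",
         paste(colnames(nsaf)[n_obs < 3], collapse = ", "))
  out <- matrix(NA_real_, nrow(nsaf), ncol(nsaf), dimnames = dimnames(nsaf))
  out[obs] <- log2(nsaf[obs])
  with_seed(seed, {
    for (j in seq_len(ncol(out))) {
      miss <- !obs[, j]
      if (!any(miss)) next
      m <- mean(out[obs[, j], j])
      s <- stats::sd(out[obs[, j], j])
      out[miss, j] <- stats::rnorm(sum(miss), m - downshift * s, width * s)
    }
    out
  })
}

#' Aggregate protein counts to taxa at their lowest assigned rank
#'
#' Protein spectral counts are grouped by the taxonomy map and summed
#' per taxon and sample.  A protein assigned only at genus or family
#' rank contributes to a taxon keyed at that rank, kept distinct from
#' any species-level taxon of the same lineage; the rank used is
#' recorded per taxon.
#'
#' @param counts a \code{\link{spectral_count_matrix}}.
#' @param taxmap data frame with columns \code{protein_id},
#'   \code{family}, \code{genus}, \code{species} (NA when unassigned)
#'   and \code{rank} (the lowest assigned rank).
#' @return a \code{\link{taxon_count_matrix}}, taxa sorted by id.
#' @export
aggregate_to_taxa <- function(counts, taxmap) {
  stopifnot(inherits(counts, "spc_matrix"),
            all(c("protein_id", "family", "genus", "species", "rank")
                %in% names(taxmap)))
  ids <- rownames(counts$counts)
  hit <- match(ids, taxmap$protein_id)
  if (anyNA(hit))
    stop("protein(s) absent from taxonomy map: ",
         paste(utils::head(ids[is.na(hit)], 5), collapse = ", "))
  tm <- taxmap[hit, ]
  taxon <- ifelse(tm$rank == "species", tm$species,
                  ifelse(tm$rank == "genus", tm$genus, tm$family))
  if (anyNA(taxon))
    stop("taxonomy rows whose stated rank has no name: ",
         paste(utils::head(tm$protein_id[is.na(taxon)], 5), collapse = ", "))
  agg <- rowsum(counts$counts, group = taxon, reorder = TRUE)
  rank_of <- tapply(tm$rank, taxon, function(r) r[1])[rownames(agg)]
  taxon_count_matrix(agg, rank = rank_of, phenotype = counts$phenotype)
}

#' Remove sparsely observed taxa
#'
#' A taxon is retained only if it reaches \code{min_count} spectral
#' counts in at least \code{min_samples} samples; with the defaults,
#' taxa with fewer than five counts in all samples but one are removed.
#' Retained counts are unchanged and the operation is idempotent.
#'
#' @param taxa a \code{\link{taxon_count_matrix}}.
#' @param min_count minimum count defining an "observed" sample.
#' @param min_samples minimum number of samples reaching
#'   \code{min_count}.
#' @return filtered \code{taxon_counts}; empty results are allowed (a
#'   warning is emitted).
#' @export
filter_low_counts <- function(taxa, min_count = 5, min_samples = 2) {
  stopifnot(inherits(taxa, "taxon_counts"), min_count >= 1,
            min_samples >= 1)
  keep <- rowSums(taxa$counts >= min_count) >= min_samples
  if (!any(keep)) warning("no taxa pass the low-count filter")
  taxon_count_matrix(taxa$counts[keep, , drop = FALSE],
                     rank = taxa$rank[keep],
                     phenotype = taxa$phenotype,
                     norm_factors = taxa$norm_factors)
}

#' TMM between-sample normalization
#'
#' Trimmed mean of M-values scaling factors, the RNA-seq composition
#' normalization applied here to taxon-level spectral counts.  For each
#' sample against a reference, per-taxon log ratios
#' \eqn{M_g = \log_2\{(T_{gj}/N_j)/(T_{gr}/N_r)\}} and log averages
#' \eqn{A_g} are computed over taxa nonzero in both samples, doubly
#' trimmed (by M and by A), and combined by a precision-weighted mean
#' with inverse asymptotic (binomial) variance weights; factors are
#' rescaled so their geometric mean is one.  The reference is the
#' sample whose upper-quartile count fraction is closest to the mean
#' upper quartile.
#'
#' The returned \code{factors} are effective per-sample scales --
#' relative library size times the TMM composition factor, rescaled to
#' geometric mean one -- so that dividing counts by them makes samples
#' directly comparable (two identical samples get factors of 1; exactly
#' doubling one sample's counts doubles its factor up to the
#' geometric-mean rescaling).  The composition-only factors are kept in
#' \code{tmm} for comparison with RNA-seq tooling.
#'
#' @param taxa a \code{\link{taxon_count_matrix}}.
#' @param trim_m two-sided trim fraction on the M values.
#' @param trim_a two-sided trim fraction on the A values.
#' @return object of class \code{tmm_norm}: \code{factors} (effective,
#'   named, geometric mean 1), \code{tmm} (composition factors,
#'   geometric mean 1), \code{lib_size}, \code{reference} (sample id),
#'   \code{trim_m}, \code{trim_a}, and per-sample lists \code{M} and
#'   \code{A} of the untrimmed values used.
#' @export
tmm_normalize <- function(taxa, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(taxa, "taxon_counts"),
            trim_m >= 0, trim_m < 0.5, trim_a >= 0, trim_a < 0.5)
  x <- taxa$counts
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(x)
  if (any(lib == 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(x)[lib == 0], collapse = ", "))

  # reference: upper-quartile count fraction closest to the mean
  uq <- apply(x, 2, stats::quantile, probs = 0.75) / lib
  ref_j <- which.min(abs(uq - mean(uq)))
  refc <- as.numeric(x[, ref_j])
  nR <- lib[ref_j]

  Ms <- As <- vector("list", ncol(x))
  names(Ms) <- names(As) <- colnames(x)
  f <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    obsc <- as.numeric(x[, j])
    nO <- lib[j]
    M <- log2((obsc / nO) / (refc / nR))
    A <- (log2(obsc / nO) + log2(refc / nR)) / 2
    v <- (nO - obsc) / (nO * obsc) + (nR - refc) / (nR * refc)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    Ms[[j]] <- M; As[[j]] <- A
    if (length(M) == 0 || max(abs(M)) < 1e-6) {
      f[j] <- 1
      next
    }
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    wmean <- sum(M[keep] / v[keep], na.rm = TRUE) /
      sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(wmean)) wmean <- 0
    f[j] <- 2^wmean
  }
  f <- f / exp(mean(log(f)))
  eff <- f * lib
  eff <- eff / exp(mean(log(eff)))
  structure(list(factors = stats::setNames(eff, colnames(x)),
                 tmm = stats::setNames(f, colnames(x)),
                 lib_size = stats::setNames(lib, colnames(x)),
                 reference = colnames(x)[ref_j],
                 trim_m = trim_m, trim_a = trim_a,
                 M = Ms, A = As),
            class = "tmm_norm")
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("TMM normalization (reference:", x$reference, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}
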