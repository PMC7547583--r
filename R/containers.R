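#' Protein-level spectral-count matrix
#'
#' The pipeline's raw input: an integer matrix of spectral counts
#' (proteins x samples) together with protein lengths in residues and a
#' phenotype label per sample.
#'
#' @param counts integer matrix, proteins in rows, samples in columns;
#'   dimnames required.
#' @param lengths protein lengths (amino-acid residues, > 0), one per
#'   row of \code{counts}.
#' @param phenotype character vector of group labels, one per column.
#' @return object of class \code{spc_matrix}.
#' @export
spectral_count_matrix <- function(counts, lengths, phenotype) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' needs row (protein) and column (sample) names")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (length(lengths) != nrow(counts))
    stop("one length per protein required")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("protein lengths must be strictly positive")
  if (length(phenotype) != ncol(counts))
    stop("one phenotype label per sample required")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 lengths = stats::setNames(as.numeric(lengths),
                                           rownames(counts)),
                 phenotype = stats::setNames(as.character(phenotype),
                                             colnames(counts))),
            class = "spc_matrix")
}

#' @export
print.spc_matrix <- function(x, ...) {
  cat("Spectral-count matrix:", nrow(x$counts), "proteins x",
      ncol(x$counts), "samples\n")
  cat("Phenotypes:", paste(sprintf("%s (n=%d)", names(table(x$phenotype)),
                                   table(x$phenotype)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Taxon-level count matrix
#'
#' Counts aggregated to taxa at their lowest assigned rank, with the
#' rank used per taxon and the per-sample phenotype carried along.
#' Optionally carries TMM normalization factors after
#' \code{\link{tmm_normalize}}.
#'
#' @param counts integer matrix, taxa x samples, dimnames required.
#' @param rank character vector, the taxonomic rank of each row.
#' @param phenotype group label per sample column.
#' @param norm_factors optional per-sample scaling factors.
#' @return object of class \code{taxon_counts}.
#' @export
taxon_count_matrix <- function(counts, rank, phenotype,
                               norm_factors = NULL) {
  counts <- as.matrix(counts)
  # an empty matrix (hard filter) legitimately has no row names
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("'counts' needs row (taxon) and column (sample) names")
  if (anyDuplicated(rownames(counts)))
    stop("taxon ids must be unique")
  if (length(rank) != nrow(counts))
    stop("one rank per taxon required")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 rank = stats::setNames(as.character(rank),
                                        rownames(counts)),
                 phenotype = stats::setNames(as.character(phenotype),
                                             colnames(counts)),
                 norm_factors = norm_factors),
            class = "taxon_counts")
}

#' @export
print.taxon_counts <- function(x, ...) {
  cat("Taxon-count matrix:", nrow(x$counts), "taxa x", ncol(x$counts),
      "samples\n")
  cat("Ranks:", paste(sprintf("%s: %d", names(table(x$rank)),
                              table(x$rank)), collapse = ", "), "\n")
  if (!is.null(x$norm_factors)) cat("TMM factors attached\n")
  invisible(x)
}

#' Rescale taxon counts by attached or supplied TMM factors
#'
#' Divides each sample column by its normalization factor, giving the
#' effective abundances used by the differential tests and the network
#' stage.
#'
#' @param taxa a \code{taxon_counts} object.
#' @param norm optional \code{tmm_norm} result; defaults to the factors
#'   attached to \code{taxa}.
#' @return numeric matrix of rescaled (non-integer) counts.
#' @export
rescaled_counts <- function(taxa, norm = NULL) {
  f <- if (!is.null(norm)) norm$factors else taxa$norm_factors
  if (is.null(f)) stop("no normalization factors attached or supplied")
  f <- f[colnames(taxa$counts)]
  sweep(taxa$counts, 2, f, `/`)
}
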