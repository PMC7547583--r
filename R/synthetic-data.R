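#' Configuration for the synthetic metaproteome generator
#'
#' Collects every knob of the generator with defaults emulating a
#' 4-group (CKD, CKDRS, HRS, H) cecal metaproteome design with four
#' animals per group: overdispersed Poisson-Tweedie protein counts,
#' multi-protein taxa (a fraction assignable only above species rank),
#' planted taxon-level fold changes in randomly chosen groups, planted
#' co-abundance modules driven by shared log-normal latent factors, and
#' sporadic detection-limit zeros.
#'
#' @param n_taxa number of bacterial taxa.
#' @param proteins_per_taxon integer range; per-taxon protein count is
#'   drawn uniformly from it.
#' @param protein_length_range protein length range in amino-acid
#'   residues.
#' @param groups ordered phenotype labels.
#' @param n_per_group samples per group.
#' @param baseline_mu_range per-protein baseline mean spectral count per
#'   sample, drawn log-uniformly from this range.
#' @param phi_range per-protein dispersion (variance/mean) range,
#'   drawn uniformly; values are >= 1.
#' @param a PT shape index: 1 (Poisson; forces phi = 1), 0 (negative
#'   binomial) or 0.5 (Poisson-inverse-Gaussian).
#' @param frac_da fraction of taxa carrying a planted fold change.
#' @param log2fc_range magnitude range of planted log2 fold changes.
#' @param n_modules number of planted co-abundance modules.
#' @param module_size taxa per module (modules are disjoint).
#' @param module_rho latent-factor coupling strength in [0, 1).
#' @param frac_unassigned_species fraction of proteins whose lineage is
#'   truncated to genus or family rank.
#' @param missing_rate expected fraction of protein/sample cells zeroed
#'   by the detection-limit mechanism.
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output.
#' @return an object of class \code{synthetic_config} (a named list).
#' @export
synthetic_config <- function(n_taxa = 50,
                             proteins_per_taxon = c(1L, 20L),
                             protein_length_range = c(80L, 1500L),
                             groups = c("CKD", "CKDRS", "HRS", "H"),
                             n_per_group = 4L,
                             baseline_mu_range = c(0.5, 30),
                             phi_range = c(1, 10),
                             a = 0,
                             frac_da = 0.2,
                             log2fc_range = c(1, 3),
                             n_modules = 3L,
                             module_size = 5L,
                             module_rho = 0.7,
                             frac_unassigned_species = 0.2,
                             missing_rate = 0.05,
                             seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa),
              proteins_per_taxon = as.integer(proteins_per_taxon),
              protein_length_range = as.integer(protein_length_range),
              groups = as.character(groups),
              n_per_group = as.integer(n_per_group),
              baseline_mu_range = as.numeric(baseline_mu_range),
              phi_range = as.numeric(phi_range),
              a = as.numeric(a),
              frac_da = as.numeric(frac_da),
              log2fc_range = as.numeric(log2fc_range),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_rho = as.numeric(module_rho),
              frac_unassigned_species = as.numeric(frac_unassigned_species),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  stopifnot(cfg$n_taxa >= 1, length(cfg$groups) >= 2,
            cfg$n_per_group >= 1,
            cfg$a %in% c(1, 0, 0.5),
            all(cfg$phi_range >= 1),
            cfg$frac_da >= 0, cfg$frac_da <= 1,
            cfg$module_rho >= 0, cfg$module_rho < 1,
            cfg$frac_unassigned_species >= 0,
            cfg$frac_unassigned_species <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  if (cfg$n_modules * cfg$module_size > cfg$n_taxa)
    stop("module_size * n_modules exceeds n_taxa")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic metaproteome with planted structure
#'
#' Emits a protein-level spectral-count matrix, its taxonomy map and a
#' ground-truth record of everything planted.  Proteins are partitioned
#' among taxa; each taxon's planted log2 fold change multiplies the mean
#' of all its proteins in the affected group; members of a co-abundance
#' module share a per-sample log-normal latent factor scaled by
#' \code{module_rho}, which induces positive mutual information between
#' their abundance profiles.  A fraction of proteins is assigned only at
#' genus or family rank, and low-abundance cells are preferentially
#' zeroed to mimic detection limits.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return a list with components \code{counts} (a
#'   \code{\link{spectral_count_matrix}}), \code{taxonomy} (data frame:
#'   protein_id, family, genus, species, rank) and \code{truth}
#'   (see Details).
#' @details \code{truth} holds \code{da_taxa} (per pairwise comparison,
#'   the taxa with nonzero planted effect), \code{effects} (taxon,
#'   affected group, signed log2FC), \code{module_membership} (taxon ->
#'   module id or NA) and \code{planted_params} (per-protein mu, phi, a).
#' @export
generate_metaproteome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_samples <- length(cfg$groups) * cfg$n_per_group
    sample_ids <- paste0(rep(cfg$groups, each = cfg$n_per_group), "_",
                         rep(seq_len(cfg$n_per_group), length(cfg$groups)))
    phenotype <- stats::setNames(rep(cfg$groups, each = cfg$n_per_group),
                                 sample_ids)

    ## --- taxonomy scaffold: ~3 species per genus, ~3 genera per family
    taxa <- sprintf("sp_%03d", seq_len(cfg$n_taxa))
    genus_of <- sprintf("gen_%03d", (seq_len(cfg$n_taxa) - 1L) %/% 3L + 1L)
    family_of <- sprintf("fam_%03d", (seq_len(cfg$n_taxa) - 1L) %/% 9L + 1L)

    ## --- proteins per taxon
    ppt <- sample(cfg$proteins_per_taxon[1]:cfg$proteins_per_taxon[2],
                  cfg$n_taxa, replace = TRUE)
    taxon_of_protein <- rep(seq_len(cfg$n_taxa), times = ppt)
    n_prot <- length(taxon_of_protein)
    protein_ids <- sprintf("prot_%05d", seq_len(n_prot))
    lengths <- sample(cfg$protein_length_range[1]:cfg$protein_length_range[2],
                      n_prot, replace = TRUE)

    ## --- per-protein PT parameters
    lmu <- stats::runif(n_prot, log(cfg$baseline_mu_range[1]),
                        log(cfg$baseline_mu_range[2]))
    mu <- exp(lmu)
    phi <- if (cfg$a == 1) rep(1, n_prot)
           else stats::runif(n_prot, cfg$phi_range[1], cfg$phi_range[2])
    a <- rep(cfg$a, n_prot)
    a[phi == 1] <- 1

    ## --- planted differential taxa: one affected group each
    n_da <- round(cfg$frac_da * cfg$n_taxa)
    da_idx <- if (n_da > 0) sort(sample(cfg$n_taxa, n_da)) else integer(0)
    effects <- data.frame(taxon = taxa[da_idx],
                          group = if (n_da > 0)
                            sample(cfg$groups, n_da, replace = TRUE)
                          else character(0),
                          log2fc = if (n_da > 0)
                            sample(c(-1, 1), n_da, replace = TRUE) *
                              stats::runif(n_da, cfg$log2fc_range[1],
                                           cfg$log2fc_range[2])
                          else numeric(0),
                          stringsAsFactors = FALSE)

    ## --- module membership (disjoint, from the non-DA pool first so
    ##     module structure is not confounded with planted shifts
    ##     whenever the pool is large enough)
    module_of <- rep(NA_integer_, cfg$n_taxa)
    pool <- setdiff(seq_len(cfg$n_taxa), da_idx)
    need <- cfg$n_modules * cfg$module_size
    if (length(pool) < need) pool <- seq_len(cfg$n_taxa)
    picked <- sample(pool, need)
    module_of[picked] <- rep(seq_len(cfg$n_modules), each = cfg$module_size)

    ## --- per-sample mean matrix: baseline x fold change x latent factor
    mu_mat <- matrix(mu, n_prot, n_samples,
                     dimnames = list(protein_ids, sample_ids))
    if (n_da > 0) {
      for (r in seq_len(nrow(effects))) {
        prot_rows <- taxon_of_protein == da_idx[r]
        cols <- phenotype == effects$group[r]
        mu_mat[prot_rows, cols] <- mu_mat[prot_rows, cols] *
          2^effects$log2fc[r]
      }
    }
    if (cfg$n_modules > 0 && cfg$module_rho > 0) {
      latent <- matrix(stats::rnorm(cfg$n_modules * n_samples),
                       cfg$n_modules, n_samples)
      rho <- cfg$module_rho
      for (m in seq_len(cfg$n_modules)) {
        fac <- exp(rho * latent[m, ] - rho^2 / 2)  # mean-one log-normal
        prot_rows <- !is.na(module_of[taxon_of_protein]) &
          module_of[taxon_of_protein] == m
        mu_mat[prot_rows, ] <- sweep(mu_mat[prot_rows, , drop = FALSE],
                                     2, fac, `*`)
      }
    }

    ## --- PT draws cell by protein row (vectorized over samples)
    counts <- matrix(0L, n_prot, n_samples,
                     dimnames = list(protein_ids, sample_ids))
    for (i in seq_len(n_prot)) {
      if (phi[i] == 1 || a[i] == 1) {
        counts[i, ] <- stats::rpois(n_samples, mu_mat[i, ])
      } else if (a[i] == 0) {
        sz <- mu_mat[i, ] / (phi[i] - 1)
        lam <- stats::rgamma(n_samples, shape = sz, scale = phi[i] - 1)
        counts[i, ] <- stats::rpois(n_samples, lam)
      } else {
        lam <- vapply(mu_mat[i, ], function(m)
          rinvgauss(1L, mean = m, shape = m^2 / (phi[i] - 1)), numeric(1))
        counts[i, ] <- stats::rpois(n_samples, lam)
      }
    }

    ## --- MNAR-light missingness: low-abundance proteins 2x more likely
    if (cfg$missing_rate > 0) {
      w <- ifelse(mu < stats::median(mu), 2, 1)
      p_cell <- pmin(cfg$missing_rate * w / mean(w), 1)
      drop <- matrix(stats::runif(n_prot * n_samples), n_prot, n_samples) <
        p_cell
      counts[drop] <- 0L
    }

    ## --- lineage truncation
    rank <- rep("species", n_prot)
    n_un <- round(cfg$frac_unassigned_species * n_prot)
    if (n_un > 0) {
      un <- sample(n_prot, n_un)
      rank[un] <- sample(c("genus", "family"), n_un, replace = TRUE,
                         prob = c(0.7, 0.3))
    }
    taxonomy <- data.frame(
      protein_id = protein_ids,
      family = family_of[taxon_of_protein],
      genus = genus_of[taxon_of_protein],
      species = ifelse(rank == "species", taxa[taxon_of_protein], NA),
      rank = rank,
      stringsAsFactors = FALSE)

    ## --- ground truth
    pairs <- utils::combn(cfg$groups, 2)
    da_taxa <- stats::setNames(
      lapply(seq_len(ncol(pairs)), function(k) {
        hit <- effects$group %in% pairs[, k]
        sort(unique(effects$taxon[hit]))
      }),
      paste(pairs[1, ], pairs[2, ], sep = "_vs_"))
    truth <- list(
      da_taxa = da_taxa,
      effects = effects,
      module_membership = stats::setNames(module_of, taxa),
      planted_params = data.frame(protein_id = protein_ids,
                                  taxon = taxa[taxon_of_protein],
                                  mu = mu, phi = phi, a = a,
                                  stringsAsFactors = FALSE))

    list(counts = spectral_count_matrix(counts, lengths, phenotype),
         taxonomy = taxonomy,
         truth = truth)
  })
}

#' Write a synthetic metaproteome to a directory
#'
#' Writes the generator output in the pipeline's on-disk interchange
#' formats: \code{counts.tsv} (protein rows; metadata columns
#' protein_length_aa and lineage, then one column per sample),
#' \code{samples.tsv} (sample id, phenotype), \code{taxonomy.tsv} and
#' \code{ground_truth.json}.
#'
#' @param sim result of \code{\link{generate_metaproteome}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_metaproteome <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sc <- sim$counts
  tx <- sim$taxonomy
  lineage <- ifelse(tx$rank == "species",
                    paste(tx$family, tx$genus, tx$species, sep = ";"),
                    ifelse(tx$rank == "genus",
                           paste(tx$family, tx$genus, sep = ";"),
                           tx$family))
  counts_df <- data.frame(protein_id = rownames(sc$counts),
                          protein_length_aa = unname(sc$lengths),
                          lineage = lineage,
                          sc$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  utils::write.table(counts_df, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = colnames(sc$counts),
                                phenotype = unname(sc$phenotype)),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tx, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}
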