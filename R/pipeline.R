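#' Pipeline configuration
#'
#' One object holding every stage parameter of the simulate ->
#' quantify -> differential-abundance -> network chain, with defaults
#' matching the pipeline's documented methodology.  Serializes
#' losslessly to JSON (\code{\link{save_config}} /
#' \code{\link{load_config}}).
#'
#' @param simulate generate inputs with the synthetic module (TRUE) or
#'   read them from \code{counts}/\code{samples}/\code{taxonomy}.
#' @param sim a \code{\link{synthetic_config}} used when
#'   \code{simulate} is TRUE.
#' @param counts,samples,taxonomy input TSV paths when \code{simulate}
#'   is FALSE.
#' @param min_count,min_samples low-count filter (see
#'   \code{\link{filter_low_counts}}).
#' @param trim_m,trim_a TMM trim fractions.
#' @param downshift,width imputation parameters in observed-SD units.
#' @param alpha_da FDR threshold of the DA tests.
#' @param B,alpha_ind,alpha_ens,n_null,bins BC3NET parameters.
#' @param percentile hub degree percentile.
#' @param seed global seed, fanned out to per-stage seeds.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulate = TRUE,
                            sim = synthetic_config(),
                            counts = NULL, samples = NULL,
                            taxonomy = NULL,
                            min_count = 5, min_samples = 2,
                            trim_m = 0.30, trim_a = 0.05,
                            downshift = 1.8, width = 0.3,
                            alpha_da = 0.05,
                            B = 100, alpha_ind = 0.05, alpha_ens = 0.05,
                            n_null = 1000, bins = NULL,
                            percentile = 95,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x <- x[!vapply(x, is.null, logical(1))]   # NULL-valued = defaults
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- if (!is.null(x$sim)) do.call(synthetic_config, x$sim)
         else synthetic_config()
  x$sim <- NULL
  do.call(pipeline_config, c(x, list(sim = sim)))
}

# deterministic fan-out of the global seed to stage seeds
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483647)
}

#' Read a protein spectral-count table and sample sheet
#'
#' Expects the interchange format written by
#' \code{\link{write_metaproteome}}: \code{counts.tsv} with columns
#' protein_id, protein_length_aa, lineage, then one column per sample;
#' \code{samples.tsv} with columns sample_id, phenotype.
#'
#' @param counts_path counts TSV path.
#' @param samples_path sample-sheet TSV path.
#' @return a \code{\link{spectral_count_matrix}}.
#' @export
read_spectral_counts <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "protein_length_aa", "lineage")
                %in% names(df)))
  meta <- c("protein_id", "protein_length_aa", "lineage")
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(m) <- df$protein_id
  smp <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "phenotype") %in% names(smp)))
  if (!setequal(smp$sample_id, colnames(m)))
    stop("sample sheet does not match count columns")
  pheno <- smp$phenotype[match(colnames(m), smp$sample_id)]
  spectral_count_matrix(m, df$protein_length_aa, pheno)
}

#' Read a protein taxonomy map
#'
#' @param path TSV with columns protein_id, family, genus, species
#'   (empty when unassigned) and rank.
#' @return data frame in the layout \code{\link{aggregate_to_taxa}}
#'   expects.
#' @export
read_taxonomy_map <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  stopifnot(all(c("protein_id", "family", "genus", "species", "rank")
                %in% names(tx)))
  tx
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full inference chain
#'
#' Executes simulate (optional) -> NSAF quantification -> taxon
#' aggregation, filtering and TMM -> six pairwise Poisson-Tweedie DA
#' comparisons -> BC3NET co-abundance network on the union of DA taxa
#' -> MST2 reduction, topology statistics, hub selection and hub
#' t-tests.  Every intermediate table is written to \code{out} as TSV
#' (networks additionally as GraphML), along with a structured stage
#' log and a manifest of file checksums; rerunning with the same
#' config and seed reproduces all outputs byte-identically.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out output directory (created).
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_entries <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    dt <- proc.time()[["elapsed"]] - t0
    log_entries[[length(log_entries) + 1L]] <<-
      list(stage = name, seconds = round(dt, 3))
    if (verbose) message(sprintf("[%s] done in %.1fs", name, dt))
    res
  }

  ## stage 1: inputs
  if (isTRUE(config$simulate)) {
    simcfg <- config$sim
    simcfg$seed <- stage_seed(config$seed, 1L)
    sim <- t_stage("simulate", {
      s <- generate_metaproteome(simcfg)
      write_metaproteome(s, file.path(out, "input"))
      s
    })
    sc <- sim$counts
    taxmap <- sim$taxonomy
  } else {
    sim <- NULL
    sc <- t_stage("read", read_spectral_counts(config$counts,
                                               config$samples))
    taxmap <- read_taxonomy_map(config$taxonomy)
  }

  ## stage 2: quantification
  quant <- t_stage("quantify", {
    nsaf <- compute_nsaf(sc)
    lg <- log2_transform_impute(nsaf, downshift = config$downshift,
                                width = config$width,
                                seed = stage_seed(config$seed, 2L))
    taxa <- aggregate_to_taxa(sc, taxmap)
    taxa_f <- filter_low_counts(taxa, min_count = config$min_count,
                                min_samples = config$min_samples)
    norm <- tmm_normalize(taxa_f, trim_m = config$trim_m,
                          trim_a = config$trim_a)
    taxa_f$norm_factors <- norm$factors
    .write_tsv(data.frame(protein_id = rownames(nsaf), nsaf,
                          check.names = FALSE),
               file.path(out, "nsaf.tsv"))
    .write_tsv(data.frame(protein_id = rownames(lg), lg,
                          check.names = FALSE),
               file.path(out, "log2_imputed.tsv"))
    .write_tsv(data.frame(taxon = rownames(taxa_f$counts),
                          rank = unname(taxa_f$rank), taxa_f$counts,
                          check.names = FALSE),
               file.path(out, "taxon_counts.tsv"))
    .write_tsv(data.frame(sample_id = names(norm$factors),
                          tmm_factor = unname(norm$factors)),
               file.path(out, "norm_factors.tsv"))
    list(nsaf = nsaf, log2 = lg, taxa = taxa_f, norm = norm)
  })

  ## stage 3: differential abundance
  da <- t_stage("da", {
    d <- run_pairwise_da(quant$taxa, quant$norm, alpha = config$alpha_da)
    .write_tsv(d$table, file.path(out, "da_results.tsv"))
    .write_tsv(data.frame(taxon = d$union_da),
               file.path(out, "union_da.tsv"))
    d
  })

  ## stage 4: network on the union of DA taxa
  net_res <- t_stage("network", {
    ids <- da$union_da
    if (length(ids) < 3) {
      warning("fewer than 3 DA taxa; network stage skipped")
      return(NULL)
    }
    abund <- rescaled_counts(quant$taxa)[ids, , drop = FALSE]
    net <- bc3net(log2(abund + 1),
                  B = config$B, alpha_ind = config$alpha_ind,
                  alpha_ens = config$alpha_ens, n_null = config$n_null,
                  bins = config$bins,
                  seed = stage_seed(config$seed, 4L))
    mst2 <- mst2_reduce(net)
    stats_full <- network_stats(net)
    stats_mst2 <- network_stats(mst2)
    hubs <- select_hubs(net, percentile = config$percentile)
    tt <- if (nrow(hubs$hubs) > 0)
      hub_ttest(quant$taxa, hubs$hubs$taxon, quant$norm) else NULL
    .write_tsv(mst2$edges, file.path(out, "network_edges.tsv"))
    igraph::write_graph(net$graph, file.path(out, "network.graphml"),
                        format = "graphml")
    igraph::write_graph(mst2$graph, file.path(out, "mst2.graphml"),
                        format = "graphml")
    jsonlite::write_json(list(network = stats_full, mst2 = stats_mst2,
                              hub_threshold = hubs$threshold),
                         file.path(out, "network_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_tsv(hubs$hubs, file.path(out, "hubs.tsv"))
    if (!is.null(tt)) .write_tsv(tt, file.path(out, "hub_ttests.tsv"))
    list(network = net, mst2 = mst2, stats = stats_full,
         stats_mst2 = stats_mst2, hubs = hubs, hub_ttests = tt)
  })

  ## manifest: config hash, seed, checksums of every written file
  save_config(config, file.path(out, "config.json"))
  files <- sort(setdiff(list.files(out, recursive = TRUE,
                                   full.names = FALSE),
                        "manifest.json"))
  sums <- tools::md5sum(file.path(out, files))
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(
                     file.path(out, "config.json"))),
                   files = as.list(stats::setNames(unname(sums), files)),
                   log = log_entries)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(sim = sim, quant = quant, da = da, network = net_res,
                 manifest = manifest))
}
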