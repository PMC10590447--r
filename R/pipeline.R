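# High-level pipeline commands. These are what the command-line wrapper
# (inst/scripts/aaebin-cli.R) calls; each writes its outputs to a run
# directory together with the effective configuration and seed, so a run
# can be reproduced from its own records.

#' Run the full binning pipeline
#'
#' Features -> adversarial autoencoder -> latent extraction -> clustering of
#' z, labels from y -> multi-split -> (optionally) de-replication of the
#' z and y bin sets. Writes cluster/bin tables, the loss history, a model
#' checkpoint and a run log to `outdir`.
#'
#' @param fasta Path to the contig catalogue FASTA.
#' @param depths Path to the depth TSV (jgi dialect).
#' @param outdir Output directory (created if missing).
#' @param config An [aae_config()].
#' @param separator Sample-prefix separator in contig ids.
#' @param min_length Minimum contig length (bp).
#' @param scorer Optional quality scorer (see [quality_scorer_truth()],
#'   [quality_scorer_report()]); when supplied, the z and y bin sets are
#'   de-replicated into `bins_dereplicated.tsv`.
#' @param min_completeness,max_contamination,overlap_threshold
#'   De-replication parameters.
#' @return Invisibly, a list with the bin tables, latent codes, fit and
#'   output paths.
#' @export
run_bin <- function(fasta, depths, outdir, config = aae_config(),
                    separator = "C", min_length = 2000, scorer = NULL,
                    min_completeness = 0.9, max_contamination = 0.05,
                    overlap_threshold = 0.75) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  contigs <- read_contigs(fasta, min_length)
  kernel <- tnf_kernel()
  tnf <- compute_tnf(contigs, kernel)
  depth_mat <- read_depths(depths, contigs$id)
  features <- assemble_features(contigs, tnf, depth_mat, separator)

  fit <- aae(features, config)
  latent <- latent_codes(fit, features)

  cl_z <- cluster_latent(latent$Z, lengths = latent$lengths)
  cl_y <- clusters_from_labels(latent)
  bins_z <- multi_split(cl_z, separator)
  bins_y <- multi_split(cl_y, separator)

  paths <- list(
    clusters_z = file.path(outdir, "clusters_z.tsv"),
    clusters_y = file.path(outdir, "clusters_y.tsv"),
    bins_z = file.path(outdir, "bins_z.tsv"),
    bins_y = file.path(outdir, "bins_y.tsv"),
    loss_history = file.path(outdir, "loss_history.tsv"),
    checkpoint = file.path(outdir, "model_checkpoint.rds"),
    log = file.path(outdir, "run_log.yaml")
  )
  write_clusters(cl_z, paths$clusters_z)
  write_clusters(cl_y, paths$clusters_y)
  write_clusters(bins_z, paths$bins_z)
  write_clusters(bins_y, paths$bins_y)
  readr::write_tsv(tidy(fit), paths$loss_history, progress = FALSE)
  write_checkpoint(fit, paths$checkpoint)

  derep <- NULL
  if (!is.null(scorer)) {
    derep <- dereplicate(list(bins_z, bins_y), scorer,
                         lengths = setNames(contigs$length, contigs$id),
                         min_completeness = min_completeness,
                         max_contamination = max_contamination,
                         overlap_threshold = overlap_threshold)
    paths$dereplicated <- file.path(outdir, "bins_dereplicated.tsv")
    write_clusters(derep, paths$dereplicated)
  }

  log <- list(
    package_version = as.character(utils::packageVersion("aaebin")),
    seed = config$seed,
    config = unclass(config),
    n_contigs = nrow(contigs),
    n_samples = features$n_samples,
    min_length = min_length,
    separator = separator,
    dereplicated = !is.null(scorer)
  )
  yaml::write_yaml(log, paths$log)

  invisible(list(bins_z = bins_z, bins_y = bins_y, dereplicated = derep,
                 clusters_z = cl_z, clusters_y = cl_y, latent = latent,
                 fit = fit, features = features, paths = paths))
}

#' De-replicate bin sets from cluster tables
#'
#' @param bin_tables Paths to bin TSVs (from [write_clusters()]) or bin
#'   tibbles; two or more sets merge into one de-replicated set (e.g.
#'   z + y + an external binner's bins).
#' @param scorer Quality scorer function.
#' @param lengths Named contig lengths (bp).
#' @param out Optional output TSV path.
#' @param ... Passed to [dereplicate()].
#' @return The de-replicated bin tibble.
#' @export
run_dereplicate <- function(bin_tables, scorer, lengths, out = NULL, ...) {
  sets <- lapply(bin_tables, function(b) {
    if (is.character(b)) {
      tab <- read_clusters(b)
      names(tab)[1] <- "bin"
      tab
    } else {
      tab <- as_tibble(b)
      names(tab)[1] <- "bin"
      tab
    }
  })
  derep <- dereplicate(sets, scorer, lengths, ...)
  if (!is.null(out)) write_clusters(derep, out)
  derep
}

#' Benchmark a bin table against ground truth
#'
#' @param bins Path to a bin TSV or a bin tibble.
#' @param truth Path to a truth TSV (`contig`, `genome`, `covered_bp`
#'   and optionally `genome_bp`) or the tibble itself.
#' @param taxonomy Optional taxonomy TSV path or tibble (`genome`,
#'   `species`, `genus`).
#' @param recall_threshold,precision_threshold Recovery thresholds.
#' @param out Optional directory for `metrics_<level>.tsv` files and a
#'   `summary.tsv` echoing the thresholds.
#' @return List with per-level recovered counts and metric tables.
#' @export
run_benchmark <- function(bins, truth, taxonomy = NULL,
                          recall_threshold = 0.9, precision_threshold = 0.95,
                          out = NULL) {
  if (is.character(bins)) {
    bins <- read_clusters(bins)
    names(bins)[1] <- "bin"
  }
  if (is.character(truth)) {
    truth <- readr::read_tsv(truth, show_col_types = FALSE, progress = FALSE)
  }
  if (is.character(taxonomy)) {
    taxonomy <- readr::read_tsv(taxonomy, show_col_types = FALSE,
                                progress = FALSE)
  }
  ref <- genome_reference(truth, taxonomy)
  levels <- if (is.null(taxonomy)) "strain" else c("strain", "species", "genus")
  res <- lapply(levels, function(lv) {
    count_recovered(bins, ref, recall_threshold, precision_threshold,
                    level = lv)
  })
  names(res) <- levels
  summary <- tibble(
    level = levels,
    recovered = unname(vapply(res, function(r) r$n, integer(1))),
    recall_threshold = recall_threshold,
    precision_threshold = precision_threshold
  )
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    for (lv in levels) {
      readr::write_tsv(res[[lv]]$clades,
                       file.path(out, paste0("metrics_", lv, ".tsv")),
                       progress = FALSE)
    }
    readr::write_tsv(summary, file.path(out, "summary.tsv"), progress = FALSE)
  }
  list(summary = summary, levels = res)
}

#' Generate a synthetic fixture directory
#'
#' @param dir Output directory.
#' @param ... Arguments to [synthetic_spec()].
#' @return The simulation result list (see [simulate_metagenome()]).
#' @export
run_simulate <- function(dir, ...) {
  spec <- synthetic_spec(...)
  simulate_metagenome(spec, dir = dir)
}
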