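# Ground-truth evaluation of bin sets: per-bin precision and recall against
# reference genomes, aggregation to higher clades, and counts of genomes
# recovered at quality thresholds.

#' Build a genome reference for benchmarking
#'
#' @param truth Tibble with columns `contig`, `genome`, `covered_bp` and
#'   optionally `genome_bp` (reference size per genome). Without
#'   `genome_bp`, a genome's size is the summed covered bp of its contigs.
#' @param taxonomy Optional tibble with columns `genome`, `species`,
#'   `genus`.
#' @return Object of class `genome_reference`.
#' @export
genome_reference <- function(truth, taxonomy = NULL) {
  stopifnot(all(c("contig", "genome", "covered_bp") %in% names(truth)))
  if (anyDuplicated(truth$contig)) {
    stop("truth table assigns some contig to multiple genomes", call. = FALSE)
  }
  sizes <- genome_sizes(truth)
  structure(
    list(truth = truth, genome_bp = sizes, taxonomy = taxonomy),
    class = "genome_reference"
  )
}

#' @export
print.genome_reference <- function(x, ...) {
  cat("<genome_reference> ", length(x$genome_bp), " genomes, ",
      nrow(x$truth), " contigs",
      if (!is.null(x$taxonomy)) " (+taxonomy)", "\n", sep = "")
  invisible(x)
}

#' Per-bin, per-genome precision and recall
#'
#' For bin B and genome G: precision is the bp of G covered by B's contigs
#' over the bp of any genome covered by B's contigs; recall is the bp of G
#' covered by B's contigs over the total bp of G.
#'
#' @param bins Tibble with columns `bin` and `contig`.
#' @param ref A [genome_reference()].
#' @return Tibble with columns `bin`, `genome`, `bp`, `precision`, `recall`.
#' @export
precision_recall <- function(bins, ref) {
  stopifnot(inherits(ref, "genome_reference"))
  per <- dplyr::inner_join(bins, ref$truth, by = "contig") |>
    dplyr::group_by(.data$bin, .data$genome) |>
    dplyr::summarise(bp = sum(.data$covered_bp), .groups = "drop") |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(precision = .data$bp / sum(.data$bp)) |>
    dplyr::ungroup() |>
    dplyr::mutate(recall = .data$bp / unname(ref$genome_bp[.data$genome]))
  dplyr::arrange(per, .data$bin, .data$genome)
}

#' Aggregate bin metrics to a taxonomic clade level
#'
#' For a clade L, a bin's recall is the maximum recall over the genomes in
#' L, and its precision is the sum of precisions over the genomes in L.
#'
#' @param metrics Output of [precision_recall()].
#' @param ref A [genome_reference()] with taxonomy (unless
#'   `level = "strain"`).
#' @param level `"strain"` (identity), `"species"` or `"genus"`.
#' @return Tibble with columns `bin`, `clade`, `precision`, `recall`.
#' @export
clade_metrics <- function(metrics, ref, level = c("strain", "species", "genus")) {
  level <- match.arg(level)
  if (level == "strain") {
    return(tibble(bin = metrics$bin, clade = metrics$genome,
                  precision = metrics$precision, recall = metrics$recall))
  }
  if (is.null(ref$taxonomy)) {
    stop("reference has no taxonomy; cannot aggregate to ", level,
         call. = FALSE)
  }
  joined <- dplyr::inner_join(metrics, ref$taxonomy, by = "genome")
  joined$clade <- joined[[level]]
  if (nrow(joined) == 0) {
    return(tibble(bin = character(), clade = character(),
                  precision = numeric(), recall = numeric()))
  }
  joined |>
    dplyr::group_by(.data$bin, .data$clade) |>
    dplyr::summarise(precision = sum(.data$precision),
                     recall = max(.data$recall), .groups = "drop") |>
    dplyr::arrange(.data$bin, .data$clade)
}

#' Count genomes or clades recovered at quality thresholds
#'
#' A genome (or clade) counts as recovered when any single bin reaches both
#' thresholds for it; each genome is counted once. By default thresholds
#' are inclusive (`recall >= 0.9`, `precision >= 0.95`); `strict = TRUE`
#' uses strict inequalities (the `> 0.9 / > 0.9` convention used for model
#' selection).
#'
#' @param bins Tibble with columns `bin` and `contig`.
#' @param ref A [genome_reference()].
#' @param recall_threshold,precision_threshold Recovery thresholds.
#' @param level Taxonomic level (see [clade_metrics()]).
#' @param strict Use strict inequalities.
#' @return List with `n` (count recovered) and `clades`, a per-clade table
#'   of the best bin (highest recall among those meeting the precision
#'   threshold, else highest recall overall) and a `recovered` flag.
#' @export
count_recovered <- function(bins, ref, recall_threshold = 0.9,
                            precision_threshold = 0.95,
                            level = "strain", strict = FALSE) {
  metrics <- precision_recall(bins, ref)
  cm <- clade_metrics(metrics, ref, level)
  cmp <- if (strict) `>` else `>=`
  if (nrow(cm) == 0) {
    return(list(n = 0L, clades = tibble(clade = character(),
                                        bin = character(),
                                        precision = numeric(),
                                        recall = numeric(),
                                        recovered = logical())))
  }
  cm$ok <- cmp(cm$recall, recall_threshold) &
    cmp(cm$precision, precision_threshold)
  best <- cm |>
    dplyr::group_by(.data$clade) |>
    dplyr::arrange(dplyr::desc(.data$ok), dplyr::desc(.data$recall),
                   dplyr::desc(.data$precision), .data$bin,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(clade = .data$clade, bin = .data$bin,
                     precision = .data$precision, recall = .data$recall,
                     recovered = .data$ok)
  list(n = sum(best$recovered), clades = best)
}
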