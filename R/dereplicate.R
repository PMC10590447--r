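# De-replication of competing bin sets over one contig catalogue. Bins from
# the z and y latent spaces (and optionally an external binner) cover the
# same contigs; the merge keeps, for each near-identical pair, the bin with
# the better quality score, and resolves remaining shared contigs by the
# largest quality-score drop.

#' Parse an external bin quality report
#'
#' Reads a tab-separated quality report with columns `Name`, `Completeness`
#' and `Contamination` (case-insensitive). Percent-scale values (any
#' completeness above 1.5) are divided by 100; fraction-scale values are
#' accepted as-is.
#'
#' @param tsv_path Path to the report.
#' @return Tibble with columns `bin`, `completeness`, `contamination`, on
#'   the fraction scale.
#' @export
parse_quality_report <- function(tsv_path) {
  tab <- readr::read_tsv(tsv_path, show_col_types = FALSE, progress = FALSE)
  lookup <- function(col) {
    i <- match(tolower(col), tolower(names(tab)))
    if (is.na(i)) stop("quality report missing column: ", col, call. = FALSE)
    tab[[i]]
  }
  out <- tibble(
    bin = as.character(lookup("Name")),
    completeness = as.numeric(lookup("Completeness")),
    contamination = as.numeric(lookup("Contamination"))
  )
  if (any(out$completeness > 1.5)) {
    out$completeness <- out$completeness / 100
    out$contamination <- out$contamination / 100
  }
  out
}

#' Quality scorer backed by a static report
#'
#' Wraps a parsed quality report into a scorer function usable by
#' [dereplicate()]. The external tool cannot be re-run on modified bins, so
#' a bin whose contigs are a subset of a reported bin is scored by
#' bp-proportional interpolation: completeness and contamination both scale
#' with the fraction of the original bin's bp retained.
#'
#' @param report Tibble from [parse_quality_report()].
#' @param bins The bin table (`bin`, `contig`) the report describes.
#' @param lengths Named numeric vector of contig lengths (bp).
#' @return A function `scorer(bins)` returning a tibble with `bin`,
#'   `completeness`, `contamination`.
#' @export
quality_scorer_report <- function(report, bins, lengths) {
  orig_bp <- bin_bp(bins, lengths)
  rep_idx <- setNames(seq_len(nrow(report)), report$bin)
  function(query) {
    bp <- bin_bp(query, lengths)
    i <- rep_idx[names(bp)]
    if (anyNA(i)) {
      stop("quality report missing bin(s): ",
           paste(head(names(bp)[is.na(i)], 5), collapse = ", "),
           call. = FALSE)
    }
    frac <- unname(bp / orig_bp[names(bp)])
    tibble(
      bin = names(bp),
      completeness = unname(report$completeness[i]) * frac,
      contamination = unname(report$contamination[i]) * frac
    )
  }
}

#' Quality scorer from ground truth
#'
#' For synthetic data with a known contig-to-genome map: a bin's dominant
#' genome is the genome with the most bp in the bin; completeness is the
#' dominant genome's bp in the bin over that genome's reference bp, and
#' contamination is the remaining (foreign) bp over the same denominator.
#'
#' @param truth Tibble with columns `contig`, `genome`, `covered_bp` and
#'   (optionally) `genome_bp`; without `genome_bp` the reference size of a
#'   genome is the summed covered bp of its contigs.
#' @return A function `scorer(bins)` returning a tibble with `bin`,
#'   `completeness`, `contamination`.
#' @export
quality_scorer_truth <- function(truth) {
  genome_bp <- genome_sizes(truth)
  contig_genome <- setNames(truth$genome, truth$contig)
  contig_bp <- setNames(truth$covered_bp, truth$contig)
  function(query) {
    if (nrow(query) == 0) stop("empty bin set", call. = FALSE)
    unknown <- setdiff(query$contig, names(contig_genome))
    if (length(unknown) > 0) {
      stop("contig(s) absent from truth: ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    per <- query |>
      dplyr::mutate(genome = contig_genome[.data$contig],
                    bp = contig_bp[.data$contig]) |>
      dplyr::group_by(.data$bin, .data$genome) |>
      dplyr::summarise(bp = sum(.data$bp), .groups = "drop_last") |>
      dplyr::arrange(dplyr::desc(.data$bp), .data$genome, .by_group = TRUE) |>
      dplyr::summarise(
        dominant = dplyr::first(.data$genome),
        dom_bp = dplyr::first(.data$bp),
        other_bp = sum(.data$bp) - dplyr::first(.data$bp),
        .groups = "drop"
      )
    ref_bp <- unname(genome_bp[per$dominant])
    tibble(
      bin = per$bin,
      completeness = per$dom_bp / ref_bp,
      contamination = per$other_bp / ref_bp
    )
  }
}

genome_sizes <- function(truth) {
  if ("genome_bp" %in% names(truth)) {
    sizes <- truth |> dplyr::distinct(.data$genome, .data$genome_bp)
    if (anyDuplicated(sizes$genome)) {
      stop("inconsistent genome_bp values in truth table", call. = FALSE)
    }
    setNames(sizes$genome_bp, sizes$genome)
  } else {
    agg <- truth |>
      dplyr::group_by(.data$genome) |>
      dplyr::summarise(bp = sum(.data$covered_bp))
    setNames(agg$bp, agg$genome)
  }
}

bin_bp <- function(bins, lengths) {
  missing_len <- setdiff(bins$contig, names(lengths))
  if (length(missing_len) > 0) {
    stop("missing contig length(s): ",
         paste(head(missing_len, 5), collapse = ", "), call. = FALSE)
  }
  vapply(split(bins$contig, bins$bin),
         function(ids) sum(lengths[ids]), numeric(1))
}

#' Score bins from a quality report
#'
#' Attaches completeness/contamination and the quality score
#' `score = completeness - 5 * contamination` to each bin.
#'
#' @param bins Tibble with columns `bin` and `contig`.
#' @param quality Tibble with `bin`, `completeness`, `contamination` (from a
#'   scorer or [parse_quality_report()]); every bin must have an entry.
#' @param lengths Optional named contig lengths to include `total_bp`.
#' @return Tibble with one row per bin: `bin`, `n_contigs`, `total_bp` (if
#'   lengths given), `completeness`, `contamination`, `score`.
#' @export
score_bins <- function(bins, quality, lengths = NULL) {
  sizes <- bins |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_contigs = dplyr::n())
  if (!is.null(lengths)) {
    bp <- bin_bp(bins, lengths)
    sizes$total_bp <- as.numeric(bp[sizes$bin])
  }
  miss <- setdiff(sizes$bin, quality$bin)
  if (length(miss) > 0) {
    stop("no quality entry for bin(s): ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::inner_join(sizes, quality, by = "bin")
  out$score <- out$completeness - 5 * out$contamination
  dplyr::arrange(out, .data$bin)
}

#' Filter near-complete bins
#'
#' Keeps bins with completeness strictly above `min_completeness` and
#' contamination strictly below `max_contamination` (both boundaries
#' excluded).
#'
#' @param scored Tibble with `completeness` and `contamination` columns.
#' @param min_completeness,max_contamination NC thresholds (defaults 0.9 and
#'   0.05).
#' @return The qualifying rows.
#' @export
filter_nc <- function(scored, min_completeness = 0.9,
                      max_contamination = 0.05) {
  dplyr::filter(scored, .data$completeness > min_completeness,
                .data$contamination < max_contamination)
}

#' Find near-identical bin pairs
#'
#' Two bins are near-identical when at least `overlap_threshold` of the
#' smaller bin's nucleotide content (total bp, shared-contig identity) is
#' present in the larger bin.
#'
#' @param bins Tibble with `bin` and `contig` columns (one or several bin
#'   sets bound together).
#' @param lengths Named numeric vector of contig lengths.
#' @param overlap_threshold Minimum shared fraction of the smaller bin.
#' @return Tibble with columns `bin1`, `bin2` (lexicographic order),
#'   `shared_bp`, `overlap`, sorted by descending overlap then names.
#' @export
find_near_identical_pairs <- function(bins, lengths, overlap_threshold = 0.75) {
  bp <- bin_bp(bins, lengths)
  shared <- dplyr::inner_join(bins, bins, by = "contig",
                              relationship = "many-to-many",
                              suffix = c("1", "2")) |>
    dplyr::filter(.data$bin1 < .data$bin2) |>
    dplyr::mutate(len = as.numeric(lengths[.data$contig])) |>
    dplyr::group_by(.data$bin1, .data$bin2) |>
    dplyr::summarise(shared_bp = sum(.data$len), .groups = "drop")
  if (nrow(shared) == 0) {
    return(tibble(bin1 = character(), bin2 = character(),
                  shared_bp = numeric(), overlap = numeric()))
  }
  shared$overlap <- shared$shared_bp /
    unname(pmin(bp[shared$bin1], bp[shared$bin2]))
  out <- dplyr::filter(shared, .data$overlap >= overlap_threshold)
  dplyr::arrange(out, dplyr::desc(.data$overlap), .data$bin1, .data$bin2)
}

#' De-replicate bin sets into one duplicate-free set
#'
#' Merges one or more bin sets over the same contig catalogue:
#' 1. score all bins (`score = completeness - 5 * contamination`) and drop
#'    bins that are not near-complete (unless `keep_subnc`);
#' 2. for every near-identical pair (>= `overlap_threshold` of the smaller
#'    bin's bp shared), remove the lower-scoring member;
#' 3. for each contig still present in two or more bins (in lexicographic
#'    contig order), re-score each owner without the contig and keep the
#'    contig only in the owner whose score would drop the most.
#'
#' Ties in step 2 keep the bin with more total bp, then the
#' lexicographically earlier name; ties in step 3 prefer the owner with the
#' higher current score, then the lexicographically earlier name. The final
#' set never contains a contig twice (asserted), never gains bins, and is
#' invariant to the order in which the input bin sets are given.
#'
#' @param bin_sets A single bin tibble (`bin`, `contig`) or a list of them;
#'   bin names must be unique across sets.
#' @param scorer A quality scorer function (see [quality_scorer_truth()] and
#'   [quality_scorer_report()]).
#' @param lengths Named numeric vector of contig lengths (bp).
#' @param min_completeness,max_contamination NC thresholds (strict).
#' @param overlap_threshold Near-identical pair threshold.
#' @param keep_subnc Keep bins below the NC thresholds instead of dropping
#'   them (for inspection).
#' @return Tibble with columns `bin` and `contig`; attribute `derep_log`
#'   holds the removed pairs and contig reassignments.
#' @export
dereplicate <- function(bin_sets, scorer, lengths,
                        min_completeness = 0.9, max_contamination = 0.05,
                        overlap_threshold = 0.75, keep_subnc = FALSE) {
  if (is.data.frame(bin_sets)) bin_sets <- list(bin_sets)
  bins <- dplyr::bind_rows(bin_sets)[, c("bin", "contig")]
  bins <- dplyr::distinct(bins)
  set_sizes <- vapply(bin_sets, function(b) length(unique(b$bin)), 1L)
  if (length(unique(bins$bin)) != sum(set_sizes)) {
    stop("bin names must be unique across bin sets", call. = FALSE)
  }
  if (nrow(bins) == 0) {
    return(structure(bins, derep_log = list()))
  }

  quality <- scorer(bins)
  scored <- score_bins(bins, quality, lengths)
  if (!keep_subnc) {
    scored <- filter_nc(scored, min_completeness, max_contamination)
  }
  bins <- dplyr::filter(bins, .data$bin %in% scored$bin)
  score_of <- setNames(scored$score, scored$bin)
  bp_of <- setNames(scored$total_bp, scored$bin)

  # Step 2: near-identical pair removal, by descending overlap. Removal
  # deletes whole bins and leaves other bins' overlaps unchanged, so a
  # single ordered pass is sufficient.
  pairs <- find_near_identical_pairs(bins, lengths, overlap_threshold)
  removed <- character()
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      b1 <- pairs$bin1[i]; b2 <- pairs$bin2[i]
      if (b1 %in% removed || b2 %in% removed) next
      removed <- c(removed, worse_bin(b1, b2, score_of, bp_of))
    }
    bins <- dplyr::filter(bins, !(.data$bin %in% removed))
  }

  # Step 3: largest-score-drop contig reassignment.
  membership <- split(bins$bin, bins$contig)
  n_owners <- vapply(membership, length, 1L)
  shared_contigs <- sort(names(membership)[n_owners > 1])
  contents <- split(bins$contig, bins$bin)
  cur_score <- score_of[names(contents)]
  reassign_log <- list()
  for (cg in shared_contigs) {
    owners <- sort(intersect(membership[[cg]], names(contents)))
    owners <- owners[vapply(contents[owners], function(x) cg %in% x, TRUE)]
    if (length(owners) < 2) next
    drops <- vapply(owners, function(b) {
      kept <- setdiff(contents[[b]], cg)
      if (length(kept) == 0) return(unname(cur_score[b]))
      q <- scorer(tibble(bin = b, contig = kept))
      unname(cur_score[b] - (q$completeness - 5 * q$contamination))
    }, numeric(1))
    ord <- order(-drops, -cur_score[owners], owners)
    winner <- owners[ord[1]]
    losers <- setdiff(owners, winner)
    for (b in losers) {
      contents[[b]] <- setdiff(contents[[b]], cg)
      if (length(contents[[b]]) == 0) {
        contents[[b]] <- NULL
      } else {
        q <- scorer(tibble(bin = b, contig = contents[[b]]))
        cur_score[b] <- q$completeness - 5 * q$contamination
      }
    }
    reassign_log[[cg]] <- tibble(contig = cg, kept_in = winner,
                                 removed_from = paste(losers, collapse = ","))
  }

  if (length(contents) == 0) {
    out <- tibble(bin = character(), contig = character())
  } else {
    out <- tibble(
      bin = rep(names(contents), vapply(contents, length, 1L)),
      contig = unlist(contents, use.names = FALSE)
    )
    out <- dplyr::arrange(out, .data$bin, .data$contig)
  }
  stopifnot(!anyDuplicated(out$contig))
  structure(out, derep_log = list(
    removed_bins = removed,
    pairs = pairs,
    reassignments = dplyr::bind_rows(reassign_log)
  ))
}

# The member of a near-identical pair to remove: lower score loses; score
# ties keep the larger bin (bp), then the lexicographically earlier name.
worse_bin <- function(b1, b2, score_of, bp_of) {
  s1 <- score_of[b1]; s2 <- score_of[b2]
  if (s1 != s2) return(if (s1 < s2) b1 else b2)
  p1 <- bp_of[b1]; p2 <- bp_of[b2]
  if (p1 != p2) return(if (p1 < p2) b1 else b2)
  if (b1 < b2) b2 else b1
}
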