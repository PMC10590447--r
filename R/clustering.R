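# Cluster extraction from the two latent spaces. The continuous z space is
# clustered with an iterative medoid algorithm on cosine distance; the
# categorical y space is read directly as cluster labels. Catalogue-level
# clusters are then split by sample of origin (multi-split binning).

#' Iterative medoid clustering of the continuous latent space
#'
#' Latent rows are centred per dimension and length-normalised, and
#' clustered on cosine distance `d = (1 - cos) / 2`. Repeatedly: pick the
#' longest unclustered contig as seed; wander to a local medoid by moving to
#' the neighbour (within `neighbour_window`) minimising the summed distance
#' to all neighbours; set the cluster radius at the first density valley of
#' the medoid's distance histogram (fallback radius if no valley); emit all
#' unclustered points within the radius and mark them clustered. The result
#' is a partition. The procedure uses no randomness: ties break by
#' lexicographic contig id, so output is reproducible.
#'
#' @param Z Numeric matrix of latent codes, contig-id rownames.
#' @param contig_ids Contig ids (default rownames of `Z`).
#' @param lengths Optional numeric vector of contig lengths (bp), used for
#'   seed ordering (descending); equal lengths fall back to lexicographic id.
#' @param neighbour_window Cosine-distance window for medoid wandering.
#' @param max_steps Maximum medoid-wander steps.
#' @param bin_width,hist_max Histogram bin width and range for the density
#'   valley search.
#' @param valley_ratio A bin is a valley only if its count falls below this
#'   fraction of the preceding peak.
#' @param fallback_radius Radius used when no valley is found.
#' @return A tibble with columns `cluster` (ids `z1`, `z2`, ...) and
#'   `contig`, forming a partition of the input contigs; attribute
#'   `origin = "z"`.
#' @export
cluster_latent <- function(Z, contig_ids = rownames(Z), lengths = NULL,
                           neighbour_window = 0.05, max_steps = 25,
                           bin_width = 0.005, hist_max = 0.3,
                           valley_ratio = 0.6, fallback_radius = 0.09) {
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = 1)
  n <- nrow(Z)
  if (n == 0) {
    return(structure(tibble(cluster = character(), contig = character()),
                     origin = "z"))
  }
  if (is.null(contig_ids)) contig_ids <- as.character(seq_len(n))
  if (!all(is.finite(Z))) stop("non-finite latent values", call. = FALSE)

  # Centre and length-normalise so cosine distance is meaningful.
  U <- add_row(Z, -colMeans(Z))
  norms <- sqrt(rowSums(U^2))
  U <- U / ifelse(norms > 1e-12, norms, 1)
  # Degenerate (zero-norm) codes carry no direction; map them to a common
  # unit vector so mutually identical points cluster together.
  zero <- norms <= 1e-12
  if (any(zero)) {
    U[zero, ] <- 0
    U[zero, 1] <- 1
  }

  if (is.null(lengths)) lengths <- rep(1, n)
  seed_order <- order(-lengths, contig_ids)

  unclustered <- rep(TRUE, n)
  assignment <- integer(n)
  k <- 0L
  n_bins <- ceiling(hist_max / bin_width)

  for (seed in seed_order) {
    if (!unclustered[seed]) next
    k <- k + 1L
    avail <- which(unclustered)
    current <- seed

    # Medoid wandering.
    visited <- current
    for (step in seq_len(max_steps)) {
      d_all <- (1 - drop(U[avail, , drop = FALSE] %*% U[current, ])) / 2
      nb <- avail[d_all <= neighbour_window]
      if (length(nb) < 2) break
      Un <- U[nb, , drop = FALSE]
      sums <- rowSums((1 - tcrossprod(Un)) / 2)
      best <- min(sums)
      cand <- nb[sums <= best + 1e-12]
      cand <- cand[order(contig_ids[cand])][1]
      if (cand == current || cand %in% visited) break
      current <- cand
      visited <- c(visited, cand)
    }

    d_all <- (1 - drop(U[avail, , drop = FALSE] %*% U[current, ])) / 2
    radius <- valley_radius(d_all, bin_width, n_bins, valley_ratio,
                            fallback_radius)
    members <- avail[d_all <= radius]
    if (length(members) == 0) members <- current
    assignment[members] <- k
    unclustered[members] <- FALSE
  }

  out <- tibble(cluster = paste0("z", assignment), contig = contig_ids)
  structure(dplyr::arrange(out, .data$cluster, .data$contig), origin = "z")
}

# First density valley of a distance histogram: counts are smoothed with a
# short moving average (raw counts per 0.005 bin are too sparse to carry a
# density estimate), then walking bins left to right, a bin is the valley
# if its smoothed density drops below valley_ratio of the running peak and
# does not exceed the next bin's density. Returns the valley bin's
# midpoint, or fallback when no valley exists.
valley_radius <- function(d, bin_width, n_bins, valley_ratio, fallback,
                          smooth_window = 5) {
  bin <- pmin(pmax(ceiling(d / bin_width), 1), n_bins + 1)
  counts <- tabulate(bin[bin <= n_bins], nbins = n_bins)
  half <- smooth_window %/% 2
  dens <- vapply(seq_len(n_bins), function(i) {
    mean(counts[max(1, i - half):min(n_bins, i + half)])
  }, numeric(1))
  peak <- dens[1]
  for (i in 2:n_bins) {
    if (dens[i] > peak) {
      peak <- dens[i]
    } else if (peak > 0 && dens[i] < valley_ratio * peak &&
               (i == n_bins || dens[i] <= dens[i + 1])) {
      return((i - 0.5) * bin_width)
    }
  }
  fallback
}

#' Clusters read directly from the categorical latent space
#'
#' Groups contigs by identical categorical label; empty categories are
#' absent.
#'
#' @param y Integer labels (e.g. from [latent_codes()]), named by contig,
#'   or an `aae_latent` object.
#' @param contig_ids Contig ids (default names of `y`).
#' @return Tibble with columns `cluster` (ids `y<label>`) and `contig`;
#'   attribute `origin = "y"`.
#' @export
clusters_from_labels <- function(y, contig_ids = names(y)) {
  if (inherits(y, "aae_latent")) {
    contig_ids <- y$contig_ids
    y <- y$y
  }
  stopifnot(length(y) == length(contig_ids))
  out <- tibble(cluster = paste0("y", as.integer(y)), contig = contig_ids)
  structure(dplyr::arrange(out, .data$cluster, .data$contig), origin = "y")
}

#' Split catalogue-level clusters into per-sample bins
#'
#' Multi-split binning: every cluster is partitioned by the sample prefix of
#' its contig ids, so each resulting bin contains contigs from a single
#' sample. Bin names are `<cluster><separator><sample>`.
#'
#' @param clusters Tibble with columns `cluster` and `contig`.
#' @param separator Sample-prefix separator in contig ids.
#' @return Tibble with columns `bin`, `contig` and `sample`; the union of
#'   bins equals the union of input clusters.
#' @export
multi_split <- function(clusters, separator = "C") {
  samples <- sample_of_contig(clusters$contig, separator)
  out <- tibble(
    bin = paste0(clusters$cluster, separator, samples),
    contig = clusters$contig,
    sample = samples
  )
  dplyr::arrange(out, .data$bin, .data$contig)
}

#' Write / read cluster and bin tables
#'
#' Two-column tab-separated files (name, contig id), sorted and
#' deterministic. Names or ids containing tabs or newlines are rejected.
#'
#' @param x Tibble whose first column is the cluster/bin name (`cluster` or
#'   `bin`) and which has a `contig` column.
#' @param path Destination file.
#' @return `write_clusters` returns `path` invisibly; `read_clusters`
#'   returns a tibble with the original two columns.
#' @export
write_clusters <- function(x, path) {
  name_col <- intersect(c("bin", "cluster"), names(x))[1]
  if (is.na(name_col)) stop("no 'bin' or 'cluster' column", call. = FALSE)
  out <- tibble(!!name_col := x[[name_col]], contig = x$contig)
  if (any(grepl("[\t\n]", unlist(out)))) {
    stop("names containing tab or newline cannot be written", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data[[name_col]], .data$contig)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
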