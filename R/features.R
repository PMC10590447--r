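# Contig feature extraction: tetranucleotide composition and multi-sample
# co-abundance, assembled into the model input matrix.

#' Read a contig catalogue from FASTA
#'
#' Reads a multi-sample contig catalogue and drops contigs shorter than
#' `min_length`. The contig id is the first whitespace-delimited token of
#' each FASTA header and must be unique within the catalogue.
#'
#' @param fasta_path Path to a FASTA file.
#' @param min_length Minimum contig length in bp; shorter records are
#'   discarded. The conventional catalogue cutoff is 2000 bp.
#' @return A tibble with columns `id`, `sequence` and `length`, in order of
#'   appearance.
#' @export
read_contigs <- function(fasta_path, min_length = 2000) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) {
      stop("malformed FASTA '", fasta_path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate contig id(s) in FASTA: ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  keep <- Biostrings::width(seqs) >= min_length
  message(sum(keep), " of ", length(seqs), " contigs kept at min_length ",
          min_length)
  if (!any(keep)) {
    stop("no contigs of length >= ", min_length, " in ", fasta_path,
         call. = FALSE)
  }
  tibble(
    id = ids[keep],
    sequence = unname(as.character(seqs[keep])),
    length = Biostrings::width(seqs)[keep]
  )
}

#' Raw tetramer frequencies per contig
#'
#' Counts overlapping 4-mers on the given strand; windows containing any
#' non-ACGT symbol are skipped. Counts are normalised to frequencies summing
#' to one per contig. Contigs with no countable window (shorter than 4 bp or
#' fully ambiguous) carry no compositional information and receive the
#' uniform frequency vector, which projects to zero under [tnf_kernel()].
#'
#' @param contigs A tibble with columns `id` and `sequence`, as returned by
#'   [read_contigs()].
#' @return An `n_contigs` x 256 matrix of frequencies, rows named by contig
#'   id, columns by tetramer.
#' @export
tetramer_frequencies <- function(contigs) {
  stopifnot(nrow(contigs) >= 1)
  seqs <- Biostrings::DNAStringSet(toupper(contigs$sequence))
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = 4, step = 1)
  totals <- rowSums(counts)
  freq <- counts / ifelse(totals > 0, totals, 1)
  freq[totals == 0, ] <- 1 / 256
  rownames(freq) <- contigs$id
  freq
}

#' Projected tetranucleotide composition
#'
#' Projects raw tetramer frequencies into the 103-dimensional strand-
#' insensitive subspace and (by default) z-scales each projected dimension
#' across contigs so that every composition feature contributes on a common
#' scale. Columns with zero variance are centred and left at zero.
#'
#' @param contigs Tibble of contigs (see [read_contigs()]).
#' @param kernel Projection kernel from [tnf_kernel()].
#' @param scale If `TRUE` (default), z-scale each of the 103 dimensions
#'   across contigs; set `FALSE` to obtain the bare projection, which is
#'   exactly invariant under reverse complementation of the input.
#' @return An `n_contigs` x 103 numeric matrix with contig id rownames.
#' @export
compute_tnf <- function(contigs, kernel = tnf_kernel(), scale = TRUE) {
  freq <- tetramer_frequencies(contigs)
  proj <- freq %*% kernel
  if (scale) proj <- zscale_columns(proj)
  rownames(proj) <- contigs$id
  proj
}

zscale_columns <- function(x) {
  if (nrow(x) < 2) {
    return(x - matrix(colMeans(x), nrow(x), ncol(x), byrow = TRUE))
  }
  m <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  t((t(x) - m) / s)
}

#' Read a per-contig, per-sample depth matrix
#'
#' Parses the tab-separated dialect of `jgi_summarize_bam_contig_depths`:
#' header columns `contigName`, `contigLen`, `totalAvgDepth`, then one depth
#' column per sample, optionally interleaved with `-var` variance columns
#' (ignored). Rows are reordered to match `contig_ids`.
#'
#' @param tsv_path Path to the depth TSV.
#' @param contig_ids Contig ids, in catalogue order, that the returned rows
#'   must align to. Every id must be present in the file.
#' @return An `n_contigs` x `n_samples` numeric matrix of raw depths with
#'   contig-id rownames and sample colnames.
#' @export
read_depths <- function(tsv_path, contig_ids) {
  tab <- readr::read_tsv(tsv_path, show_col_types = FALSE, progress = FALSE)
  required <- c("contigName", "contigLen", "totalAvgDepth")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("depth file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  depth_cols <- setdiff(names(tab), required)
  depth_cols <- depth_cols[!endsWith(depth_cols, "-var")]
  if (length(depth_cols) == 0) {
    stop("depth file has no per-sample depth columns", call. = FALSE)
  }
  idx <- match(contig_ids, tab$contigName)
  if (anyNA(idx)) {
    missing_ids <- contig_ids[is.na(idx)]
    stop("contig(s) absent from depth file: ",
         paste(head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) ", ..." else "", call. = FALSE)
  }
  raw <- as.matrix(tab[idx, depth_cols])
  mode(raw) <- "double"
  if (anyNA(raw) || any(raw < 0)) {
    stop("depth matrix contains missing or negative values", call. = FALSE)
  }
  dimnames(raw) <- list(contig_ids, depth_cols)
  raw
}

#' Normalise depths across samples per contig
#'
#' Each contig's depth row is scaled to sum to one, turning depths into the
#' distribution of a random mapped read over samples. Contigs with zero
#' depth everywhere carry no abundance information and receive the uniform
#' row `1/S`.
#'
#' @param raw Nonnegative `n_contigs` x `n_samples` matrix.
#' @return Matrix of the same shape with rows summing to one.
#' @export
normalize_abundances <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("depths must be nonnegative", call. = FALSE)
  totals <- rowSums(raw)
  out <- raw / ifelse(totals > 0, totals, 1)
  out[totals == 0, ] <- 1 / ncol(raw)
  out
}

#' Split a contig id into its sample prefix
#'
#' Contig ids follow the multi-sample convention
#' `<sample><separator><name>`; the sample of origin is everything before
#' the first occurrence of the separator.
#'
#' @param ids Character vector of contig ids.
#' @param separator Single string separating sample prefix from contig name
#'   (default `"C"`).
#' @return Character vector of sample prefixes.
#' @export
sample_of_contig <- function(ids, separator = "C") {
  pos <- regexpr(separator, ids, fixed = TRUE)
  bad <- ids[pos <= 1]
  if (length(bad) > 0) {
    stop("contig id(s) lack a non-empty sample prefix before separator '",
         separator, "': ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  substr(ids, 1, pos - 1)
}

#' Assemble the model input matrix
#'
#' Concatenates z-scaled composition and normalised co-abundance per contig
#' into the `[TNF, Coab]` input vector of length `103 + S`, and derives each
#' contig's sample of origin from its id.
#'
#' @param contigs Tibble of contigs (see [read_contigs()]).
#' @param tnf `n_contigs` x 103 composition matrix from [compute_tnf()].
#' @param abundance `n_contigs` x `S` matrix of raw or normalised depths;
#'   rows are normalised to sum to one if they do not already.
#' @param separator Sample-prefix separator in contig ids.
#' @return An object of class `aae_features`: a list with the input matrix
#'   `X`, `contig_ids`, `lengths`, `samples` (sample of origin per contig)
#'   and `n_samples`.
#' @export
assemble_features <- function(contigs, tnf, abundance, separator = "C") {
  stopifnot(nrow(contigs) == nrow(tnf), nrow(contigs) == nrow(abundance))
  ab <- normalize_abundances(abundance)
  samples <- sample_of_contig(contigs$id, separator)
  X <- cbind(tnf, ab)
  dimnames(X) <- list(contigs$id, NULL)
  structure(
    list(
      X = X,
      contig_ids = contigs$id,
      lengths = setNames(contigs$length, contigs$id),
      samples = samples,
      n_samples = ncol(ab),
      n_tnf = ncol(tnf),
      separator = separator
    ),
    class = "aae_features"
  )
}

#' @export
print.aae_features <- function(x, ...) {
  cat("<aae_features> ", length(x$contig_ids), " contigs, ",
      x$n_samples, " samples, input dim ", ncol(x$X), "\n", sep = "")
  invisible(x)
}
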