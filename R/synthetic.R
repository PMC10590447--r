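# Desk-scale synthetic multi-sample metagenomes with exact ground truth.
# The generator reproduces the statistical structure the binning model
# exploits: genome-specific tetranucleotide bias (a distinct order-k Markov
# composition per genome), log-normal per-sample genome abundances shared by
# all contigs of a genome (the co-abundance signal), and multiplicative
# depth noise. Each genome is fragmented independently in every sample,
# tiling the full genome, which mirrors the per-sample assemblies that a
# multi-sample catalogue concatenates and which multi-split binning
# presumes.

#' Specification of a synthetic metagenome
#'
#' @param n_genomes Number of genomes.
#' @param genome_bp Genome length in bp.
#' @param n_samples Number of samples.
#' @param contigs_per_genome Target fragments per genome per sample; sets
#'   the default fragment length range.
#' @param frag_min,frag_max Fragment length range in bp (defaults 0.6x and
#'   1.4x of `genome_bp / contigs_per_genome`).
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   per-genome, per-sample abundance draws.
#' @param depth_dispersion Dispersion of the multiplicative gamma depth
#'   noise (mean 1, variance = dispersion); 0 disables noise.
#' @param markov_order Order of the per-genome Markov composition model
#'   (0-3).
#' @param seed Integer seed; all generator output is reproducible given the
#'   spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genomes = 10, genome_bp = 50000, n_samples = 8,
                           contigs_per_genome = 10, frag_min = NULL,
                           frag_max = NULL, abundance_meanlog = 1,
                           abundance_sdlog = 1, depth_dispersion = 0.05,
                           markov_order = 3, seed = 1) {
  stopifnot(n_genomes >= 1, genome_bp >= 100, n_samples >= 1,
            contigs_per_genome >= 1, depth_dispersion >= 0,
            markov_order %in% 0:3, abundance_sdlog >= 0)
  mean_frag <- genome_bp / contigs_per_genome
  if (is.null(frag_min)) frag_min <- max(4, floor(0.6 * mean_frag))
  if (is.null(frag_max)) frag_max <- ceiling(1.4 * mean_frag)
  stopifnot(frag_min >= 4, frag_max >= frag_min, frag_max <= genome_bp)
  structure(
    list(n_genomes = as.integer(n_genomes), genome_bp = as.integer(genome_bp),
         n_samples = as.integer(n_samples),
         contigs_per_genome = as.integer(contigs_per_genome),
         frag_min = as.integer(frag_min), frag_max = as.integer(frag_max),
         abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog,
         depth_dispersion = depth_dispersion,
         markov_order = as.integer(markov_order), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_genomes, " genomes x ", x$genome_bp,
      " bp, ", x$n_samples, " samples, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate genome sequences with genome-specific composition
#'
#' Each genome gets its own order-`markov_order` transition table with rows
#' drawn from a flat Dirichlet, giving genomes distinct tetranucleotide
#' signatures.
#'
#' @param spec A [synthetic_spec()].
#' @return Named character vector of genome sequences (`G01`, `G02`, ...).
#' @export
generate_genomes <- function(spec) {
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  k <- spec$markov_order
  n_ctx <- 4L^k
  genomes <- character(spec$n_genomes)
  for (g in seq_len(spec$n_genomes)) {
    # Dirichlet(1) rows via normalised gamma draws.
    trans <- matrix(stats::rgamma(n_ctx * 4, shape = 1), n_ctx, 4)
    trans <- trans / rowSums(trans)
    cum <- t(apply(trans, 1, cumsum))
    seq_i <- integer(spec$genome_bp)
    seq_i[seq_len(max(k, 1))] <- sample.int(4, max(k, 1), replace = TRUE)
    ctx <- 0L
    if (k > 0) {
      for (j in seq_len(k)) ctx <- ctx * 4L + (seq_i[j] - 1L)
    }
    u <- runif(spec$genome_bp)
    start <- max(k, 1) + 1
    if (k == 0) {
      seq_i <- findInterval(u, cum[1, ]) + 1L
    } else {
      for (j in start:spec$genome_bp) {
        b <- findInterval(u[j], cum[ctx + 1L, ]) + 1L
        seq_i[j] <- b
        ctx <- (ctx * 4L + (b - 1L)) %% n_ctx
      }
    }
    genomes[g] <- paste(bases[seq_i], collapse = "")
  }
  names(genomes) <- sprintf("G%02d", seq_len(spec$n_genomes))
  genomes
}

#' Fragment genomes into a multi-sample contig catalogue
#'
#' Every genome is fragmented independently in each sample into
#' non-overlapping fragments with lengths uniform in
#' `[frag_min, frag_max]`, tiling the full genome (a trailing remainder
#' shorter than `frag_min` is absorbed into the final fragment). Contig ids
#' are `S<sample>C<k>` with a global counter `k`.
#'
#' @param genomes Named genome sequences from [generate_genomes()].
#' @param spec The [synthetic_spec()].
#' @return List with `contigs` (tibble `id`, `sequence`, `length`) and
#'   `truth` (tibble `contig`, `genome`, `covered_bp`, `genome_bp`).
#' @export
fragment_genomes <- function(genomes, spec) {
  set.seed(spec$seed + 1L)
  ids <- character(); seqs <- character(); lens <- integer()
  gen <- character()
  counter <- 0L
  for (s in seq_len(spec$n_samples)) {
    for (g in names(genomes)) {
      L <- nchar(genomes[[g]])
      pos <- 1L
      while (pos <= L) {
        remaining <- L - pos + 1L
        if (remaining <= spec$frag_max) {
          len <- remaining
        } else {
          len <- sample.int(spec$frag_max - spec$frag_min + 1L, 1L) +
            spec$frag_min - 1L
          # Do not leave an untileable remainder.
          if (L - (pos + len - 1L) < spec$frag_min &&
              L - (pos + len - 1L) > 0L) {
            len <- remaining
          }
        }
        counter <- counter + 1L
        ids <- c(ids, sprintf("S%dC%d", s, counter))
        seqs <- c(seqs, substr(genomes[[g]], pos, pos + len - 1L))
        lens <- c(lens, len)
        gen <- c(gen, g)
        pos <- pos + len
      }
    }
  }
  genome_bp <- vapply(genomes, nchar, 1L)
  list(
    contigs = tibble(id = ids, sequence = seqs, length = lens),
    truth = tibble(contig = ids, genome = gen, covered_bp = lens,
                   genome_bp = as.integer(genome_bp[gen]))
  )
}

#' Simulate a per-contig, per-sample depth matrix
#'
#' Genome g receives an i.i.d. log-normal abundance in every sample; every
#' contig of g inherits that abundance profile times multiplicative gamma
#' noise with mean one and the spec's dispersion, so depth profiles
#' correlate within genomes. With the catalogue mapped against every
#' sample, a contig's profile spans all samples regardless of its sample of
#' origin.
#'
#' @param truth Truth table from [fragment_genomes()].
#' @param spec The [synthetic_spec()].
#' @return Matrix `n_contigs x n_samples` of depths, contig-id rownames and
#'   `S1..S<n>` colnames.
#' @export
simulate_depths <- function(truth, spec) {
  set.seed(spec$seed + 2L)
  genomes <- sort(unique(truth$genome))
  ab <- matrix(stats::rlnorm(length(genomes) * spec$n_samples,
                             spec$abundance_meanlog, spec$abundance_sdlog),
               length(genomes), spec$n_samples,
               dimnames = list(genomes, paste0("S", seq_len(spec$n_samples))))
  depths <- ab[truth$genome, , drop = FALSE]
  if (spec$depth_dispersion > 0) {
    shape <- 1 / spec$depth_dispersion
    noise <- matrix(stats::rgamma(length(depths), shape = shape,
                                  rate = shape),
                    nrow(depths), ncol(depths))
    depths <- depths * noise
  }
  rownames(depths) <- truth$contig
  depths
}

#' Write a depth matrix in the jgi depth-file dialect
#'
#' Emits `contigName`, `contigLen`, `totalAvgDepth`, then per-sample depth
#' and `-var` variance columns, as produced by the standard depth
#' summariser.
#'
#' @param depths Depth matrix from [simulate_depths()].
#' @param lengths Named contig lengths.
#' @param path Destination TSV.
#' @param dispersion Dispersion used to fill the variance columns.
#' @return `path`, invisibly.
#' @export
write_depths_jgi <- function(depths, lengths, path, dispersion = 0) {
  out <- data.frame(
    contigName = rownames(depths),
    contigLen = as.integer(lengths[rownames(depths)]),
    totalAvgDepth = rowSums(depths),
    check.names = FALSE
  )
  for (s in colnames(depths)) {
    out[[paste0(s, ".bam")]] <- depths[, s]
    out[[paste0(s, ".bam-var")]] <- (depths[, s] * dispersion)^2
  }
  readr::write_tsv(as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Generate a complete synthetic metagenome
#'
#' Runs genome generation, fragmentation and depth simulation, builds the
#' taxonomy (each genome its own species; genera assigned in pairs) and
#' optionally writes the four standard files: `catalogue.fna`,
#' `depths.tsv` (jgi dialect), `truth.tsv` and `taxonomy.tsv`, plus a
#' `spec.yaml` echo.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory (created if missing).
#' @return List with `contigs`, `depths`, `truth`, `taxonomy`, `genomes`,
#'   `spec` and (when `dir` is given) `paths`.
#' @export
simulate_metagenome <- function(spec = synthetic_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genomes <- generate_genomes(spec)
  frag <- fragment_genomes(genomes, spec)
  depths <- simulate_depths(frag$truth, spec)
  taxonomy <- tibble(
    genome = names(genomes),
    species = sprintf("species_%02d", seq_along(genomes)),
    genus = sprintf("genus_%02d", (seq_along(genomes) + 1) %/% 2)
  )
  out <- list(contigs = frag$contigs, depths = depths, truth = frag$truth,
              taxonomy = taxonomy, genomes = genomes, spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      fasta = file.path(dir, "catalogue.fna"),
      depths = file.path(dir, "depths.tsv"),
      truth = file.path(dir, "truth.tsv"),
      taxonomy = file.path(dir, "taxonomy.tsv"),
      spec = file.path(dir, "spec.yaml")
    )
    dna <- Biostrings::DNAStringSet(setNames(frag$contigs$sequence,
                                             frag$contigs$id))
    Biostrings::writeXStringSet(dna, paths$fasta)
    write_depths_jgi(depths, setNames(frag$contigs$length, frag$contigs$id),
                     paths$depths, spec$depth_dispersion)
    readr::write_tsv(frag$truth, paths$truth, progress = FALSE)
    readr::write_tsv(taxonomy, paths$taxonomy, progress = FALSE)
    yaml::write_yaml(unclass(spec), paths$spec)
    out$paths <- paths
  }
  out
}
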