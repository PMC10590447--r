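# The 103-dimensional tetranucleotide projection.
#
# Raw tetramer frequency vectors live in a 256-dimensional simplex, but the
# informative part of that space is much smaller: counting on one strand of a
# double-stranded molecule makes a tetramer and its reverse complement
# interchangeable, the frequencies sum to one, and overlapping counts tie each
# 3-mer's outgoing and incoming tetramer mass together. Removing those linear
# redundancies leaves a 103-dimensional subspace; projecting onto an
# orthonormal basis of it gives compact, strand-insensitive composition
# features.

#' All tetramers in column order used throughout the package
#'
#' Lexicographic order over the alphabet A, C, G, T, matching the column
#' order of [Biostrings::oligonucleotideFrequency()].
#'
#' @return Character vector of length 256.
#' @keywords internal
all_tetramers <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b4 = bases, b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  paste0(grid$b1, grid$b2, grid$b3, grid$b4)
}

reverse_complement_tetramers <- function(tetramers) {
  flipped <- chartr("ACGT", "TGCA", tetramers)
  vapply(strsplit(flipped, ""), function(x) paste(rev(x), collapse = ""), "")
}

#' Orthonormal tetranucleotide projection kernel
#'
#' Builds the deterministic 256 x 103 matrix that maps a raw tetramer
#' frequency vector into the subspace of composition space that is (a)
#' invariant under reverse complementation, (b) orthogonal to the uniform
#' (total frequency) direction, and (c) orthogonal to the 3-mer continuity
#' constraints coupling overlapping tetramer counts. The basis is extracted
#' as the null space of the stacked constraint matrix; column signs are fixed
#' so the first entry of non-negligible magnitude is positive.
#'
#' @return A 256 x 103 numeric matrix with tetramer rownames. `t(K) %*% K`
#'   is the identity, `t(K)` maps a frequency vector and its
#'   reverse-complement-permuted twin to the same point, and the uniform
#'   vector (all 1/256) maps to zero.
#' @examples
#' K <- tnf_kernel()
#' max(abs(crossprod(K) - diag(103))) < 1e-8
#' @export
tnf_kernel <- function() {
  tet <- all_tetramers()
  n <- length(tet)
  rc <- match(reverse_complement_tetramers(tet), tet)

  # Reverse-complement symmetry: f[i] - f[rc(i)] = 0 for each unordered pair.
  pairs <- which(seq_len(n) < rc)
  c_rc <- matrix(0, length(pairs), n)
  c_rc[cbind(seq_along(pairs), pairs)] <- 1
  c_rc[cbind(seq_along(pairs), rc[pairs])] <- -1

  # Total-frequency direction.
  c_sum <- matrix(1, 1, n)

  # 3-mer continuity: overlapping counting forces the mass of tetramers
  # starting with 3-mer w to track the mass of tetramers ending with w.
  bases <- c("A", "C", "G", "T")
  trimers <- apply(expand.grid(b3 = bases, b2 = bases, b1 = bases,
                               stringsAsFactors = FALSE)[, 3:1], 1, paste,
                   collapse = "")
  c_flow <- matrix(0, length(trimers), n)
  for (i in seq_along(trimers)) {
    w <- trimers[i]
    out <- match(paste0(w, bases), tet)
    inc <- match(paste0(bases, w), tet)
    c_flow[i, out] <- c_flow[i, out] + 1
    c_flow[i, inc] <- c_flow[i, inc] - 1
  }

  constraints <- rbind(c_rc, c_sum, c_flow)
  s <- svd(constraints, nu = 0, nv = n)
  rank <- sum(s$d > max(dim(constraints)) * max(s$d) * 1e-12)
  kernel <- s$v[, (rank + 1):n, drop = FALSE]
  stopifnot(ncol(kernel) == 103L)

  # Deterministic sign convention.
  for (j in seq_len(ncol(kernel))) {
    lead <- which(abs(kernel[, j]) > 1e-8)[1]
    if (kernel[lead, j] < 0) kernel[, j] <- -kernel[, j]
  }
  rownames(kernel) <- tet
  kernel
}
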