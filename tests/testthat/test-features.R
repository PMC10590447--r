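test_that("projection kernel is orthonormal, RC-symmetric and mean-free", {
  K <- tnf_kernel()
  expect_equal(dim(K), c(256L, 103L))
  expect_lt(max(abs(crossprod(K) - diag(103))), 1e-8)

  tet <- rownames(K)
  v <- numeric(256); v[match("AAAA", tet)] <- 1
  w <- numeric(256); w[match("TTTT", tet)] <- 1
  expect_lt(max(abs(crossprod(K, v) - crossprod(K, w))), 1e-10)

  expect_lt(max(abs(crossprod(K, rep(1 / 256, 256)))), 1e-10)
  expect_equal(qr(K)$rank, 103L)
  expect_identical(K, tnf_kernel()) # deterministic construction
})

test_that("tetramer counting skips ambiguous windows and normalises", {
  contigs <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c("AAAAAA", "ACGNACG", "ACGTACGT"),
    length = c(6L, 7L, 8L)
  )
  freq <- tetramer_frequencies(contigs)
  expect_equal(unname(freq["a", "AAAA"]), 1)
  expect_equal(sum(freq["a", ] > 0), 1L)
  # every 4-window of "ACGNACG" touches the N: uniform fallback row
  expect_equal(unname(freq["b", ]), rep(1 / 256, 256), ignore_attr = TRUE)
  expect_equal(unname(rowSums(freq)), rep(1, 3))
})

test_that("projected composition is invariant under reverse complement", {
  set.seed(7)
  seqs <- vapply(c(80, 120, 200), random_dna, "")
  fwd <- tibble::tibble(id = paste0("f", 1:3), sequence = seqs,
                        length = nchar(seqs))
  rev <- dplyr::mutate(fwd, sequence = rc_string(sequence))
  K <- tnf_kernel()
  expect_lt(max(abs(compute_tnf(fwd, K, scale = FALSE) -
                      compute_tnf(rev, K, scale = FALSE))), 1e-10)
  # and identical input gives bitwise-identical output
  expect_identical(compute_tnf(fwd, K), compute_tnf(fwd, K))
})

test_that("z-scaling gives zero-mean unit-sd columns", {
  set.seed(11)
  seqs <- vapply(rep(150, 6), random_dna, "")
  contigs <- tibble::tibble(id = paste0("c", 1:6), sequence = seqs,
                            length = nchar(seqs))
  tnf <- compute_tnf(contigs)
  expect_lt(max(abs(colMeans(tnf))), 1e-6)
  expect_lt(max(abs(apply(tnf, 2, sd) - 1)), 1e-6)
})

test_that("read_contigs filters by length and rejects duplicate headers", {
  set.seed(3)
  seqs <- vapply(c(150, 90, 300), random_dna, "")
  path <- write_fasta_tmp(seqs, c("S1C1", "S1C2", "S1C3"))
  expect_message(kept <- read_contigs(path, min_length = 100), "2 of 3")
  expect_equal(kept$id, c("S1C1", "S1C3"))
  expect_equal(kept$length, c(150L, 300L))
  expect_equal(nrow(suppressMessages(read_contigs(path, min_length = 0))), 3L)
  expect_error(suppressMessages(read_contigs(path, min_length = 1000)),
               "no contigs")

  dup <- write_fasta_tmp(seqs[1:2], c("S1C1", "S1C1"))
  expect_error(read_contigs(dup, 0), "duplicate.*S1C1")
})

test_that("read_depths parses the jgi dialect and aligns to contig order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("contigName", "contigLen", "totalAvgDepth",
          "s1.bam", "s1.bam-var", "s2.bam", "s2.bam-var", "s3.bam",
          "s3.bam-var", sep = "\t"),
    paste("S1C2", "500", "4", "0", "0", "0", "0", "4", "16", sep = "\t"),
    paste("S1C1", "300", "6", "1", "1", "2", "4", "3", "9", sep = "\t")
  ), path)
  raw <- read_depths(path, c("S1C1", "S1C2"))
  expect_equal(unname(raw), rbind(c(1, 2, 3), c(0, 0, 4)))
  expect_equal(colnames(raw), c("s1.bam", "s2.bam", "s3.bam"))
  expect_error(read_depths(path, c("S1C1", "S1C9")), "S1C9")
})

test_that("abundance normalisation sums rows to one with uniform fallback", {
  out <- normalize_abundances(rbind(c(1, 2, 3), c(0, 0, 0)))
  expect_equal(out[1, ], c(1, 2, 3) / 6, ignore_attr = TRUE)
  expect_equal(out[2, ], rep(1 / 3, 3), ignore_attr = TRUE)
  expect_equal(normalize_abundances(matrix(5))[1, 1], 1)
  expect_error(normalize_abundances(matrix(-1)), "nonnegative")

  set.seed(5)
  m <- matrix(rexp(40), 8, 5)
  expect_lt(max(abs(rowSums(normalize_abundances(m)) - 1)), 1e-9)
})

test_that("feature assembly concatenates TNF and abundance per contig", {
  set.seed(9)
  seqs <- vapply(rep(100, 4), random_dna, "")
  contigs <- tibble::tibble(id = c("S1C1", "S1C2", "S2C3", "S2C4"),
                            sequence = seqs, length = nchar(seqs))
  tnf <- compute_tnf(contigs)
  ab <- matrix(rexp(16), 4, 4)
  feats <- assemble_features(contigs, tnf, ab)
  expect_equal(ncol(feats$X), 103L + 4L)
  expect_equal(feats$samples, c("S1", "S1", "S2", "S2"))

  expect_equal(sample_of_contig("S1C42"), "S1")
  expect_error(sample_of_contig("contig42"), "sample prefix")
  expect_error(sample_of_contig("Cxyz"), "sample prefix")
})
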