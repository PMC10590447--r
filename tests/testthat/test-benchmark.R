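test_that("precision and recall follow the bp-coverage definitions", {
  truth <- tibble::tibble(
    contig = c("S1C1", "S1C2", "S1C3"),
    genome = c("G", "H", "G"),
    covered_bp = c(900, 100, 100),
    genome_bp = c(1000, 1000, 1000)
  )
  ref <- genome_reference(truth)
  bins <- tibble::tibble(bin = "b", contig = c("S1C1", "S1C2"))
  pr <- precision_recall(bins, ref)
  g <- pr[pr$genome == "G", ]
  expect_equal(g$recall, 0.9)
  expect_equal(g$precision, 0.9)
  # no row for genomes without any contig in the bin
  expect_false("H" %in% precision_recall(
    tibble::tibble(bin = "b", contig = "S1C1"), ref)$genome)

  pure <- precision_recall(
    tibble::tibble(bin = "b", contig = c("S1C1", "S1C3")), ref)
  expect_equal(pure$precision, 1)
  expect_equal(pure$recall, 1)
})

test_that("clade aggregation takes max recall and summed precision", {
  truth <- tibble::tibble(
    contig = c("S1C1", "S1C2"),
    genome = c("strainA", "strainB"),
    covered_bp = c(500, 400),
    genome_bp = c(1000, 1000)
  )
  taxonomy <- tibble::tibble(genome = c("strainA", "strainB"),
                             species = "sp1", genus = "gen1")
  ref <- genome_reference(truth, taxonomy)
  bins <- tibble::tibble(bin = "b", contig = c("S1C1", "S1C2"))
  pr <- precision_recall(bins, ref)
  expect_equal(pr$precision, c(5 / 9, 4 / 9))

  cm <- clade_metrics(pr, ref, "species")
  expect_equal(cm$precision, 1)
  expect_equal(cm$recall, 0.5)

  # singleton clade equals genome-level metrics
  tax1 <- tibble::tibble(genome = "strainA", species = "spA", genus = "genA")
  ref1 <- genome_reference(truth[1, ], tax1)
  pr1 <- precision_recall(tibble::tibble(bin = "b", contig = "S1C1"), ref1)
  cm1 <- clade_metrics(pr1, ref1, "species")
  expect_equal(cm1$precision, pr1$precision)
  expect_equal(cm1$recall, pr1$recall)
})

test_that("recovery counting is once-per-genome and threshold-monotone", {
  set.seed(17)
  sim <- simulate_metagenome(synthetic_spec(n_genomes = 5, genome_bp = 5000,
                                            n_samples = 2,
                                            contigs_per_genome = 4, seed = 17))
  ref <- genome_reference(sim$truth, sim$taxonomy)
  # perfect binning: one bin per genome per sample
  perfect <- sim$truth |>
    dplyr::mutate(bin = paste0(genome, "_", sample_of_contig(contig))) |>
    dplyr::select(bin, contig)
  rec <- count_recovered(perfect, ref)
  expect_equal(rec$n, 5L)

  # degenerate thresholds count every clade touched by any bin
  all_touched <- count_recovered(perfect, ref, 0, 0)
  expect_equal(all_touched$n, 5L)

  # one catch-all bin: nothing passes strict purity thresholds
  lump <- tibble::tibble(bin = "all", contig = sim$truth$contig)
  expect_equal(count_recovered(lump, ref)$n, 0L)

  # monotone non-increasing in both thresholds
  grid <- expand.grid(r = c(0, 0.5, 0.9), p = c(0, 0.5, 0.95))
  counts <- mapply(function(r, p) count_recovered(perfect, ref, r, p)$n,
                   grid$r, grid$p)
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      if (grid$r[j] >= grid$r[i] && grid$p[j] >= grid$p[i]) {
        expect_lte(counts[j], counts[i])
      }
    }
  }
})

test_that("metrics match the nested-loop oracle on random instances", {
  set.seed(31)
  for (rep in 1:100) {
    n_genomes <- sample(2:10, 1)
    n_contigs <- sample(5:50, 1)
    genomes <- sprintf("g%d", seq_len(n_genomes))
    truth <- tibble::tibble(
      contig = sprintf("S1C%d", seq_len(n_contigs)),
      genome = sample(genomes, n_contigs, replace = TRUE),
      covered_bp = sample(100:2000, n_contigs, replace = TRUE)
    )
    truth$genome_bp <- vapply(truth$genome, function(g) {
      sum(truth$covered_bp[truth$genome == g]) + sample(0:500, 1)
    }, 1)
    # make genome_bp consistent per genome
    sizes <- tapply(truth$genome_bp, truth$genome, max)
    truth$genome_bp <- as.numeric(sizes[truth$genome])
    ref <- genome_reference(truth)
    n_bins <- sample(1:6, 1)
    bins <- tibble::tibble(
      bin = sprintf("b%d", sample.int(n_bins, n_contigs, replace = TRUE)),
      contig = truth$contig
    )
    got <- precision_recall(bins, ref)
    want <- oracle_metrics(bins, truth, setNames(truth$genome_bp, truth$genome))
    want <- want[order(want$bin, want$genome), ]
    expect_equal(got$bp, want$bp)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)

    thr <- c(runif(1), runif(1))
    expect_equal(count_recovered(bins, ref, thr[1], thr[2])$n,
                 oracle_count_recovered(got, thr[1], thr[2]))
  }
})

test_that("clade precision over disjoint top-level clades sums to at most 1", {
  set.seed(41)
  sim <- simulate_metagenome(synthetic_spec(n_genomes = 6, genome_bp = 4000,
                                            n_samples = 2,
                                            contigs_per_genome = 3, seed = 41))
  ref <- genome_reference(sim$truth, sim$taxonomy)
  bins <- tibble::tibble(
    bin = sprintf("b%d", sample.int(4, nrow(sim$truth), replace = TRUE)),
    contig = sim$truth$contig
  )
  cm <- clade_metrics(precision_recall(bins, ref), ref, "genus")
  per_bin <- tapply(cm$precision, cm$bin, sum)
  expect_true(all(per_bin <= 1 + 1e-12))
})
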