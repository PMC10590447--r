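test_that("bin scores follow completeness - 5 * contamination", {
  bins <- tibble::tibble(bin = c("b1", "b2", "b3"),
                         contig = c("S1C1", "S1C2", "S1C3"))
  quality <- tibble::tibble(
    bin = c("b1", "b2", "b3"),
    completeness = c(1.0, 0.9, 0.9),
    contamination = c(0.0, 0.05, 0.2)
  )
  scored <- score_bins(bins, quality)
  expect_equal(scored$score, c(1.0, 0.65, -0.1), tolerance = 1e-12)
  expect_error(score_bins(bins, quality[1:2, ]), "b3")
})

test_that("NC filtering uses strict inequalities on both boundaries", {
  scored <- tibble::tibble(
    bin = c("kept", "comp_at_boundary", "cont_at_boundary"),
    completeness = c(0.95, 0.90, 0.99),
    contamination = c(0.01, 0.01, 0.05)
  )
  expect_equal(filter_nc(scored)$bin, "kept")
})

test_that("near-identical pairs use the smaller bin's bp fraction", {
  lengths <- c(S1C1 = 80, S1C2 = 20, S1C3 = 300, S1C4 = 100)
  identical_bins <- tibble::tibble(
    bin = rep(c("a", "b"), each = 2),
    contig = c("S1C1", "S1C2", "S1C1", "S1C2")
  )
  p <- find_near_identical_pairs(identical_bins, lengths)
  expect_equal(p$overlap, 1)

  disjoint <- tibble::tibble(bin = c("a", "b"), contig = c("S1C1", "S1C3"))
  expect_equal(nrow(find_near_identical_pairs(disjoint, lengths)), 0L)

  # 100 bp bin shares its 80 bp contig with a larger bin: overlap 0.8
  partial <- tibble::tibble(
    bin = c("small", "small", "big", "big"),
    contig = c("S1C1", "S1C2", "S1C1", "S1C3")
  )
  p <- find_near_identical_pairs(partial, lengths)
  expect_equal(p$overlap, 0.8)
  expect_equal(nrow(find_near_identical_pairs(partial, lengths,
                                              overlap_threshold = 0.81)), 0L)
})

test_that("quality reports parse percent and fraction scales", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Name\tCompleteness\tContamination", "bin1\t95.2\t1.3"), path)
  rep <- parse_quality_report(path)
  expect_equal(rep$completeness, 0.952)
  expect_equal(rep$contamination, 0.013)

  writeLines(c("Name\tCompleteness\tContamination", "bin1\t0.95\t0.01"), path)
  rep <- parse_quality_report(path)
  expect_equal(rep$completeness, 0.95)
  expect_equal(rep$contamination, 0.01)

  writeLines(c("Name\tCompleteness", "bin1\t0.95"), path)
  expect_error(parse_quality_report(path), "Contamination")
})

test_that("ground-truth scorer implements the dominant-genome definition", {
  truth <- tibble::tibble(
    contig = c("S1C1", "S1C2", "S1C3", "S1C4"),
    genome = c("g1", "g1", "g1", "g2"),
    covered_bp = c(400, 400, 200, 100),
    genome_bp = c(1000, 1000, 1000, 1000)
  )
  scorer <- quality_scorer_truth(truth)
  pure <- scorer(tibble::tibble(bin = "b", contig = c("S1C1", "S1C2", "S1C3")))
  expect_equal(pure$completeness, 1)
  expect_equal(pure$contamination, 0)

  mixed <- scorer(tibble::tibble(bin = "b",
                                 contig = c("S1C1", "S1C2", "S1C3", "S1C4")))
  expect_equal(mixed$completeness, 1)
  expect_equal(mixed$contamination, 0.1)

  expect_error(scorer(tibble::tibble(bin = character(), contig = character())),
               "empty")
  expect_error(scorer(tibble::tibble(bin = "b", contig = "S9C9")), "absent")
})

test_that("pair removal keeps the higher-scoring duplicate", {
  truth <- tibble::tibble(
    contig = sprintf("S1C%d", 1:4),
    genome = c("g1", "g1", "g1", "g2"),
    covered_bp = c(500, 300, 150, 400),
    genome_bp = c(1000, 1000, 1000, 400)
  )
  lengths <- setNames(truth$covered_bp, truth$contig)
  scorer <- quality_scorer_truth(truth)
  # z-side bin is pure g1 at 0.95 completeness; y-side adds a g2 contig
  bz <- tibble::tibble(bin = "zbin", contig = c("S1C1", "S1C2", "S1C3"))
  by <- tibble::tibble(bin = "ybin",
                       contig = c("S1C1", "S1C2", "S1C3", "S1C4"))
  out <- dereplicate(list(bz, by), scorer, lengths, max_contamination = 0.5)
  expect_equal(unique(out$bin), "zbin")
})

test_that("shared contigs go to the owner with the largest score drop", {
  # Contig S1C3 completes g1 (drop 0.30 from bin P) but barely matters to
  # the g2 bin Q (drop 0.05); both bins stay NC throughout.
  truth <- tibble::tibble(
    contig = c("S1C1", "S1C2", "S1C3", "S1C4", "S1C5"),
    genome = c("g1", "g1", "g1", "g2", "g2"),
    covered_bp = c(400, 300, 300, 1900, 100),
    genome_bp = c(1000, 1000, 1000, 2000, 2000)
  )
  lengths <- setNames(truth$covered_bp, truth$contig)
  scorer <- quality_scorer_truth(truth)
  p <- tibble::tibble(bin = "P", contig = c("S1C1", "S1C2", "S1C3"))
  q <- tibble::tibble(bin = "Q", contig = c("S1C3", "S1C4", "S1C5"))
  out <- dereplicate(list(p, q), scorer, lengths, max_contamination = 0.5)
  expect_true("S1C3" %in% out$contig[out$bin == "P"])
  expect_false("S1C3" %in% out$contig[out$bin == "Q"])
  expect_false(anyDuplicated(out$contig) > 0)
})

test_that("de-replication matches the exhaustive oracle on small instances", {
  set.seed(99)
  for (rep in 1:30) {
    inst <- random_derep_instance()
    scorer <- quality_scorer_truth(inst$truth)
    got <- dereplicate(inst$sets, scorer, inst$lengths,
                       min_completeness = 0.5, max_contamination = 0.6)
    want <- oracle_dereplicate(inst$sets, scorer, inst$lengths,
                               min_completeness = 0.5,
                               max_contamination = 0.6)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
    expect_false(anyDuplicated(got$contig) > 0)
    # no bin appears that was not in the input
    expect_true(all(got$bin %in% c(inst$sets[[1]]$bin, inst$sets[[2]]$bin)))
  }
})

test_that("de-replication is invariant to bin-set order", {
  set.seed(123)
  inst <- random_derep_instance()
  scorer <- quality_scorer_truth(inst$truth)
  a <- dereplicate(inst$sets, scorer, inst$lengths,
                   min_completeness = 0.5, max_contamination = 0.6)
  b <- dereplicate(rev(inst$sets), scorer, inst$lengths,
                   min_completeness = 0.5, max_contamination = 0.6)
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})
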