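# Independent brute-force oracles and small fixture builders. These are
# deliberately written with plain loops and base R, independent of the
# package's implementation paths they check.

rc_string <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""),
         function(ch) paste(rev(ch), collapse = ""), "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_fasta_tmp <- function(seqs, ids = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".fna", .local_envir = parent.frame())
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# Connected components at a fixed cosine-distance radius via union-find;
# oracle for clustering of well-separated point clouds.
connected_components <- function(Z, radius) {
  U <- sweep(Z, 2, colMeans(Z))
  U <- U / sqrt(rowSums(U^2))
  D <- (1 - tcrossprod(U)) / 2
  n <- nrow(Z)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] <= radius) parent[find(j)] <- find(i)
    }
  }
  vapply(seq_len(n), find, 1L)
}

# Nested-loop evaluation of per-bin precision/recall and clade aggregation.
oracle_metrics <- function(bins, truth, genome_bp) {
  out <- list()
  for (b in unique(bins$bin)) {
    contigs <- bins$contig[bins$bin == b]
    bp_by_genome <- c()
    for (g in unique(truth$genome)) {
      bp <- 0
      for (cg in contigs) {
        rows <- which(truth$contig == cg & truth$genome == g)
        if (length(rows) > 0) bp <- bp + sum(truth$covered_bp[rows])
      }
      if (bp > 0) bp_by_genome[g] <- bp
    }
    denom <- sum(bp_by_genome)
    for (g in names(bp_by_genome)) {
      out[[length(out) + 1]] <- data.frame(
        bin = b, genome = g, bp = bp_by_genome[[g]],
        precision = bp_by_genome[[g]] / denom,
        recall = bp_by_genome[[g]] / genome_bp[[g]]
      )
    }
  }
  do.call(rbind, out)
}

oracle_clade_metrics <- function(pr, taxonomy, level) {
  clade_of <- setNames(taxonomy[[level]], taxonomy$genome)
  out <- list()
  for (b in unique(pr$bin)) {
    rows <- pr[pr$bin == b, ]
    for (cl in unique(clade_of[rows$genome])) {
      sub <- rows[clade_of[rows$genome] == cl, ]
      out[[length(out) + 1]] <- data.frame(
        bin = b, clade = cl,
        precision = sum(sub$precision), recall = max(sub$recall)
      )
    }
  }
  do.call(rbind, out)
}

oracle_count_recovered <- function(pr, recall_thr, precision_thr) {
  n <- 0
  for (g in unique(pr$genome)) {
    rows <- pr[pr$genome == g, ]
    if (any(rows$recall >= recall_thr & rows$precision >= precision_thr)) {
      n <- n + 1
    }
  }
  n
}

# Exhaustive de-replication oracle: plain-loop application of the quality
# score, the near-identical pair rule and largest-score-drop reassignment,
# recomputing everything from scratch at each iteration.
oracle_dereplicate <- function(bin_sets, scorer, lengths,
                               min_completeness = 0.9,
                               max_contamination = 0.05,
                               overlap_threshold = 0.75) {
  bins <- list()
  for (set in bin_sets) {
    for (b in unique(set$bin)) {
      bins[[b]] <- sort(unique(set$contig[set$bin == b]))
    }
  }
  score1 <- function(name, contigs) {
    q <- scorer(tibble::tibble(bin = name, contig = contigs))
    list(score = q$completeness - 5 * q$contamination,
         completeness = q$completeness, contamination = q$contamination)
  }
  qual <- lapply(names(bins), function(b) score1(b, bins[[b]]))
  names(qual) <- names(bins)
  keep <- vapply(names(bins), function(b) {
    qual[[b]]$completeness > min_completeness &&
      qual[[b]]$contamination < max_contamination
  }, TRUE)
  bins <- bins[keep]
  scores <- vapply(names(bins), function(b) qual[[b]]$score, 1)
  bp <- vapply(bins, function(ids) sum(lengths[ids]), 1)

  repeat {
    nms <- sort(names(bins))
    best <- NULL
    for (i in seq_along(nms)) {
      for (j in seq_along(nms)) {
        if (i >= j) next
        shared <- intersect(bins[[nms[i]]], bins[[nms[j]]])
        if (length(shared) == 0) next
        ov <- sum(lengths[shared]) / min(bp[nms[i]], bp[nms[j]])
        if (ov >= overlap_threshold &&
            (is.null(best) || ov > best$ov + 1e-12)) {
          best <- list(b1 = nms[i], b2 = nms[j], ov = ov)
        }
      }
    }
    if (is.null(best)) break
    s1 <- scores[best$b1]; s2 <- scores[best$b2]
    loser <- if (s1 != s2) {
      if (s1 < s2) best$b1 else best$b2
    } else if (bp[best$b1] != bp[best$b2]) {
      if (bp[best$b1] < bp[best$b2]) best$b1 else best$b2
    } else {
      max(best$b1, best$b2)
    }
    bins[[loser]] <- NULL
  }

  repeat {
    all_contigs <- sort(unique(unlist(bins)))
    shared <- all_contigs[vapply(all_contigs, function(cg) {
      sum(vapply(bins, function(ids) cg %in% ids, TRUE)) > 1
    }, TRUE)]
    if (length(shared) == 0) break
    cg <- shared[1]
    owners <- sort(names(bins)[vapply(bins, function(ids) cg %in% ids, TRUE)])
    cur <- vapply(owners, function(b) score1(b, bins[[b]])$score, 1)
    drops <- vapply(owners, function(b) {
      kept <- setdiff(bins[[b]], cg)
      if (length(kept) == 0) return(unname(cur[b]))
      unname(cur[b] - score1(b, kept)$score)
    }, 1)
    ord <- order(-drops, -cur, owners)
    winner <- owners[ord[1]]
    for (b in setdiff(owners, winner)) {
      bins[[b]] <- setdiff(bins[[b]], cg)
      if (length(bins[[b]]) == 0) bins[[b]] <- NULL
    }
  }

  if (length(bins) == 0) {
    return(tibble::tibble(bin = character(), contig = character()))
  }
  out <- tibble::tibble(
    bin = rep(names(bins), vapply(bins, length, 1L)),
    contig = unlist(bins, use.names = FALSE)
  )
  out[order(out$bin, out$contig), ]
}

# A small random truth/bin instance for oracle comparisons: two competing
# bin sets whose bins are genome-based with random dropped and foreign
# contigs, so that NC filtering, pairing and reassignment all trigger.
random_derep_instance <- function(n_genomes = 3, n_contigs = 12) {
  genomes <- sprintf("g%d", seq_len(n_genomes))
  contigs <- sprintf("S1C%d", seq_len(n_contigs))
  truth <- tibble::tibble(
    contig = contigs,
    genome = sample(genomes, n_contigs, replace = TRUE),
    covered_bp = sample(50:500, n_contigs, replace = TRUE)
  )
  truth$genome_bp <- vapply(truth$genome, function(g) {
    sum(truth$covered_bp[truth$genome == g])
  }, 1)
  sets <- list()
  for (k in seq_len(2)) {
    rows <- list()
    for (g in genomes) {
      own <- truth$contig[truth$genome == g]
      keep <- own[runif(length(own)) > 0.2]
      foreign <- setdiff(contigs, own)
      if (length(foreign) > 0 && runif(1) < 0.3) {
        keep <- c(keep, sample(foreign, 1))
      }
      if (length(keep) == 0) next
      rows[[g]] <- tibble::tibble(bin = sprintf("set%d_%s", k, g),
                                  contig = sort(unique(keep)))
    }
    sets[[k]] <- do.call(rbind, rows)
  }
  list(truth = truth, sets = sets,
       lengths = setNames(truth$covered_bp, truth$contig))
}
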