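# Synthetic genome, fragmentation and ultra-long-read PAF generator.

test_that("simulate_genome is deterministic per seed and plants features where stated", {
  a <- simulate_genome(n_chrom = 2, chrom_len = 1e5, telomere_copies = 150,
                       centromere_len = 2e4, n_at_arrays = 3, at_array_len = 2000, seed = 5)
  b <- simulate_genome(n_chrom = 2, chrom_len = 1e5, telomere_copies = 150,
                       centromere_len = 2e4, n_at_arrays = 3, at_array_len = 2000, seed = 5)
  expect_identical(as.character(a$genome), as.character(b$genome))
  c2 <- simulate_genome(n_chrom = 2, chrom_len = 1e5, telomere_copies = 150,
                        centromere_len = 2e4, n_at_arrays = 3, at_array_len = 2000, seed = 6)
  expect_false(identical(as.character(a$genome), as.character(c2$genome)))

  # a 150-copy motif run occupies [0, 1050) of each chromosome
  head_seq <- substr(as.character(a$genome[["Chr01"]]), 1, 1050)
  expect_equal(head_seq, strrep("CCCTAAA", 150))
  tail_seq <- substr(as.character(a$genome[["Chr02"]]), 1e5 - 1050 + 1, 1e5)
  expect_equal(tail_seq, strrep("TTTAGGG", 150))

  # features are recorded where planted
  for (r in seq_len(nrow(a$features))) {
    fe <- a$features[r, ]
    frag <- substr(as.character(a$genome[[fe$seq_id]]), fe$start + 1, fe$end)
    expect_equal(substr(frag, 1, fe$period), substr(fe$unit, 1, fe$period))
  }

  expect_error(simulate_genome(n_chrom = 1, chrom_len = 1e4, centromere_len = 1e6),
               class = "ulscaf_parameter_error")
})

test_that("fragment_genome partitions chromosomes exactly when gap_margin is 0", {
  truth <- simulate_genome(n_chrom = 2, chrom_len = 1e5, telomere_copies = 50,
                           centromere_len = 1e4, n_at_arrays = 2, at_array_len = 1500,
                           seed = 9)
  fr <- fragment_genome(truth, n_contigs_per_chrom = 4, gap_margin = 0,
                        flip_prob = 0.5, seed = 10)
  expect_equal(nrow(fr$placements), 8L)
  expect_equal(names(fr$contigs), sprintf("ctg%04d", 1:8))
  for (chrom in names(fr$genome)) {
    pl <- fr$placements[fr$placements$chrom == chrom, ]
    pl <- pl[order(pl$start), ]
    expect_equal(pl$start[1], 0)
    expect_equal(pl$end[nrow(pl)], 1e5)
    expect_equal(pl$start[-1], pl$end[-nrow(pl)])
    # reassembling oriented contig sequences reproduces the chromosome
    pieces <- vapply(seq_len(nrow(pl)), function(i) {
      s <- fr$contigs[[pl$contig_id[i]]]
      if (pl$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    expect_equal(paste(pieces, collapse = ""), as.character(fr$genome[[chrom]]))
  }
})

test_that("fragment_genome records 2*gap_margin junction gaps and AT breakpoints", {
  truth <- simulate_genome(n_chrom = 1, chrom_len = 2e5, telomere_copies = 50,
                           centromere_len = 1e4, n_at_arrays = 6, at_array_len = 3000,
                           seed = 12)
  fr <- fragment_genome(truth, n_contigs_per_chrom = 5, gap_margin = 200, seed = 13)
  expect_equal(fr$junctions$gap, rep(400, 4))

  at_fr <- fragment_genome(truth, n_contigs_per_chrom = 4, break_at_at = TRUE,
                           gap_margin = 100, seed = 14)
  at_feats <- truth$features[truth$features$kind == "at", ]
  pl <- at_fr$placements[order(at_fr$placements$start), ]
  internal_ends <- c(pl$end[-nrow(pl)], pl$start[-1])
  for (pos in internal_ends) {
    expect_true(any(at_feats$start <= pos & at_feats$end >= pos),
                label = sprintf("breakpoint-side end %d inside an AT array", pos))
  }

  expect_error(fragment_genome(truth, n_contigs_per_chrom = 8, break_at_at = TRUE,
                               seed = 1),
               class = "ulscaf_parameter_error")
})

test_that("simulated PAF records are valid and consistent with placements", {
  truth <- simulate_genome(n_chrom = 2, chrom_len = 2e5, telomere_copies = 50,
                           centromere_len = 1e4, n_at_arrays = 2, at_array_len = 1500,
                           seed = 21)
  truth <- fragment_genome(truth, n_contigs_per_chrom = 4, gap_margin = 150,
                           flip_prob = 0.5, seed = 22)
  sim <- simulate_ultralong_paf(truth, coverage = 10, read_len_mean = 2e4,
                                seed = 23)
  paf <- sim$paf
  expect_gt(nrow(paf), 0)
  expect_true(all(paf$read_start >= 0 & paf$read_start < paf$read_end &
                    paf$read_end <= paf$read_len))
  expect_true(all(paf$target_start >= 0 & paf$target_start < paf$target_end &
                    paf$target_end <= paf$target_len))
  expect_true(all(paf$matches <= paf$block_len))

  # every record's contig bases equal the read's bases from the chromosome
  pl <- truth$placements
  rt <- sim$read_truth
  set.seed(1)
  for (i in sample(nrow(paf), 25)) {
    rec <- paf[i, ]
    read <- rt[rt$read_id == rec$read_id, ]
    chrom_seq <- truth$genome[[read$chrom]]
    from_read <- Biostrings::subseq(chrom_seq, read$start + rec$read_start + 1,
                                    read$start + rec$read_end)
    ctg <- truth$contigs[[rec$target_id]]
    from_ctg <- Biostrings::subseq(ctg, rec$target_start + 1, rec$target_end)
    if (rec$strand == "-") from_ctg <- Biostrings::reverseComplement(from_ctg)
    expect_equal(as.character(from_read), as.character(from_ctg))
  }
})

test_that("reads within one contig give one record; junction reads give gap 0 at margin 0", {
  truth <- simulate_genome(n_chrom = 1, chrom_len = 1e5, telomere_copies = 20,
                           centromere_len = 5e3, n_at_arrays = 1, at_array_len = 1000,
                           seed = 31)
  truth <- fragment_genome(truth, n_contigs_per_chrom = 2, gap_margin = 0,
                           flip_prob = 0, seed = 32)
  sim <- simulate_ultralong_paf(truth, coverage = 15, read_len_mean = 1e4, seed = 33)
  per_read <- table(sim$paf$read_id)
  expect_true(all(per_read %in% c(1L, 2L)))
  ct <- extract_contacts(sim$paf, min_block = 500)
  expect_true(all(ct$gap == 0))

  empty <- simulate_ultralong_paf(truth, coverage = 0, seed = 34)
  expect_equal(nrow(empty$paf), 0L)
})

test_that("requested coverage is approximately realised", {
  truth <- simulate_genome(n_chrom = 1, chrom_len = 3e5, telomere_copies = 20,
                           centromere_len = 5e3, n_at_arrays = 1, at_array_len = 1000,
                           seed = 41)
  truth <- fragment_genome(truth, n_contigs_per_chrom = 2, gap_margin = 0, seed = 42)
  sim <- simulate_ultralong_paf(truth, coverage = 25, read_len_mean = 1.5e4, seed = 43)
  realised <- sum(sim$read_truth$end - sim$read_truth$start) / 3e5
  expect_lt(abs(realised - 25) / 25, 0.15)
})

test_that("the pipeline reconstructs true junctions from noise-free reads across seeds", {
  for (seed in c(3, 4)) {
    truth <- simulate_genome(n_chrom = 2, chrom_len = 4e5, telomere_copies = 50,
                             centromere_len = 2e4, n_at_arrays = 3, at_array_len = 2000,
                             seed = seed)
    truth <- fragment_genome(truth, n_contigs_per_chrom = 4, gap_margin = 200,
                             flip_prob = 0.5, seed = seed + 100)
    sim <- simulate_ultralong_paf(truth, coverage = 25, read_len_mean = 3e4,
                                  seed = seed + 200)
    res <- scaffold_pipeline(sim$paf, truth$contigs, max_end_distance = 10000,
                             min_scaffold_len = 2e5)
    jr <- junction_recovery(res$paths, truth)
    expect_equal(jr$recovery_pct, 100)
    expect_equal(jr$n_false, 0)
    expect_true(all(jr$gaps == 400))
  }
})

test_that("scaffolds are invariant to reversing the alignment order of every read", {
  truth <- simulate_genome(n_chrom = 1, chrom_len = 3e5, telomere_copies = 50,
                           centromere_len = 2e4, n_at_arrays = 3, at_array_len = 2000,
                           seed = 55)
  truth <- fragment_genome(truth, n_contigs_per_chrom = 4, gap_margin = 200,
                           flip_prob = 0.5, seed = 56)
  sim <- simulate_ultralong_paf(truth, coverage = 20, read_len_mean = 3e4, seed = 57)
  fwd <- scaffold_pipeline(sim$paf, truth$contigs, max_end_distance = 10000,
                           min_scaffold_len = 2e5)
  rev_paf <- sim$paf[rev(seq_len(nrow(sim$paf))), , drop = FALSE]
  bwd <- scaffold_pipeline(rev_paf, truth$contigs, max_end_distance = 10000,
                           min_scaffold_len = 2e5)
  expect_equal(as.character(fwd$scaffolds), as.character(bwd$scaffolds))
})
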