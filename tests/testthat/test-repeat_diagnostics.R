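# Tandem-array scanning, telomere/centromere calls, AT-end classes, Nx.

test_that("canonical_unit minimizes over rotations and strands", {
  expect_equal(canonical_unit("TA"), "AT")
  expect_equal(canonical_unit("TTTAGGG"), "AAACCCT")
  expect_equal(canonical_unit("CCCTAAA"), "AAACCCT")
  expect_equal(canonical_unit("G"), "C")
  expect_error(canonical_unit("ACGU"), class = "ulscaf_alphabet_error")
  expect_error(canonical_unit(""), class = "ulscaf_alphabet_error")
})

test_that("canonical_unit is idempotent and rotation/strand invariant", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    u <- random_dna_string(n)
    cu <- canonical_unit(u)
    expect_equal(canonical_unit(cu), cu)
    rot <- sample(n, 1)
    rotated <- paste0(substr(u, rot, n), substr(u, 1, rot - 1))
    expect_equal(canonical_unit(rotated), cu)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(u)))
    expect_equal(canonical_unit(rc), cu)
  }
})

test_that("scan_tandem_arrays finds exact arrays at their smallest period", {
  a <- scan_tandem_arrays(c(s = "ATATATATAT"), max_unit = 5, min_copies = 2)
  expect_equal(nrow(a), 1L)
  expect_equal(c(a$start, a$end), c(0, 10))
  expect_equal(a$period, 2)
  expect_equal(a$copies, 5)
  expect_equal(a$unit, "AT")

  h <- scan_tandem_arrays(c(s = "AAAAAA"), max_unit = 3, min_copies = 2)
  expect_equal(h$period, 1)
  expect_equal(h$unit, "A")
  expect_equal(h$copies, 6)

  none <- scan_tandem_arrays(c(s = "ACGTTGCA"), max_unit = 4, min_copies = 3)
  expect_equal(nrow(none), 0L)
})

test_that("scan_tandem_arrays matches the quadratic brute-force scanner", {
  set.seed(33)
  for (i in 1:40) {
    s <- random_dna_string(500)
    got <- scan_tandem_arrays(stats::setNames(s, "x"), max_unit = 10, min_copies = 2,
                              min_span = 4)
    want <- brute_tandem_spans(s, max_unit = 10, min_copies = 2, min_span = 4)
    got <- got[order(got$period, got$start), c("start", "end", "period")]
    rownames(got) <- NULL
    expect_equal(got, want, label = sprintf("iteration %d", i))
  }
})

test_that("detect_telomeres calls terminal motif arrays on either strand", {
  arr <- data.frame(seq_id = "Chr01", start = 0, end = 1050, period = 7,
                    copies = 150, unit = "CCCTAAA", score = NA)
  calls <- detect_telomeres(arr, c(Chr01 = 3e7), end_window = 1e4, min_array_len = 500)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$end, "head")
  expect_equal(calls$array_len, 1050)

  interior <- transform(arr, start = 5e6, end = 5e6 + 1050)
  expect_equal(nrow(detect_telomeres(interior, c(Chr01 = 3e7))), 0L)

  tail_rc <- data.frame(seq_id = "Chr01", start = 3e7 - 900, end = 3e7, period = 7,
                        copies = 128.6, unit = "TTTAGGG", score = NA)
  calls2 <- detect_telomeres(tail_rc, c(Chr01 = 3e7))
  expect_equal(calls2$end, "tail")

  # longest qualifying array wins; short arrays are ignored
  both <- rbind(arr, transform(arr, start = 2000, end = 8000, copies = 857))
  expect_equal(detect_telomeres(both, c(Chr01 = 3e7))$array_len, 6000)
  short <- transform(arr, end = 300)
  expect_equal(nrow(detect_telomeres(short, c(Chr01 = 3e7), min_array_len = 500)), 0L)

  expect_error(detect_telomeres(arr, c(Chr02 = 1e6)), class = "ulscaf_input_error")
})

test_that("telomere_completeness reproduces printed percentages", {
  expect_equal(telomere_completeness(17, 30), 88.24)
  expect_equal(telomere_completeness(5, 10), 100)
  expect_equal(telomere_completeness(17, 0), 0)
  expect_error(telomere_completeness(0, 0), class = "ulscaf_parameter_error")
  expect_error(telomere_completeness(5, 11), class = "ulscaf_parameter_error")
})

test_that("detect_centromeres applies the strict length cutoff and merges clusters", {
  one <- data.frame(seq_id = "c1", start = 1e6, end = 1.8e6, period = 126,
                    copies = 6349, unit = random_dna_string(126, seed = 1), score = NA)
  expect_equal(nrow(detect_centromeres(one)), 1L)

  small <- transform(one, end = 1e6 + 6.5e5)
  expect_equal(nrow(detect_centromeres(small)), 0L)

  # 400 kb + 350 kb arrays 5 kb apart merge into one 750 kb call
  two <- rbind(data.frame(seq_id = "c1", start = 0, end = 4e5, period = 126,
                          copies = 3174, unit = "X", score = NA),
               data.frame(seq_id = "c1", start = 4.05e5, end = 7.55e5, period = 126,
                          copies = 2777, unit = "X", score = NA))
  m <- detect_centromeres(two, merge_dist = 1e4)
  expect_equal(nrow(m), 1L)
  expect_equal(m$total_array_len, 7.5e5)
  expect_equal(m$mean_period, 126)
  expect_equal(m$n_arrays, 2L)

  # distant arrays do not merge; off-period arrays are ignored
  apart <- transform(two, start = c(0, 5e5), end = c(4e5, 8.5e5))
  expect_equal(nrow(detect_centromeres(apart, merge_dist = 1e4)), 0L)
  off <- transform(one, period = 140)
  expect_equal(nrow(detect_centromeres(off, period_tol = 5)), 0L)
})

test_that("classify_at_ends reproduces the printed class percentages", {
  pct <- at_end_percentages(1086, 908, 550)
  expect_equal(pct$pct_with_at_ends, 57.31)
  expect_equal(pct$pct_without, 42.69)
  expect_equal(pct$pct_with_at_ends + pct$pct_without, 100)
})

test_that("classify_at_ends counts AT ends within the terminal window", {
  lens <- c(k1 = 1e5, k2 = 1e5, k3 = 1e5)
  arr <- rbind(
    data.frame(seq_id = "k1", start = 0, end = 5000, period = 2, copies = 2500,
               unit = "AT", score = NA),
    data.frame(seq_id = "k2", start = 200, end = 900, period = 2, copies = 350,
               unit = "TA", score = NA),
    data.frame(seq_id = "k2", start = 1e5 - 800, end = 1e5, period = 2, copies = 400,
               unit = "AT", score = NA),
    data.frame(seq_id = "k3", start = 5e4, end = 5.2e4, period = 2, copies = 1000,
               unit = "AT", score = NA),
    data.frame(seq_id = "k3", start = 0, end = 3000, period = 3, copies = 1000,
               unit = "ACG", score = NA))
  cls <- classify_at_ends(lens, arr, end_window = 1000)
  expect_equal(unname(cls$classes), c(1, 2, 0))
  expect_equal(cls$n0 + cls$n1 + cls$n2, 3)
  expect_equal(cls$pct_with_at_ends, 66.67)
  expect_equal(cls$pct_without, 33.33)
  expect_false(is.null(cls$nx_by_class$at_ends_1))

  none <- classify_at_ends(lens, arr[arr$unit == "ACG", , drop = FALSE])
  expect_equal(unname(none$classes), c(0, 0, 0))
  expect_equal(none$pct_with_at_ends, 0)

  bad <- transform(arr, seq_id = "nope")
  expect_error(classify_at_ends(lens, bad), class = "ulscaf_input_error")
})

test_that("Nx agrees with the exhaustive cumulative-sum oracle", {
  expect_equal(unname(nx_curve(c(10, 9, 8, 7, 6, 5))["50"]), 8)
  expect_equal(unname(nx_curve(100)[c("50", "90")]), c(100, 100))
  set.seed(17)
  for (i in 1:20) {
    lens <- sample(1:5000, sample(1:40, 1))
    nx <- nx_curve(lens)
    for (x in c(10, 50, 90)) {
      expect_equal(unname(nx[as.character(x)]), oracle_nx(lens, x))
    }
    expect_true(all(diff(nx) <= 0))  # non-increasing in x
  }
})

test_that("assembly_stats unions overlapping arrays and sizes tandem content", {
  lens <- c(a = 60, b = 40)
  arr <- rbind(data.frame(seq_id = "a", start = 0, end = 15, period = 2,
                          copies = 7.5, unit = "AT", score = NA),
               data.frame(seq_id = "a", start = 10, end = 20, period = 2,
                          copies = 5, unit = "AT", score = NA),
               data.frame(seq_id = "b", start = 0, end = 5, period = 1,
                          copies = 5, unit = "A", score = NA))
  st <- assembly_stats(lens, arr)
  expect_equal(st$total, 100)
  expect_equal(st$tandem_bp, 25)  # [0,20) on a (overlap counted once) + [0,5) on b
  expect_equal(st$tandem_pct, 25)
  expect_equal(st$tandem_n50, 15)  # array lengths 15,10,5: cumsum 15 >= 30/2
  expect_error(assembly_stats(numeric(0)), class = "ulscaf_input_error")
})

test_that("planted telomeres, centromeres and AT ends are recovered on a synthetic genome", {
  truth <- simulate_genome(n_chrom = 2, chrom_len = 3e5, telomere_copies = 100,
                           centromere_len = 5e4, n_at_arrays = 4, at_array_len = 3000,
                           seed = 77)
  lens <- stats::setNames(Biostrings::width(truth$genome), names(truth$genome))
  arrays <- scan_tandem_arrays(truth$genome, max_unit = 131, min_copies = 2, min_span = 50)

  tel <- detect_telomeres(arrays, lens, end_window = 1e4, min_array_len = 500)
  expect_equal(nrow(tel), 4L)  # both ends of both chromosomes, nothing else
  expect_setequal(paste(tel$seq_id, tel$end),
                  c("Chr01 head", "Chr01 tail", "Chr02 head", "Chr02 tail"))
  expect_equal(telomere_completeness(2, nrow(tel)), 100)

  cen <- detect_centromeres(arrays, min_total = 4e4)
  expect_equal(nrow(cen), 2L)
  planted <- truth$features[truth$features$kind == "centromere", ]
  expect_setequal(cen$seq_id, planted$seq_id)
  # below-cutoff chromosomes are not called
  expect_equal(nrow(detect_centromeres(arrays, min_total = 7e5)), 0L)

  # planted interior AT arrays are all found within a few bases
  at <- arrays[arrays$period == 2 & vapply(arrays$unit, canonical_unit, "") == "AT", ]
  at_truth <- truth$features[truth$features$kind == "at", ]
  for (r in seq_len(nrow(at_truth))) {
    hit <- at[at$seq_id == at_truth$seq_id[r] &
                at$start <= at_truth$start[r] & at$end >= at_truth$end[r], ]
    expect_equal(nrow(hit), 1L)
    expect_lte((at_truth$start[r] - hit$start) + (hit$end - at_truth$end[r]), 30)
  }
})
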