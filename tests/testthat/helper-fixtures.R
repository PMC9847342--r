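# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

random_records <- function(n, min_len = 20, max_len = 200, seed = 1) {
  set.seed(seed)
  lens <- sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T", "N"), l, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  }, character(1))
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- sprintf("seq%03d", seq_len(n))
  s
}

random_dna_string <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# one PAF alignment as a one-row data.frame
aln <- function(read_id, read_len, read_start, read_end, strand,
                target_id, target_len, target_start, target_end,
                mapq = 60, block_len = NULL, matches = NULL, tags = "") {
  bl <- if (is.null(block_len)) read_end - read_start else block_len
  data.frame(read_id = read_id, read_len = as.numeric(read_len),
             read_start = as.numeric(read_start), read_end = as.numeric(read_end),
             strand = strand, target_id = target_id,
             target_len = as.numeric(target_len), target_start = as.numeric(target_start),
             target_end = as.numeric(target_end),
             matches = as.numeric(if (is.null(matches)) bl else matches),
             block_len = as.numeric(bl), mapq = as.numeric(mapq), tags = tags,
             stringsAsFactors = FALSE)
}

# contact-edge data.frame from triplets list(c(contig, end, contig, end), count)
edge_df <- function(...) {
  specs <- list(...)
  rows <- lapply(specs, function(sp) {
    ends <- sp[[1]]
    ka <- paste0(ends[1], ":", ends[2])
    kb <- paste0(ends[3], ":", ends[4])
    if (ka > kb) ends <- ends[c(3, 4, 1, 2)]
    gaps <- if (length(sp) >= 3) sp[[3]] else numeric(0)
    d <- data.frame(contig_a = ends[1], end_a = ends[2], contig_b = ends[3],
                    end_b = ends[4], count = sp[[2]], stringsAsFactors = FALSE)
    d$gaps <- list(gaps)
    d$gap_median <- if (length(gaps)) stats::median(gaps) else NA_real_
    d
  })
  do.call(rbind, rows)
}

# random contact graph on n contigs: distinct end pairs, counts in `counts`
random_edge_graph <- function(n_contigs, n_edges, counts = 1:3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("c%02d", seq_len(n_contigs))
  ends <- expand.grid(a = seq_len(2 * n_contigs), b = seq_len(2 * n_contigs))
  ends <- ends[ends$a < ends$b, ]
  key <- function(i) list(contig = ids[(i + 1) %/% 2], end = if (i %% 2 == 1) "head" else "tail")
  ok <- vapply(seq_len(nrow(ends)), function(r) {
    key(ends$a[r])$contig != key(ends$b[r])$contig
  }, logical(1))
  ends <- ends[ok, ]
  pick <- ends[sample(nrow(ends), min(n_edges, nrow(ends))), ]
  rows <- lapply(seq_len(nrow(pick)), function(r) {
    ea <- key(pick$a[r]); eb <- key(pick$b[r])
    edge_df(list(c(ea$contig, ea$end, eb$contig, eb$end), sample(counts, 1)))
  })
  do.call(rbind, rows)
}
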