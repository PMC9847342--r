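# Tandem-array based assembly diagnostics: an exact tandem-repeat scanner,
# telomere and centromere calls, AT-dinucleotide contig-end classification and
# Nx assembly statistics.
#
# Unit matching is rotation- and strand-invariant via canonical_unit(), since
# a repeat finder may report any rotation of either strand of the same array.

#' Canonical form of a repeat unit
#'
#' The lexicographically smallest string among all rotations of the unit and
#' all rotations of its reverse complement. Both `"TA"` and `"AT"` map to
#' `"AT"`; both telomere motifs `"CCCTAAA"` and `"TTTAGGG"` map to
#' `"AAACCCT"`.
#'
#' @param unit Non-empty character unit over `{A,C,G,T}`.
#' @return The canonical unit string.
#' @export
canonical_unit <- function(unit) {
  if (length(unit) != 1L || is.na(unit) || !nzchar(unit) || grepl("[^ACGT]", unit)) {
    abort_alphabet(sprintf("repeat unit must be a non-empty string over A,C,G,T: '%s'", unit))
  }
  n <- nchar(unit)
  rots <- function(u) substring(strrep(u, 2L), 1:n, n:(2L * n - 1L))
  min(c(rots(unit), rots(revcomp_chr(unit))))
}

# vectorized canonical units with memoisation over distinct inputs
canonical_units <- function(units) {
  u <- unique(units)
  canon <- vapply(u, canonical_unit, character(1))
  unname(canon[match(units, u)])
}

#' Scan sequences for exact tandem-repeat arrays
#'
#' A self-contained exact-array scanner: for each period `p <= max_unit`,
#' maximal runs satisfying `seq[i] == seq[i + p]` define arrays (partial
#' trailing copies included). Arrays are reported when `copies = span / p`
#' reaches `min_copies` and the span reaches `min_span`; an array reportable
#' at several periods is reported once, at its smallest period. This is a
#' stand-in for an approximate-repeat finder such as TRF, whose `.dat` output
#' can be used instead via [parse_trf_dat()].
#'
#' @param seqs A named `DNAStringSet` or named character vector.
#' @param max_unit Largest repeat period to scan (bp).
#' @param min_copies Minimum copy number (fraction allowed).
#' @param min_span Minimum array span (bp).
#' @return A tandem-array data.frame (`seq_id`, `start`, `end`, `period`,
#'   `copies`, `unit`, `score`); coordinates 0-based half-open.
#' @export
scan_tandem_arrays <- function(seqs, max_unit = 10, min_copies = 2, min_span = 1) {
  if (max_unit < 1) abort_parameter("max_unit must be >= 1")
  if (!is.character(seqs)) seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs))) abort_input("sequences must be named")
  out <- vector("list", 0L)
  for (id in names(seqs)) {
    s <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
    n <- length(s)
    found <- empty_tandem()
    for (p in seq_len(min(max_unit, n - 1L))) {
      m <- s[seq_len(n - p)] == s[(p + 1L):n]
      r <- rle(m)
      pos <- cumsum(c(1L, r$lengths))
      runs <- which(r$values)
      for (ri in runs) {
        i0 <- pos[ri]                       # 1-based first matching offset
        L <- r$lengths[ri]
        start <- i0 - 1L                    # 0-based
        end <- start + L + p                # half-open
        span <- L + p
        if (span / p < min_copies || span < min_span) next
        if (nrow(found) && any(found$start <= start & found$end >= end)) next
        found <- rbind(found, data.frame(
          seq_id = id, start = start, end = end, period = p,
          copies = span / p, unit = paste(s[(start + 1L):(start + p)], collapse = ""),
          score = NA_real_, stringsAsFactors = FALSE))
      }
    }
    out[[length(out) + 1L]] <- found
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect telomeres at sequence ends
#'
#' A head call is made when a tandem array whose canonical unit equals the
#' canonical telomere motif, of length at least `min_array_len`, intersects
#' the first `end_window` bases; a tail call symmetrically for the last
#' `end_window` bases. At most one call per sequence end (the longest
#' qualifying array wins).
#'
#' @param arrays Tandem-array data.frame (scanner or TRF output).
#' @param seq_lengths Named numeric vector of sequence lengths.
#' @param motif Telomere motif (either strand / any rotation).
#' @param end_window Terminal window size (bp).
#' @param min_array_len Minimum qualifying array length (bp).
#' @return data.frame of calls: `seq_id`, `end` (head/tail), `array_start`,
#'   `array_end`, `array_len`.
#' @export
detect_telomeres <- function(arrays, seq_lengths, motif = "CCCTAAA",
                             end_window = 10000, min_array_len = 500) {
  empty <- data.frame(seq_id = character(), end = character(),
                      array_start = numeric(), array_end = numeric(),
                      array_len = numeric(), stringsAsFactors = FALSE)
  if (nrow(arrays) == 0L) return(empty)
  unknown <- setdiff(unique(arrays$seq_id), names(seq_lengths))
  if (length(unknown)) abort_input(sprintf("array on unknown sequence: %s", unknown[1]))
  target <- canonical_unit(motif)
  cand <- arrays[nchar(arrays$unit) == nchar(motif), , drop = FALSE]
  if (nrow(cand)) cand <- cand[canonical_units(cand$unit) == target, , drop = FALSE]
  cand <- cand[cand$end - cand$start >= min_array_len, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  lens <- seq_lengths[cand$seq_id]
  with_label <- function(df, lab) {
    df$end_label <- rep(lab, nrow(df))
    df
  }
  calls <- rbind(
    with_label(cand[cand$start < end_window, , drop = FALSE], "head"),
    with_label(cand[cand$end > lens - end_window, , drop = FALSE], "tail"))
  if (nrow(calls) == 0L) return(empty)
  calls$array_len <- calls$end - calls$start
  key <- paste(calls$seq_id, calls$end_label)
  best <- unlist(lapply(split(seq_len(nrow(calls)), key), function(i) {
    i[which.max(calls$array_len[i])]
  }))
  calls <- calls[best, , drop = FALSE]
  res <- data.frame(seq_id = calls$seq_id, end = calls$end_label,
                    array_start = calls$start, array_end = calls$end,
                    array_len = calls$array_len, stringsAsFactors = FALSE)
  res <- res[order(res$seq_id, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Telomere completeness percentage
#'
#' The percentage of sequence ends (two per sequence) carrying a telomere
#' call, rounded half away from zero to 2 decimals.
#'
#' @param n_sequences Number of sequences (chromosomes).
#' @param n_called_ends Number of ends with a telomere call.
#' @return Percentage (0-100).
#' @export
telomere_completeness <- function(n_sequences, n_called_ends) {
  if (n_sequences < 1) abort_parameter("n_sequences must be >= 1")
  if (n_called_ends < 0 || n_called_ends > 2 * n_sequences) {
    abort_parameter("n_called_ends must be between 0 and 2 * n_sequences")
  }
  round_half_out(100 * n_called_ends / (2 * n_sequences), 2)
}

#' Detect centromeric satellite clusters
#'
#' Per sequence, arrays whose period is within `period_tol` of
#' `target_period` are selected; selected spans closer than `merge_dist` are
#' merged, and one call is emitted per merged cluster whose summed array
#' length exceeds `min_total` (strict). The defaults encode a 126 bp
#' satellite unit with a 0.7 Mb total-length cutoff.
#'
#' @param arrays Tandem-array data.frame.
#' @param target_period Satellite unit size (bp).
#' @param period_tol Allowed deviation from `target_period` (bp).
#' @param merge_dist Maximum distance (bp) between arrays in one cluster.
#' @param min_total Minimum summed array length (bp, strict).
#' @return data.frame of calls: `seq_id`, `start`, `end`, `total_array_len`,
#'   `mean_period`, `n_arrays`.
#' @export
detect_centromeres <- function(arrays, target_period = 126, period_tol = 5,
                               merge_dist = 10000, min_total = 7e5) {
  empty <- data.frame(seq_id = character(), start = numeric(), end = numeric(),
                      total_array_len = numeric(), mean_period = numeric(),
                      n_arrays = integer(), stringsAsFactors = FALSE)
  sel <- arrays[abs(arrays$period - target_period) <= period_tol, , drop = FALSE]
  if (nrow(sel) == 0L) return(empty)
  out <- vector("list", 0L)
  for (id in unique(sel$seq_id)) {
    a <- sel[sel$seq_id == id, , drop = FALSE]
    a <- a[order(a$start, a$end), , drop = FALSE]
    cl <- cumsum(c(TRUE, a$start[-1] - cummax(a$end)[-nrow(a)] >= merge_dist))
    for (g in split(seq_len(nrow(a)), cl)) {
      lens <- a$end[g] - a$start[g]
      total <- sum(lens)
      if (total <= min_total) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = id, start = min(a$start[g]), end = max(a$end[g]),
        total_array_len = total,
        mean_period = sum(a$period[g] * lens) / total,
        n_arrays = length(g), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' AT-end percentages from class counts
#'
#' @param n0,n1,n2 Contig counts with AT tandem arrays at 0, 1 and 2 ends.
#' @return List with `pct_with_at_ends` (= classes 1+2) and `pct_without`
#'   (= class 0), both rounded half away from zero to 2 decimals.
#' @export
at_end_percentages <- function(n0, n1, n2) {
  total <- n0 + n1 + n2
  if (total < 1) abort_parameter("class counts sum to zero")
  list(pct_with_at_ends = round_half_out(100 * (n1 + n2) / total, 2),
       pct_without = round_half_out(100 * n0 / total, 2))
}

#' Classify contigs by AT tandem arrays at their ends
#'
#' An end counts as an AT end when an array whose canonical unit is `"AT"`
#' intersects its terminal `end_window`. Contigs fall in classes 0, 1 or 2
#' (number of AT ends); per-class Nx curves describe how contig length
#' distributions differ between classes.
#'
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param arrays Tandem-array data.frame.
#' @param end_window Terminal window (bp).
#' @return List: `classes` (named integer per contig), `n0`, `n1`, `n2`,
#'   `pct_with_at_ends`, `pct_without`, `nx_by_class` (list of Nx vectors,
#'   `NULL` for empty classes).
#' @export
classify_at_ends <- function(contig_lengths, arrays, end_window = 1000) {
  if (nrow(arrays)) {
    unknown <- setdiff(unique(arrays$seq_id), names(contig_lengths))
    if (length(unknown)) abort_input(sprintf("array on unknown contig: %s", unknown[1]))
  }
  ids <- names(contig_lengths)
  head_at <- tail_at <- character(0)
  if (nrow(arrays)) {
    at <- arrays[canonical_units(arrays$unit) == "AT", , drop = FALSE]
    if (nrow(at)) {
      lens <- contig_lengths[at$seq_id]
      head_at <- unique(at$seq_id[at$start < end_window])
      tail_at <- unique(at$seq_id[at$end > lens - end_window])
    }
  }
  classes <- stats::setNames((ids %in% head_at) + (ids %in% tail_at), ids)
  n <- tabulate(classes + 1L, nbins = 3L)
  pct <- at_end_percentages(n[1], n[2], n[3])
  nx_by_class <- lapply(0:2, function(cl) {
    l <- contig_lengths[classes == cl]
    if (length(l)) nx_curve(l) else NULL
  })
  names(nx_by_class) <- c("at_ends_0", "at_ends_1", "at_ends_2")
  list(classes = classes, n0 = n[1], n1 = n[2], n2 = n[3],
       pct_with_at_ends = pct$pct_with_at_ends, pct_without = pct$pct_without,
       nx_by_class = nx_by_class)
}

#' Nx curve of a length set
#'
#' `Nx(x)` is the length `L` such that sequences of length `>= L` cover at
#' least `x` percent of the total (descending cumulative sum).
#'
#' @param lengths Numeric vector of sequence lengths.
#' @param x Percent grid (default 1..100).
#' @return Named numeric vector of Nx values.
#' @export
nx_curve <- function(lengths, x = 1:100) {
  if (!length(lengths)) abort_input("Nx of an empty length set")
  l <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(l)
  total <- cs[length(cs)]
  stats::setNames(vapply(x, function(p) l[which(cs >= p / 100 * total)[1]], numeric(1)),
                  as.character(x))
}

#' Assembly and tandem-repeat summary statistics
#'
#' Computes the Nx curve of the assembly, the tandem-repeat content as the
#' per-sequence union of array spans (overlaps counted once), and the N50 of
#' individual array lengths.
#'
#' @param lengths Numeric vector of sequence lengths (named if `arrays` are
#'   supplied).
#' @param arrays Optional tandem-array data.frame.
#' @return List: `total`, `n`, `nx` (named vector), `n50`, and with arrays
#'   `tandem_bp`, `tandem_pct` (2 decimals), `tandem_n50`.
#' @export
assembly_stats <- function(lengths, arrays = NULL) {
  if (!length(lengths)) abort_input("assembly_stats needs at least one length")
  nx <- nx_curve(lengths)
  res <- list(total = sum(lengths), n = length(lengths), nx = nx, n50 = unname(nx["50"]))
  if (!is.null(arrays) && nrow(arrays)) {
    tandem_bp <- 0
    for (id in unique(arrays$seq_id)) {
      a <- arrays[arrays$seq_id == id, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(start = a$start + 1, end = a$end))
      tandem_bp <- tandem_bp + sum(IRanges::width(ir))
    }
    if (tandem_bp > res$total) abort_input("tandem span union exceeds assembly size")
    res$tandem_bp <- tandem_bp
    res$tandem_pct <- round_half_out(100 * tandem_bp / res$total, 2)
    res$tandem_n50 <- unname(nx_curve(arrays$end - arrays$start)["50"])
  } else {
    res$tandem_bp <- 0
    res$tandem_pct <- 0
    res$tandem_n50 <- NA_real_
  }
  res
}
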