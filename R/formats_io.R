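# Readers and writers for the external formats the toolkit touches:
# FASTA (via Biostrings), PAF, Tandem Repeats Finder .dat, GFA 1.0 and AGP 2.1.
#
# Internal coordinates are 0-based, half-open everywhere. Conversion happens
# only at format boundaries: TRF .dat and AGP are 1-based inclusive on disk.

#' Read a validated FASTA file
#'
#' Reads a multi-record FASTA file into a [Biostrings::DNAStringSet].
#' Sequence identifiers are the first whitespace-delimited token of each
#' header and must be unique. Lowercase (soft-masked) input is accepted and
#' uppercased; only the characters `A`, `C`, `G`, `T`, `N` (either case) are
#' allowed. CRLF line endings are tolerated.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` with one element per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("FASTA file not found: %s", path))
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) abort_malformed(sprintf("cannot parse FASTA '%s': %s",
                                                            path, conditionMessage(e))))
  if (length(x) == 0L) abort_malformed(sprintf("no FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) abort_malformed("FASTA record with an empty header")
  if (anyDuplicated(ids)) {
    abort_duplicate(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  s <- as.character(x)
  s <- gsub("[\r\t ]", "", s)
  if (any(!nzchar(s))) abort_malformed(sprintf("empty sequence for record %s", ids[!nzchar(s)][1]))
  bad <- grepl("[^ACGTNacgtn]", s)
  if (any(bad)) abort_alphabet(sprintf("illegal character in sequence of record %s", ids[bad][1]))
  out <- Biostrings::DNAStringSet(toupper(s))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort_input("all sequences must be named before writing FASTA")
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

paf_columns <- c("read_id", "read_len", "read_start", "read_end", "strand",
                 "target_id", "target_len", "target_start", "target_end",
                 "matches", "block_len", "mapq", "tags")

empty_paf <- function() {
  data.frame(read_id = character(), read_len = numeric(), read_start = numeric(),
             read_end = numeric(), strand = character(), target_id = character(),
             target_len = numeric(), target_start = numeric(), target_end = numeric(),
             matches = numeric(), block_len = numeric(), mapq = numeric(),
             tags = character(), stringsAsFactors = FALSE)
}

#' Parse one PAF line
#'
#' Parses a minimap2-style PAF line (12 mandatory tab-separated columns plus
#' optional SAM-style tags, which are retained verbatim). Coordinates are
#' 0-based half-open on both the read and the target, as in the format itself.
#'
#' @param line A single PAF line (trailing CR tolerated).
#' @return A named list with elements `read_id`, `read_len`, `read_start`,
#'   `read_end`, `strand`, `target_id`, `target_len`, `target_start`,
#'   `target_end`, `matches`, `block_len`, `mapq` and `tags` (a single
#'   tab-joined string, `""` when absent).
#' @export
parse_paf_line <- function(line) {
  f <- strsplit(sub("\r$", "", line), "\t", fixed = TRUE)[[1]]
  if (length(f) < 12L) abort_malformed("PAF line has fewer than 12 columns")
  num <- suppressWarnings(as.numeric(f[c(2, 3, 4, 7, 8, 9, 10, 11, 12)]))
  if (anyNA(num)) abort_malformed("non-numeric value in a mandatory PAF column")
  if (!f[5] %in% c("+", "-")) abort_malformed(sprintf("PAF strand must be '+' or '-', got '%s'", f[5]))
  rec <- list(read_id = f[1], read_len = num[1], read_start = num[2], read_end = num[3],
              strand = f[5], target_id = f[6], target_len = num[4],
              target_start = num[5], target_end = num[6],
              matches = num[7], block_len = num[8], mapq = num[9],
              tags = if (length(f) > 12L) paste(f[13:length(f)], collapse = "\t") else "")
  if (!(rec$read_start >= 0 && rec$read_start < rec$read_end && rec$read_end <= rec$read_len)) {
    abort_coordinate(sprintf("invalid read interval [%g,%g) for read %s (length %g)",
                             rec$read_start, rec$read_end, rec$read_id, rec$read_len))
  }
  if (!(rec$target_start >= 0 && rec$target_start < rec$target_end &&
        rec$target_end <= rec$target_len)) {
    abort_coordinate(sprintf("invalid target interval [%g,%g) on %s (length %g)",
                             rec$target_start, rec$target_end, rec$target_id, rec$target_len))
  }
  if (rec$matches > rec$block_len) abort_malformed("PAF matches exceed block length")
  if (rec$mapq < 0 || rec$mapq > 255) abort_malformed("PAF mapq outside 0..255")
  rec
}

#' Read a PAF file
#'
#' @param path Path to a PAF file. Empty lines are skipped; CRLF tolerated.
#' @return A data.frame with one row per alignment record (see
#'   [parse_paf_line()] for columns).
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("PAF file not found: %s", path))
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_paf())
  recs <- lapply(lines, parse_paf_line)
  chr_cols <- c("read_id", "strand", "target_id", "tags")
  cols <- lapply(paf_columns, function(col) {
    mode <- if (col %in% chr_cols) character(1) else numeric(1)
    vapply(recs, function(r) r[[col]], mode)
  })
  names(cols) <- paf_columns
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Write alignments as PAF
#'
#' @param paf A data.frame as returned by [read_paf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- paste(paf$read_id, fmt_int(paf$read_len), fmt_int(paf$read_start),
                 fmt_int(paf$read_end), paf$strand, paf$target_id,
                 fmt_int(paf$target_len), fmt_int(paf$target_start),
                 fmt_int(paf$target_end), fmt_int(paf$matches),
                 fmt_int(paf$block_len), fmt_int(paf$mapq), sep = "\t")
  has_tags <- nzchar(paf$tags %||% character(nrow(paf)))
  if (nrow(paf) && any(has_tags)) {
    lines[has_tags] <- paste(lines[has_tags], paf$tags[has_tags], sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

empty_tandem <- function() {
  data.frame(seq_id = character(), start = numeric(), end = numeric(),
             period = numeric(), copies = numeric(), unit = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Parse Tandem Repeats Finder .dat output
#'
#' Parses the TRF `.dat` dialect: `Sequence: <id>` headers followed by
#' space-separated data rows
#' (`start end period copies consensus_size pct_match pct_indel score A C G T
#' entropy unit array_sequence`). TRF prints 1-based inclusive coordinates;
#' the returned spans are converted to 0-based half-open. Boilerplate lines
#' (program banner, `Parameters:` etc.) are ignored.
#'
#' @param path Path to a TRF `.dat` file.
#' @return A data.frame of tandem arrays with columns `seq_id`, `start`,
#'   `end`, `period`, `copies`, `unit`, `score`.
#' @export
parse_trf_dat <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("TRF .dat file not found: %s", path))
  lines <- sub("\r$", "", readLines(path))
  current <- NA_character_
  rows <- vector("list", 0L)
  for (ln in lines) {
    if (grepl("^Sequence:", ln)) {
      current <- sub("\\s.*$", "", sub("^Sequence:\\s*", "", ln))
      next
    }
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) >= 14L && grepl("^[0-9]+$", f[1]) && grepl("^[0-9]+$", f[2])) {
      if (is.na(current)) abort_malformed("TRF data row before any 'Sequence:' header")
      s <- as.numeric(f[1]); e <- as.numeric(f[2])
      if (e < s) abort_coordinate(sprintf("TRF array end %g before start %g", e, s))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = current, start = s - 1, end = e,
        period = as.numeric(f[3]), copies = as.numeric(f[4]),
        unit = f[14], score = as.numeric(f[8]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_tandem())
  do.call(rbind, rows)
}

#' Write a contig contact graph as GFA 1.0
#'
#' Segments become `S` lines (sequence or `*` plus an `LN` tag); each contact
#' edge becomes an `L` line with a `0M` overlap, a supporting-read count tag
#' `ct:i` and a median-gap tag `gp:i`. Contig-end orientation encoding: the
#' from-segment is `+` when the link leaves its tail and `-` when it leaves
#' its head; the to-segment is `+` when the link enters its head and `-` when
#' it enters its tail. GFA 1.0 cannot express a positive gap in the CIGAR, so
#' the gap length is carried in the `gp:i` tag.
#'
#' @param segments A named `DNAStringSet`, or a named numeric vector of
#'   segment lengths (then sequences are written as `*`).
#' @param edges A contact-edge data.frame (see [aggregate_contacts()]); may
#'   have zero rows.
#' @param path Optional output path.
#' @param include_sequences Write full sequences on `S` lines (only possible
#'   when `segments` carries sequences).
#' @return The GFA text as a single string, invisibly when `path` is given.
#' @export
write_gfa <- function(segments, edges, path = NULL, include_sequences = FALSE) {
  if (is.numeric(segments)) {
    lens <- segments
    seq_chr <- NULL
  } else {
    if (is.character(segments)) segments <- Biostrings::DNAStringSet(segments)
    lens <- stats::setNames(Biostrings::width(segments), names(segments))
    seq_chr <- as.character(segments)
  }
  ids <- names(lens)
  if (is.null(ids)) abort_input("segments must be named")
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$contig_a, edges$contig_b), ids)
    if (length(unknown)) abort_segment(sprintf("edge references unknown segment: %s", unknown[1]))
  }
  fmt_int <- function(x) format(round(x), scientific = FALSE, trim = TRUE)
  s_body <- if (include_sequences && !is.null(seq_chr)) seq_chr else rep("*", length(ids))
  s_lines <- sprintf("S\t%s\t%s\tLN:i:%s", ids, s_body, fmt_int(lens))
  l_lines <- character(0)
  if (nrow(edges)) {
    from_or <- ifelse(edges$end_a == "tail", "+", "-")
    to_or <- ifelse(edges$end_b == "head", "+", "-")
    gp <- if ("gap_median" %in% names(edges)) edges$gap_median else rep(0, nrow(edges))
    l_lines <- sprintf("L\t%s\t%s\t%s\t%s\t0M\tct:i:%s\tgp:i:%s",
                       edges$contig_a, from_or, edges$contig_b, to_or,
                       fmt_int(edges$count), fmt_int(gp))
  }
  txt <- paste0(paste(c("H\tVN:Z:1.0", s_lines, l_lines), collapse = "\n"), "\n")
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}

#' Serialize scaffold paths as AGP 2.1 rows
#'
#' Contigs become `W` component rows and inter-contig gaps become `N` rows
#' with gap type `scaffold` and linkage `yes`. Object coordinates are 1-based
#' inclusive and contiguous. The linkage evidence defaults to `map`, the
#' closest AGP 2.1 vocabulary for long-range read linkage.
#'
#' @param paths A list of scaffold paths (see [extract_paths()]).
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param gap_evidence Linkage evidence string for `N` rows.
#' @param path Optional output path (tab-separated, with an
#'   `##agp-version 2.1` pragma line).
#' @return A data.frame of AGP rows with columns `object`, `object_beg`,
#'   `object_end`, `part_number`, `component_type`, `component_id`,
#'   `component_beg`, `component_end`, `orientation` (the last four columns
#'   hold `gap_length`, `gap_type`, `linkage`, `linkage_evidence` on N rows).
#' @export
write_agp <- function(paths, contig_lengths, gap_evidence = "map", path = NULL) {
  rows <- vector("list", 0L)
  for (p in paths) {
    pos <- 0
    part <- 1L
    k <- length(p$contigs)
    for (i in seq_len(k)) {
      id <- p$contigs[i]
      if (!id %in% names(contig_lengths)) {
        abort_segment(sprintf("contig %s has no known length", id))
      }
      len <- contig_lengths[[id]]
      rows[[length(rows) + 1L]] <- data.frame(
        object = p$scaffold_id, object_beg = pos + 1, object_end = pos + len,
        part_number = part, component_type = "W", component_id = id,
        component_beg = "1", component_end = as.character(len),
        orientation = p$orientations[i], stringsAsFactors = FALSE)
      pos <- pos + len
      part <- part + 1L
      if (i < k) {
        g <- p$gaps[i]
        rows[[length(rows) + 1L]] <- data.frame(
          object = p$scaffold_id, object_beg = pos + 1, object_end = pos + g,
          part_number = part, component_type = "N", component_id = as.character(g),
          component_beg = "scaffold", component_end = "yes",
          orientation = gap_evidence, stringsAsFactors = FALSE)
        pos <- pos + g
        part <- part + 1L
      }
    }
  }
  agp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object = character(), object_beg = numeric(), object_end = numeric(),
               part_number = integer(), component_type = character(),
               component_id = character(), component_beg = character(),
               component_end = character(), orientation = character(),
               stringsAsFactors = FALSE)
  if (!is.null(path)) {
    fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)
    lines <- c("##agp-version\t2.1",
               if (nrow(agp)) paste(agp$object, fmt_int(agp$object_beg), fmt_int(agp$object_end),
                                    agp$part_number, agp$component_type, agp$component_id,
                                    agp$component_beg, agp$component_end, agp$orientation,
                                    sep = "\t"))
    writeLines(lines, path)
  }
  agp
}
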