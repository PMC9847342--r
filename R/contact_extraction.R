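# From per-read PAF alignments to contig-end contacts.
#
# A read that aligns near the ends of two different contigs is evidence that
# those two contig ends are adjacent in the genome. Each surviving adjacent
# alignment pair on a read contributes one EndContact carrying a per-read gap
# estimate; contacts are then aggregated into weighted contact-graph edges.

empty_contacts <- function() {
  data.frame(read_id = character(), left_contig = character(), left_end = character(),
             right_contig = character(), right_end = character(), gap = numeric(),
             stringsAsFactors = FALSE)
}

#' Classify how close an alignment sits to its contig's ends
#'
#' An alignment supports linkage through a contig end only if it reaches into
#' the terminal `max_end_distance` of that contig; alignments confined to the
#' interior ("inner" alignments) are evidence of nothing and are dropped.
#'
#' @param aln A single PAF alignment (list or one-row data.frame).
#' @param max_end_distance Maximum distance (bp) from a contig end for the
#'   alignment to count as reaching that end.
#' @return A character vector that is a subset of `c("head", "tail")`;
#'   length 0 means an inner alignment.
#' @export
classify_end_proximity <- function(aln, max_end_distance = 20000) {
  if (max_end_distance < 0) abort_parameter("max_end_distance must be non-negative")
  res <- character(0)
  if (aln$target_start <= max_end_distance) res <- c(res, "head")
  if (aln$target_len - aln$target_end <= max_end_distance) res <- c(res, "tail")
  res
}

# Vectorized core shared by contacts_from_read and extract_contacts:
# filter -> sort along each read -> collapse same-contig/strand runs ->
# emit each adjacent pair whose facing ends both reach a contig end.
contacts_core <- function(paf, max_end_distance, min_mapq, min_block) {
  if (max_end_distance < 0) abort_parameter("max_end_distance must be non-negative")
  n0 <- nrow(paf)
  if (n0 == 0L) return(empty_contacts())
  tags <- paf$tags %||% rep("", n0)
  keep <- paf$mapq >= min_mapq & paf$block_len >= min_block &
    !grepl("tp:A:S", tags, fixed = TRUE)
  a <- paf[keep, , drop = FALSE]
  n <- nrow(a)
  if (n < 2L) return(empty_contacts())
  a <- a[order(match(a$read_id, unique(a$read_id)), a$read_start, a$read_end), , drop = FALSE]

  new_read <- c(TRUE, a$read_id[-1] != a$read_id[-n])
  changed <- c(TRUE, a$target_id[-1] != a$target_id[-n] | a$strand[-1] != a$strand[-n])
  new_run <- new_read | changed
  fi <- which(new_run)
  li <- c(fi[-1] - 1L, n)

  # collapse: outermost read/target coordinates per run (reads are sorted by
  # read_start, so the first element of a run carries its minimum read_start)
  read_id <- a$read_id[fi]
  read_start <- a$read_start[fi]
  read_end <- a$read_end[fi]
  strand <- a$strand[fi]
  target_id <- a$target_id[fi]
  target_len <- a$target_len[fi]
  target_start <- a$target_start[fi]
  target_end <- a$target_end[fi]
  for (g in which(li > fi)) {
    idx <- fi[g]:li[g]
    read_end[g] <- max(a$read_end[idx])
    target_start[g] <- min(a$target_start[idx])
    target_end[g] <- max(a$target_end[idx])
  }

  m <- length(fi)
  if (m < 2L) return(empty_contacts())
  i <- seq_len(m - 1L)
  j <- i + 1L
  exit <- ifelse(strand[i] == "+", "tail", "head")
  entry <- ifelse(strand[j] == "+", "head", "tail")
  ov_i <- ifelse(exit == "head", target_start[i], target_len[i] - target_end[i])
  ov_j <- ifelse(entry == "head", target_start[j], target_len[j] - target_end[j])
  emit <- read_id[i] == read_id[j] &
    target_id[i] != target_id[j] &
    ov_i <= max_end_distance &
    ov_j <= max_end_distance
  if (!any(emit)) return(empty_contacts())
  i <- i[emit]; j <- j[emit]
  gap <- (read_start[j] - read_end[i]) - ov_i[emit] - ov_j[emit]
  lk <- end_key(target_id[i], exit[emit])
  rk <- end_key(target_id[j], entry[emit])
  swap <- lk > rk
  data.frame(read_id = read_id[i],
             left_contig = ifelse(swap, target_id[j], target_id[i]),
             left_end = ifelse(swap, entry[emit], exit[emit]),
             right_contig = ifelse(swap, target_id[i], target_id[j]),
             right_end = ifelse(swap, exit[emit], entry[emit]),
             gap = gap, stringsAsFactors = FALSE)
}

#' Derive contig-end contacts from one read's alignments
#'
#' Implements the per-read filtering and head/tail tagging: alignments below
#' the mapq or block-length thresholds (and minimap2 secondary alignments,
#' marked `tp:A:S`) are dropped; survivors are sorted along the read;
#' consecutive alignments to the same contig (and strand) are collapsed to
#' their outermost coordinates; and every adjacent pair whose facing ends
#' both pass [classify_end_proximity()] yields one contact. Reads left with a
#' single contig yield nothing. The per-read gap estimate is the unaligned
#' read length between the two alignments minus the unaligned contig
#' overhangs on both sides; it may be negative (probable overlap) and is kept
#' raw here so the downstream median sees all evidence.
#'
#' @param alignments data.frame of PAF records sharing one `read_id`.
#' @param max_end_distance See [classify_end_proximity()].
#' @param min_mapq Minimum mapping quality.
#' @param min_block Minimum alignment block length (bp).
#' @return data.frame of contacts with columns `read_id`, `left_contig`,
#'   `left_end`, `right_contig`, `right_end`, `gap`; the lexicographically
#'   smaller (contig, end) is stored on the left.
#' @export
contacts_from_read <- function(alignments, max_end_distance = 20000,
                               min_mapq = 10, min_block = 1000) {
  if (nrow(alignments) && length(unique(alignments$read_id)) > 1L) {
    abort_input("contacts_from_read received alignments from more than one read")
  }
  contacts_core(alignments, max_end_distance, min_mapq, min_block)
}

#' Derive contacts from a whole PAF table
#'
#' Applies the per-read contact logic of [contacts_from_read()] to every read
#' in the table (alignments need not be grouped; they are sorted internally).
#'
#' @param paf data.frame as returned by [read_paf()].
#' @inheritParams contacts_from_read
#' @return data.frame of contacts (see [contacts_from_read()]).
#' @export
extract_contacts <- function(paf, max_end_distance = 20000,
                             min_mapq = 10, min_block = 1000) {
  contacts_core(paf, max_end_distance, min_mapq, min_block)
}

#' Aggregate contacts into contact-graph edges
#'
#' One edge per canonical end pair, carrying the supporting-read count and the
#' per-read gap estimates in input order, plus their median (`gap_median`,
#' unclamped; clamping happens at scaffold emission). Self pairs (both ends on
#' the same contig) are never emitted.
#'
#' @param contacts data.frame of contacts (see [contacts_from_read()]).
#' @return data.frame of edges with columns `contig_a`, `end_a`, `contig_b`,
#'   `end_b`, `count`, `gaps` (list column), `gap_median`.
#' @export
aggregate_contacts <- function(contacts) {
  empty <- data.frame(contig_a = character(), end_a = character(),
                      contig_b = character(), end_b = character(),
                      count = integer(), gap_median = numeric(),
                      stringsAsFactors = FALSE)
  empty$gaps <- list()
  if (nrow(contacts) == 0L) return(empty)
  contacts <- contacts[contacts$left_contig != contacts$right_contig, , drop = FALSE]
  if (nrow(contacts) == 0L) return(empty)
  key <- paste(contacts$left_contig, contacts$left_end,
               contacts$right_contig, contacts$right_end, sep = "\r")
  f <- factor(key, levels = unique(key))
  idx <- split(seq_len(nrow(contacts)), f)
  first <- vapply(idx, `[`, integer(1), 1L)
  edges <- data.frame(contig_a = contacts$left_contig[first],
                      end_a = contacts$left_end[first],
                      contig_b = contacts$right_contig[first],
                      end_b = contacts$right_end[first],
                      count = vapply(idx, length, integer(1)),
                      stringsAsFactors = FALSE)
  edges$gaps <- lapply(idx, function(i) contacts$gap[i])
  edges$gap_median <- vapply(edges$gaps, median_half_out, numeric(1))
  rownames(edges) <- NULL
  edges
}

#' Write contacts as a TSV for inspection
#'
#' Columns: `read_id`, `left`, `right`, `gap`, with ends rendered as
#' `contig:head` / `contig:tail`.
#'
#' @param contacts data.frame of contacts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(contacts, path) {
  df <- data.frame(read_id = contacts$read_id,
                   left = end_key(contacts$left_contig, contacts$left_end),
                   right = end_key(contacts$right_contig, contacts$right_end),
                   gap = contacts$gap, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
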