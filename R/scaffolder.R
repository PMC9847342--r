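# Contact-graph filtering and simplification, path extraction, gap sizing and
# scaffold emission.
#
# The graph lives on contig *ends* (head = coordinate-0 side, tail =
# coordinate-length side), so an edge between two ends simultaneously encodes
# adjacency and relative orientation. After the reciprocal-best filter and
# branch/cycle simplification every end has degree <= 1, which makes each
# component a simple contig chain.

edge_keys <- function(edges) {
  list(a = end_key(edges$contig_a, edges$end_a),
       b = end_key(edges$contig_b, edges$end_b))
}

edge_pair_keys <- function(edges) {
  pair_key(edges$contig_a, edges$end_a, edges$contig_b, edges$end_b)
}

#' Filter contact edges by support and reciprocal-best linkage
#'
#' Drops edges supported by fewer than `min_contacts` reads. With
#' `reciprocal_max`, an edge is then kept only if its count is the strict
#' unique maximum among surviving edges incident to *both* of its ends
#' (a tie disqualifies every tied edge), after which every contig end has
#' degree at most 1.
#'
#' @param edges Contact-edge data.frame (see [aggregate_contacts()]).
#' @param min_contacts Minimum supporting-read count (>= 1).
#' @param reciprocal_max Apply the reciprocal-best-end filter.
#' @return The surviving edges; dropped edges and reasons are recorded in the
#'   `"dropped"` attribute as a data.frame (`edge`, `reason`).
#' @export
filter_edges <- function(edges, min_contacts = 2, reciprocal_max = TRUE) {
  if (min_contacts < 1) abort_parameter("min_contacts must be >= 1")
  dropped <- data.frame(edge = character(), reason = character(), stringsAsFactors = FALSE)
  if (nrow(edges)) {
    low <- edges$count < min_contacts
    if (any(low)) {
      dropped <- rbind(dropped, data.frame(edge = edge_pair_keys(edges[low, , drop = FALSE]),
                                           reason = sprintf("count below min_contacts=%g", min_contacts),
                                           stringsAsFactors = FALSE))
    }
    edges <- edges[!low, , drop = FALSE]
  }
  if (reciprocal_max && nrow(edges)) {
    k <- edge_keys(edges)
    ok <- vapply(seq_len(nrow(edges)), function(i) {
      inc_a <- setdiff(which(k$a == k$a[i] | k$b == k$a[i]), i)
      inc_b <- setdiff(which(k$a == k$b[i] | k$b == k$b[i]), i)
      all(edges$count[i] > edges$count[inc_a]) && all(edges$count[i] > edges$count[inc_b])
    }, logical(1))
    if (any(!ok)) {
      dropped <- rbind(dropped, data.frame(edge = edge_pair_keys(edges[!ok, , drop = FALSE]),
                                           reason = "not the reciprocal strict maximum",
                                           stringsAsFactors = FALSE))
    }
    edges <- edges[ok, , drop = FALSE]
  }
  rownames(edges) <- NULL
  attr(edges, "dropped") <- dropped
  edges
}

# connected components over contigs; each element lists edge indices
contig_components <- function(edges) {
  contigs <- unique(c(edges$contig_a, edges$contig_b))
  parent <- stats::setNames(contigs, contigs)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$contig_a[i]); rb <- find(edges$contig_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots_e <- vapply(seq_len(nrow(edges)), function(i) find(edges$contig_a[i]), character(1))
  roots_c <- vapply(contigs, find, character(1))
  list(edge_groups = split(seq_len(nrow(edges)), roots_e),
       contig_groups = split(contigs, roots_c))
}

#' Simplify a contact graph to simple paths
#'
#' Two deterministic passes: (i) branch removal — at any contig end with
#' degree > 1, keep the highest-count incident edge; if the maximum is tied,
#' remove *all* edges at that end; (ii) cycle breaking — every remaining
#' cycle loses its minimum-count edge (ties broken by the lexicographically
#' smallest canonical edge key). The result is a disjoint union of simple
#' paths over contig-end nodes.
#'
#' @param edges Contact-edge data.frame.
#' @return The surviving edges, with removed edges recorded in the
#'   `"dropped"` attribute.
#' @export
simplify_graph <- function(edges) {
  dropped <- data.frame(edge = character(), reason = character(), stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    attr(edges, "dropped") <- dropped
    return(edges)
  }
  k <- edge_keys(edges)
  remove <- rep(FALSE, nrow(edges))
  for (key in unique(c(k$a, k$b))) {
    inc <- which(k$a == key | k$b == key)
    if (length(inc) > 1L) {
      mx <- max(edges$count[inc])
      winners <- inc[edges$count[inc] == mx]
      if (length(winners) == 1L) remove[setdiff(inc, winners)] <- TRUE else remove[inc] <- TRUE
    }
  }
  if (any(remove)) {
    dropped <- rbind(dropped, data.frame(edge = edge_pair_keys(edges[remove, , drop = FALSE]),
                                         reason = "branch edge", stringsAsFactors = FALSE))
  }
  e <- edges[!remove, , drop = FALSE]

  # after branch removal each end has degree <= 1, so a component of n contigs
  # has either n-1 edges (path) or n edges (one cycle)
  if (nrow(e)) {
    comp <- contig_components(e)
    cut <- integer(0)
    for (r in names(comp$edge_groups)) {
      ei <- comp$edge_groups[[r]]
      nc <- length(comp$contig_groups[[r]])
      if (length(ei) == nc) {
        counts <- e$count[ei]
        cand <- ei[counts == min(counts)]
        if (length(cand) > 1L) cand <- cand[order(edge_pair_keys(e[cand, , drop = FALSE]))][1]
        cut <- c(cut, cand)
      }
    }
    if (length(cut)) {
      dropped <- rbind(dropped, data.frame(edge = edge_pair_keys(e[cut, , drop = FALSE]),
                                           reason = "weakest link in cycle",
                                           stringsAsFactors = FALSE))
      e <- e[-cut, , drop = FALSE]
    }
  }
  rownames(e) <- NULL
  attr(e, "dropped") <- dropped
  e
}

#' Median-based gap estimate for one edge
#'
#' The estimated gap between two linked contig ends is the median of the
#' per-read gap estimates (even cardinality: arithmetic mean of the two
#' central values, rounded half away from zero), clamped up to `min_gap`.
#' Negative medians indicate probable overlap, but contigs are never merged.
#'
#' @param gap_estimates Numeric vector of per-read gap estimates (bp); an
#'   edge data.frame row's `gaps[[1]]`.
#' @param min_gap Minimum emitted gap (bp).
#' @return The clamped median gap (bp).
#' @export
estimate_gap <- function(gap_estimates, min_gap = 10) {
  if (is.list(gap_estimates)) gap_estimates <- unlist(gap_estimates)
  if (!length(gap_estimates)) abort_input("estimate_gap needs at least one gap estimate")
  max(min_gap, median_half_out(gap_estimates))
}

# gap for one traversed edge row, tolerating edges built without raw estimates
edge_gap <- function(edge_row, min_gap) {
  g <- edge_row$gaps
  if (!is.null(g)) {
    g <- g[[1]]
    if (length(g)) return(estimate_gap(g, min_gap))
  }
  if (!is.null(edge_row$gap_median) && length(edge_row$gap_median) &&
      !is.na(edge_row$gap_median)) {
    return(max(min_gap, edge_row$gap_median))
  }
  min_gap
}

#' Extract ordered, oriented scaffold paths
#'
#' Walks each connected component of a simplified contact graph from a
#' degree-1 contig. Orientation algebra: the first contig is `+` when exited
#' via its tail (else `-`); every subsequent contig is `+` when entered via
#' its head (else `-`). The canonical traversal direction is the one whose
#' first contig id sorts before the last's. Candidate scaffolds whose summed
#' contig length (gaps excluded) is below `min_scaffold_len` are dissolved and
#' their contigs returned as leftovers, together with all unlinked contigs.
#'
#' @param edges Simplified contact-edge data.frame (simple paths only).
#' @param contig_lengths Named numeric vector of contig lengths; its names
#'   define the contig universe.
#' @param min_scaffold_len Minimum summed contig length (bp) for a scaffold.
#' @param min_gap Minimum emitted gap (bp), see [estimate_gap()].
#' @return A list with `paths` (list of scaffold paths: `scaffold_id`,
#'   `contigs`, `orientations`, `gaps`, `contig_span`) and `leftovers`
#'   (character vector of contig ids).
#' @export
extract_paths <- function(edges, contig_lengths, min_scaffold_len = 2e6, min_gap = 10) {
  universe <- names(contig_lengths)
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$contig_a, edges$contig_b), universe)
    if (length(unknown)) abort_segment(sprintf("edge references unknown contig: %s", unknown[1]))
    k <- edge_keys(edges)
    if (anyDuplicated(c(k$a, k$b))) {
      abort_graphstate("a contig end has degree > 1; run simplify_graph first")
    }
  }
  paths <- list()
  leftovers <- character(0)
  if (nrow(edges)) {
    comp <- contig_components(edges)
    # incident edges per end key
    k <- edge_keys(edges)
    for (r in names(comp$edge_groups)) {
      ei <- comp$edge_groups[[r]]
      contigs <- comp$contig_groups[[r]]
      if (length(ei) == length(contigs)) {
        abort_graphstate("component is a cycle, not a simple path; run simplify_graph first")
      }
      # degree per contig
      deg <- table(c(edges$contig_a[ei], edges$contig_b[ei]))
      start <- sort(names(deg)[deg == 1])[1]
      # walk
      ids <- character(0); ors <- character(0); gaps <- numeric(0)
      cur <- start
      prev_edge <- 0L
      first <- TRUE
      repeat {
        inc <- ei[edges$contig_a[ei] == cur | edges$contig_b[ei] == cur]
        inc <- setdiff(inc, prev_edge)
        if (first) {
          e1 <- inc[1]
          conn_end <- if (edges$contig_a[e1] == cur) edges$end_a[e1] else edges$end_b[e1]
          ids <- cur
          ors <- if (conn_end == "tail") "+" else "-"
          first <- FALSE
          next_edge <- e1
        } else if (length(inc) == 0L) {
          break
        } else {
          next_edge <- inc[1]
        }
        # cross next_edge from cur to the other contig
        if (edges$contig_a[next_edge] == cur) {
          nxt <- edges$contig_b[next_edge]; entry <- edges$end_b[next_edge]
        } else {
          nxt <- edges$contig_a[next_edge]; entry <- edges$end_a[next_edge]
        }
        gaps <- c(gaps, edge_gap(edges[next_edge, , drop = FALSE], min_gap))
        ids <- c(ids, nxt)
        ors <- c(ors, if (entry == "head") "+" else "-")
        cur <- nxt
        prev_edge <- next_edge
      }
      # canonical direction: first contig id sorts before the last's
      if (ids[1] > ids[length(ids)]) {
        ids <- rev(ids)
        ors <- rev(ifelse(ors == "+", "-", "+"))
        gaps <- rev(gaps)
      }
      missing <- setdiff(ids, universe)
      if (length(missing)) abort_segment(sprintf("unknown contig in path: %s", missing[1]))
      span <- sum(contig_lengths[ids])
      if (span < min_scaffold_len) {
        leftovers <- c(leftovers, ids)
      } else {
        paths[[length(paths) + 1L]] <- list(scaffold_id = NA_character_, contigs = ids,
                                            orientations = ors, gaps = gaps,
                                            contig_span = span)
      }
    }
  }
  in_paths <- unlist(lapply(paths, `[[`, "contigs"))
  leftovers <- sort(unique(c(leftovers, setdiff(universe, in_paths))))
  if (length(paths)) {
    ord <- order(-vapply(paths, `[[`, numeric(1), "contig_span"),
                 vapply(paths, function(p) p$contigs[1], character(1)))
    paths <- paths[ord]
    for (i in seq_along(paths)) paths[[i]]$scaffold_id <- sprintf("scaffold_%04d", i)
  }
  list(paths = paths, leftovers = leftovers)
}

#' Render scaffold sequences
#'
#' Joins each path's contigs left to right, reverse-complementing `-` parts
#' and rendering gaps as runs of `N` of the clamped length. Leftover contigs
#' are emitted unchanged under their original ids, after the scaffolds.
#'
#' @param paths List of scaffold paths (see [extract_paths()]).
#' @param leftovers Character vector of leftover contig ids.
#' @param contigs Named `DNAStringSet` of contig sequences.
#' @return A `DNAStringSet` of scaffolds followed by leftover contigs.
#' @export
emit_scaffolds <- function(paths, leftovers, contigs) {
  need <- c(unlist(lapply(paths, `[[`, "contigs")), leftovers)
  missing <- setdiff(need, names(contigs))
  if (length(missing)) abort_segment(sprintf("contig missing from sequences: %s", missing[1]))
  out <- character(length(paths) + length(leftovers))
  nms <- character(length(out))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    parts <- character(2L * length(p$contigs) - 1L)
    for (j in seq_along(p$contigs)) {
      s <- contigs[[p$contigs[j]]]
      if (p$orientations[j] == "-") s <- Biostrings::reverseComplement(s)
      parts[2L * j - 1L] <- as.character(s)
      if (j < length(p$contigs)) parts[2L * j] <- strrep("N", p$gaps[j])
    }
    out[i] <- paste(parts, collapse = "")
    nms[i] <- p$scaffold_id
  }
  for (j in seq_along(leftovers)) {
    out[length(paths) + j] <- as.character(contigs[[leftovers[j]]])
    nms[length(paths) + j] <- leftovers[j]
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- nms
  res
}

#' Run the full ultra-long-read scaffolding pipeline
#'
#' PAF alignments -> per-read contacts -> aggregated contact edges ->
#' support/reciprocal filtering -> branch/cycle simplification -> ordered,
#' oriented paths with median gap estimates -> scaffold sequences.
#'
#' @param paf data.frame of alignments (see [read_paf()]).
#' @param contigs Named `DNAStringSet` of contig sequences.
#' @param min_contacts,reciprocal_max See [filter_edges()].
#' @param max_end_distance,min_mapq,min_block See [contacts_from_read()].
#' @param min_scaffold_len,min_gap See [extract_paths()].
#' @return A list: `contacts`, `edges` (raw), `kept_edges` (post filter +
#'   simplify), `paths`, `leftovers`, `scaffolds` (`DNAStringSet`),
#'   `dropped` (edge drop log).
#' @export
scaffold_pipeline <- function(paf, contigs, min_contacts = 2, reciprocal_max = TRUE,
                              max_end_distance = 20000, min_mapq = 10, min_block = 1000,
                              min_scaffold_len = 2e6, min_gap = 10) {
  contig_lengths <- stats::setNames(Biostrings::width(contigs), names(contigs))
  contacts <- extract_contacts(paf, max_end_distance, min_mapq, min_block)
  edges <- aggregate_contacts(contacts)
  filtered <- filter_edges(edges, min_contacts, reciprocal_max)
  simplified <- simplify_graph(filtered)
  dropped <- rbind(attr(filtered, "dropped"), attr(simplified, "dropped"))
  res <- extract_paths(simplified, contig_lengths, min_scaffold_len, min_gap)
  scaffolds <- emit_scaffolds(res$paths, res$leftovers, contigs)
  list(contacts = contacts, edges = edges, kept_edges = simplified,
       paths = res$paths, leftovers = res$leftovers, scaffolds = scaffolds,
       dropped = dropped)
}
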