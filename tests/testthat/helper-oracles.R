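# Independent oracles used to cross-check the implementation.

# quadratic brute-force exact tandem scanner: start-and-extend per position,
# then the smallest-period containment dedup. Compares by (seq span, period).
brute_tandem_spans <- function(seq_chr, max_unit = 10, min_copies = 2, min_span = 1) {
  s <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  n <- length(s)
  rows <- list()
  for (p in seq_len(min(max_unit, n - 1))) {
    i <- 1L
    while (i + p <= n) {
      if (s[i] == s[i + p]) {
        j <- i
        while (j + p <= n && s[j] == s[j + p]) j <- j + 1L
        start <- i - 1L
        end <- start + (j - i) + p
        span <- end - start
        if (span / p >= min_copies && span >= min_span) {
          rows[[length(rows) + 1L]] <- c(start = start, end = end, period = p)
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = numeric(0), end = numeric(0), period = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, rows))
  df <- df[order(df$period, df$start), ]
  keep <- rep(TRUE, nrow(df))
  for (r in seq_len(nrow(df))) {
    prior <- which(df$period < df$period[r] & keep)
    if (any(df$start[prior] <= df$start[r] & df$end[prior] >= df$end[r])) keep[r] <- FALSE
  }
  df <- df[keep, ]
  rownames(df) <- NULL
  df
}

# exhaustive Nx oracle: largest observed length L whose >=L sequences cover
# at least x% of the total
oracle_nx <- function(lengths, x) {
  total <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= x / 100 * total) return(L)
  }
}

# igraph view of a contact graph: vertices are contig ends, with implicit
# internal head--tail edges so cycles through contigs are visible
edges_to_igraph <- function(edges) {
  contigs <- unique(c(edges$contig_a, edges$contig_b))
  verts <- c(paste0(contigs, ":head"), paste0(contigs, ":tail"))
  contact <- cbind(paste0(edges$contig_a, ":", edges$end_a),
                   paste0(edges$contig_b, ":", edges$end_b))
  internal <- cbind(paste0(contigs, ":head"), paste0(contigs, ":tail"))
  igraph::graph_from_data_frame(as.data.frame(rbind(contact, internal)),
                                directed = FALSE, vertices = verts)
}

igraph_has_cycle <- function(g) {
  igraph::ecount(g) > igraph::vcount(g) - igraph::components(g)$no
}

# independent simplification oracle: per-end strongest-edge rule evaluated on
# the input graph, then igraph-detected cycles broken at their weakest edge
oracle_simplify <- function(edges) {
  n <- nrow(edges)
  if (n == 0L) return(edges)
  ka <- paste0(edges$contig_a, ":", edges$end_a)
  kb <- paste0(edges$contig_b, ":", edges$end_b)
  remove <- rep(FALSE, n)
  for (k in unique(c(ka, kb))) {
    inc <- which(ka == k | kb == k)
    if (length(inc) > 1) {
      mx <- max(edges$count[inc])
      winners <- inc[edges$count[inc] == mx]
      if (length(winners) == 1) remove[setdiff(inc, winners)] <- TRUE else remove[inc] <- TRUE
    }
  }
  e <- edges[!remove, , drop = FALSE]
  repeat {
    if (nrow(e) == 0L) break
    g <- edges_to_igraph(e)
    if (!igraph_has_cycle(g)) break
    memb <- igraph::components(g)$membership
    cut <- NULL
    for (cm in unique(memb)) {
      vids <- names(memb)[memb == cm]
      sub <- igraph::induced_subgraph(g, vids)
      if (igraph::ecount(sub) >= igraph::vcount(sub)) {
        eka <- paste0(e$contig_a, ":", e$end_a)
        inside <- which(eka %in% vids)
        counts <- e$count[inside]
        cand <- inside[counts == min(counts)]
        if (length(cand) > 1) {
          keys <- paste(pmin(eka[cand], paste0(e$contig_b, ":", e$end_b)[cand]),
                        pmax(eka[cand], paste0(e$contig_b, ":", e$end_b)[cand]))
          cand <- cand[order(keys)][1]
        }
        cut <- c(cut, cand)
      }
    }
    if (is.null(cut)) break
    e <- e[-cut, , drop = FALSE]
  }
  rownames(e) <- NULL
  e
}

# reciprocal-max oracle via an explicit end-incidence table
oracle_filter <- function(edges, min_contacts, reciprocal_max) {
  e <- edges[edges$count >= min_contacts, , drop = FALSE]
  if (!reciprocal_max || nrow(e) == 0L) return(e)
  ka <- paste0(e$contig_a, ":", e$end_a)
  kb <- paste0(e$contig_b, ":", e$end_b)
  best <- function(k, self) {
    inc <- setdiff(which(ka == k | kb == k), self)
    if (!length(inc)) return(TRUE)
    e$count[self] > max(e$count[inc])
  }
  keep <- vapply(seq_len(nrow(e)), function(i) best(ka[i], i) && best(kb[i], i), logical(1))
  out <- e[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

edge_key_set <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  ka <- paste0(edges$contig_a, ":", edges$end_a)
  kb <- paste0(edges$contig_b, ":", edges$end_b)
  sort(paste(pmin(ka, kb), pmax(ka, kb), edges$count))
}

# multiset of bases per contig id, for conservation checks
base_multiset <- function(seqs) {
  sort(unlist(lapply(as.character(seqs), function(s) {
    sort(strsplit(gsub("N", "", s), "", fixed = TRUE)[[1]])
  }), use.names = FALSE))
}

# canonical base content (forward or reverse complement, whichever sorts
# first) so orientation flips do not matter
seq_content_key <- function(s) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  min(s, rc)
}
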