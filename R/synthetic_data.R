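# Seeded synthetic-data generator: multi-chromosome genomes with planted
# telomere/centromere/AT tandem-repeat arrays, contig fragmentations with true
# gaps and orientation flips, and ultra-long reads whose exact per-contig
# alignments are emitted as PAF — all with full ground truth, so the whole
# scaffolding pipeline is testable hermetically.

TELOMERE_MOTIF <- "CCCTAAA"

# sequences are manipulated as integer UTF-8 code vectors (A=65 C=67 G=71
# T=84) and converted with intToUtf8 only once per chromosome; this keeps
# multi-megabase simulation fast in plain R
DNA_CODES <- c(A = 65L, C = 67L, G = 71L, T = 84L)

rand_dna <- function(n, prob = rep(0.25, 4)) {
  sample(unname(DNA_CODES), n, replace = TRUE, prob = prob)
}

chr_codes <- function(s) utf8ToInt(s)

rep_to_len <- function(unit_chars, len) {
  rep_len(unit_chars, len)
}

#' Simulate a genome with planted repeat features
#'
#' Each chromosome is uniform-random background sequence carrying: telomere
#' motif arrays (`CCCTAAA` units) of `telomere_copies` at both ends, with the
#' tail array reverse-complemented (`TTTAGGG` units); one centromeric array of
#' a random 126 bp unit of total length `centromere_len` near the middle; and
#' `n_at_arrays` interior `AT` dinucleotide arrays of `at_array_len` at random
#' non-overlapping loci. All planted features are recorded in the truth.
#' Deterministic for a fixed seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length (bp).
#' @param telomere_copies Telomere motif copies per end.
#' @param centromere_len Centromeric array length (bp).
#' @param n_at_arrays Number of interior AT arrays per chromosome.
#' @param at_array_len AT array length (bp).
#' @param seed Integer seed; all randomness flows from it.
#' @param at_frac Optional background AT fraction (default uniform base
#'   composition).
#' @return An object of class `synthetic_truth`: list with `genome`
#'   (`DNAStringSet`), `features` (tandem-array data.frame with a `kind`
#'   column) and `params`.
#' @export
simulate_genome <- function(n_chrom = 5, chrom_len = 2e6, telomere_copies = 150,
                            centromere_len = 8e5, n_at_arrays = 20,
                            at_array_len = 5000, seed = 1, at_frac = NULL) {
  if (n_chrom < 1) abort_parameter("n_chrom must be >= 1")
  tel_len <- 7L * telomere_copies
  feature_bp <- 2 * tel_len + centromere_len + n_at_arrays * (at_array_len + 2000) + 4000
  if (feature_bp >= chrom_len) {
    abort_parameter("planted features do not fit in the chromosome length")
  }
  set.seed(seed)
  prob <- if (is.null(at_frac)) rep(0.25, 4) else
    c(at_frac / 2, (1 - at_frac) / 2, (1 - at_frac) / 2, at_frac / 2)
  tel_head <- rep(chr_codes(TELOMERE_MOTIF), telomere_copies)
  tel_tail <- rep(chr_codes(revcomp_chr(TELOMERE_MOTIF)), telomere_copies)
  seqs <- character(n_chrom)
  feats <- vector("list", 0L)
  add_feat <- function(id, start, end, period, unit, kind) {
    feats[[length(feats) + 1L]] <<- data.frame(
      seq_id = id, start = start, end = end, period = period,
      copies = (end - start) / period, unit = unit, score = NA_real_,
      kind = kind, stringsAsFactors = FALSE)
  }
  for (ci in seq_len(n_chrom)) {
    id <- sprintf("Chr%02d", ci)
    L <- chrom_len
    s <- rand_dna(L, prob)
    s[seq_len(tel_len)] <- tel_head
    s[(L - tel_len + 1L):L] <- tel_tail
    add_feat(id, 0, tel_len, 7, TELOMERE_MOTIF, "telomere")
    add_feat(id, L - tel_len, L, 7, revcomp_chr(TELOMERE_MOTIF), "telomere")
    # centromere near the middle, jittered
    cen_unit <- rand_dna(126)
    jit <- sample(seq(-floor(0.02 * L), floor(0.02 * L)), 1)
    cs <- floor(L / 2 - centromere_len / 2) + jit
    cs <- max(tel_len + 2000, min(cs, L - tel_len - 2000 - centromere_len))
    s[(cs + 1L):(cs + centromere_len)] <- rep_to_len(cen_unit, centromere_len)
    add_feat(id, cs, cs + centromere_len, 126, intToUtf8(cen_unit), "centromere")
    occupied <- rbind(c(0, tel_len), c(L - tel_len, L), c(cs, cs + centromere_len))
    at_chars <- rep_to_len(chr_codes("AT"), at_array_len)
    for (k in seq_len(n_at_arrays)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 1000L) abort_parameter("could not place AT arrays without overlap")
        pos <- sample(seq(tel_len + 1000, L - tel_len - 1000 - at_array_len), 1)
        if (all(pos + at_array_len + 1000 <= occupied[, 1] | pos >= occupied[, 2] + 1000)) break
      }
      s[(pos + 1L):(pos + at_array_len)] <- at_chars
      occupied <- rbind(occupied, c(pos, pos + at_array_len))
      add_feat(id, pos, pos + at_array_len, 2, "AT", "at")
    }
    seqs[ci] <- intToUtf8(s)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- sprintf("Chr%02d", seq_len(n_chrom))
  truth <- list(genome = genome, features = do.call(rbind, feats),
                params = list(n_chrom = n_chrom, chrom_len = chrom_len,
                              telomere_copies = telomere_copies,
                              centromere_len = centromere_len,
                              n_at_arrays = n_at_arrays, at_array_len = at_array_len,
                              seed = seed))
  class(truth) <- "synthetic_truth"
  truth
}

#' Fragment a synthetic genome into contigs
#'
#' Breaks each chromosome at `n_contigs_per_chrom - 1` positions (random, or
#' centred on planted AT arrays when `break_at_at`), removing `gap_margin`
#' bases on each side of every breakpoint so that every true junction has a
#' gap of `2 * gap_margin`. Each contig is independently reverse-complemented
#' with probability `flip_prob`; placements and orientations are recorded.
#'
#' @param truth A `synthetic_truth` from [simulate_genome()].
#' @param n_contigs_per_chrom Contigs per chromosome (>= 1).
#' @param break_at_at Centre breakpoints on planted AT arrays.
#' @param gap_margin Unassembled margin (bp) on each side of a breakpoint.
#' @param flip_prob Per-contig reverse-complement probability.
#' @param seed Integer seed.
#' @return The truth, augmented with `contigs` (`DNAStringSet`), `placements`
#'   (data.frame: `contig_id`, `chrom`, `start`, `end`, `orientation`) and
#'   `junctions` (data.frame: `left_contig`, `left_end`, `right_contig`,
#'   `right_end`, `gap`, `key`).
#' @export
fragment_genome <- function(truth, n_contigs_per_chrom = 8, break_at_at = FALSE,
                            gap_margin = 200, flip_prob = 0, seed = 1) {
  if (!inherits(truth, "synthetic_truth")) abort_input("truth must come from simulate_genome")
  k <- n_contigs_per_chrom
  if (k < 1) abort_parameter("n_contigs_per_chrom must be >= 1")
  set.seed(seed)
  placements <- vector("list", 0L)
  junctions <- vector("list", 0L)
  contig_seqs <- character(0)
  idx <- 0L
  for (chrom in names(truth$genome)) {
    L <- Biostrings::width(truth$genome)[match(chrom, names(truth$genome))]
    s <- as.character(truth$genome[[chrom]])
    if (k > 1L) {
      if (break_at_at) {
        at <- truth$features[truth$features$kind == "at" & truth$features$seq_id == chrom, ]
        if (nrow(at) < k - 1L) abort_parameter("not enough AT arrays to break at")
        pick <- at[sample(nrow(at), k - 1L), ]
        br <- sort(floor((pick$start + pick$end) / 2))
      } else {
        min_sp <- max(4 * gap_margin + 2000, floor(L / (4 * k)))
        lo <- ceiling(0.05 * L); hi <- floor(0.95 * L)
        if (hi - lo < (k - 1L) * min_sp) abort_parameter("more breakpoints than available positions")
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 1000L) abort_parameter("could not place breakpoints with spacing")
          br <- sort(sample(seq(lo, hi), k - 1L))
          if (k == 2L || all(diff(br) >= min_sp)) break
        }
      }
    } else {
      br <- numeric(0)
    }
    bounds <- c(0, br, L)
    ids <- character(k)
    ors <- character(k)
    for (j in seq_len(k)) {
      a <- bounds[j] + if (j > 1L) gap_margin else 0
      b <- bounds[j + 1L] - if (j < k) gap_margin else 0
      if (b - a < 1) abort_parameter("contig collapsed to zero length; reduce gap_margin")
      idx <- idx + 1L
      id <- sprintf("ctg%04d", idx)
      flip <- stats::runif(1) < flip_prob
      seq <- substr(s, a + 1, b)
      if (flip) seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      contig_seqs[id] <- seq
      ids[j] <- id
      ors[j] <- if (flip) "-" else "+"
      placements[[length(placements) + 1L]] <- data.frame(
        contig_id = id, chrom = chrom, start = a, end = b,
        orientation = ors[j], stringsAsFactors = FALSE)
    }
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        le <- if (ors[j] == "+") "tail" else "head"
        re <- if (ors[j + 1L] == "+") "head" else "tail"
        junctions[[length(junctions) + 1L]] <- data.frame(
          left_contig = ids[j], left_end = le,
          right_contig = ids[j + 1L], right_end = re,
          gap = 2 * gap_margin,
          key = pair_key(ids[j], le, ids[j + 1L], re),
          stringsAsFactors = FALSE)
      }
    }
  }
  truth$contigs <- Biostrings::DNAStringSet(contig_seqs)
  names(truth$contigs) <- names(contig_seqs)
  truth$placements <- do.call(rbind, placements)
  truth$junctions <- if (length(junctions)) do.call(rbind, junctions) else
    data.frame(left_contig = character(), left_end = character(),
               right_contig = character(), right_end = character(),
               gap = numeric(), key = character(), stringsAsFactors = FALSE)
  truth$fragment_params <- list(n_contigs_per_chrom = k, break_at_at = break_at_at,
                                gap_margin = gap_margin, flip_prob = flip_prob,
                                seed = seed)
  truth
}

#' Simulate ultra-long reads and their exact PAF alignments
#'
#' Reads are sampled uniformly over the chromosomes with log-normal lengths
#' (mean `read_len_mean`, sdlog `read_len_sigma`, clipped at chromosome
#' ends). Each read's overlap with each underlying contig is emitted as one
#' exact PAF record (coordinates derived from the recorded placements and
#' orientations, mapq 60, tagged `tp:A:P`). Records are then independently
#' dropped with probability `drop_prob`, and `spurious_rate` times the true
#' contact count of extra two-alignment reads linking *distinct* random
#' contig-end pairs are injected as mapping noise.
#'
#' @param truth A fragmented `synthetic_truth` (see [fragment_genome()]).
#' @param coverage Requested genome coverage (0 gives an empty PAF).
#' @param read_len_mean Mean read length (bp).
#' @param read_len_sigma Log-normal sdlog of read lengths.
#' @param drop_prob Per-record dropout probability.
#' @param spurious_rate Spurious contact pairs per true contact.
#' @param seed Integer seed.
#' @return List: `paf` (alignment data.frame as from [read_paf()]),
#'   `read_truth` (data.frame: `read_id`, `chrom`, `start`, `end`) and
#'   `n_true_contacts`.
#' @export
simulate_ultralong_paf <- function(truth, coverage = 30, read_len_mean = 5e4,
                                   read_len_sigma = 0.4, drop_prob = 0,
                                   spurious_rate = 0, seed = 1) {
  if (is.null(truth$placements)) abort_input("truth has no contigs; run fragment_genome first")
  if (coverage < 0) abort_parameter("coverage must be >= 0")
  set.seed(seed)
  lens <- Biostrings::width(truth$genome)
  chroms <- names(truth$genome)
  total <- sum(lens)
  n_reads <- round(total * coverage / read_len_mean)
  pl_by_chrom <- split(truth$placements, truth$placements$chrom)
  clen <- stats::setNames(Biostrings::width(truth$contigs), names(truth$contigs))

  paf <- empty_paf()
  read_truth <- data.frame(read_id = character(), chrom = character(),
                           start = numeric(), end = numeric(), stringsAsFactors = FALSE)
  n_contacts <- 0L
  if (n_reads > 0) {
    ci <- sample(length(chroms), n_reads, replace = TRUE, prob = lens)
    rl <- pmax(1000, round(stats::rlnorm(n_reads,
                                         meanlog = log(read_len_mean) - read_len_sigma^2 / 2,
                                         sdlog = read_len_sigma)))
    rs <- floor(stats::runif(n_reads, 0, pmax(1, lens[ci] - 1)))
    re <- pmin(rs + rl, lens[ci])
    rid <- sprintf("read%06d", seq_len(n_reads))
    read_truth <- data.frame(read_id = rid, chrom = chroms[ci], start = rs, end = re,
                             stringsAsFactors = FALSE)
    parts <- vector("list", 0L)
    for (chrom in chroms) {
      ri <- which(chroms[ci] == chrom)
      pls <- pl_by_chrom[[chrom]]
      if (!length(ri) || is.null(pls)) next
      hits <- IRanges::findOverlaps(IRanges::IRanges(rs[ri] + 1, re[ri]),
                                    IRanges::IRanges(pls$start + 1, pls$end))
      q <- ri[S4Vectors::queryHits(hits)]
      p <- S4Vectors::subjectHits(hits)
      if (!length(q)) next
      n_contacts <- n_contacts + length(q) - length(unique(q))
      cs <- pls$start[p]; ce <- pls$end[p]
      os <- pmax(rs[q], cs); oe <- pmin(re[q], ce)
      cl <- ce - cs
      plus <- pls$orientation[p] == "+"
      parts[[length(parts) + 1L]] <- data.frame(
        read_id = rid[q], read_len = re[q] - rs[q],
        read_start = os - rs[q], read_end = oe - rs[q],
        strand = ifelse(plus, "+", "-"), target_id = pls$contig_id[p],
        target_len = cl,
        target_start = ifelse(plus, os - cs, ce - oe),
        target_end = ifelse(plus, oe - cs, ce - os),
        matches = oe - os, block_len = oe - os,
        mapq = 60, tags = "tp:A:P", stringsAsFactors = FALSE)
    }
    if (length(parts)) {
      paf <- do.call(rbind, parts)
      paf <- paf[order(match(paf$read_id, rid), paf$read_start), , drop = FALSE]
    }
  }

  if (nrow(paf) && drop_prob > 0) {
    paf <- paf[stats::runif(nrow(paf)) >= drop_prob, , drop = FALSE]
  }

  n_spur <- round(spurious_rate * n_contacts)
  if (n_spur > 0) {
    ids <- names(truth$contigs)
    combos <- expand.grid(i = seq_along(ids), j = seq_along(ids),
                          e1 = c("head", "tail"), e2 = c("head", "tail"),
                          stringsAsFactors = FALSE)
    combos <- combos[combos$i < combos$j, , drop = FALSE]
    n_spur <- min(n_spur, nrow(combos))
    pick <- combos[sample(nrow(combos), n_spur), , drop = FALSE]
    g <- 500
    spur <- vector("list", 0L)
    spur_aln <- function(rid, rlen, qs, qe, contig, end) {
      cl <- clen[[contig]]
      s <- qe - qs
      if (end == "tail") {
        data.frame(read_id = rid, read_len = rlen, read_start = qs, read_end = qe,
                   strand = "+", target_id = contig, target_len = cl,
                   target_start = cl - s, target_end = cl, matches = s, block_len = s,
                   mapq = 60, tags = "tp:A:P", stringsAsFactors = FALSE)
      } else {
        data.frame(read_id = rid, read_len = rlen, read_start = qs, read_end = qe,
                   strand = "-", target_id = contig, target_len = cl,
                   target_start = 0, target_end = s, matches = s, block_len = s,
                   mapq = 60, tags = "tp:A:P", stringsAsFactors = FALSE)
      }
    }
    for (si in seq_len(n_spur)) {
      c1 <- ids[pick$i[si]]; c2 <- ids[pick$j[si]]
      s1 <- min(5000, floor(clen[[c1]] / 2))
      s2 <- min(5000, floor(clen[[c2]] / 2))
      rid <- sprintf("spurious%05d", si)
      rlen <- s1 + g + s2
      # first alignment exits via e1, second enters via e2
      a1 <- spur_aln(rid, rlen, 0, s1, c1, pick$e1[si])
      e2 <- pick$e2[si]
      cl2 <- clen[[c2]]
      a2 <- if (e2 == "head") {
        data.frame(read_id = rid, read_len = rlen, read_start = s1 + g, read_end = rlen,
                   strand = "+", target_id = c2, target_len = cl2,
                   target_start = 0, target_end = s2, matches = s2, block_len = s2,
                   mapq = 60, tags = "tp:A:P", stringsAsFactors = FALSE)
      } else {
        data.frame(read_id = rid, read_len = rlen, read_start = s1 + g, read_end = rlen,
                   strand = "-", target_id = c2, target_len = cl2,
                   target_start = cl2 - s2, target_end = cl2, matches = s2, block_len = s2,
                   mapq = 60, tags = "tp:A:P", stringsAsFactors = FALSE)
      }
      spur[[length(spur) + 1L]] <- rbind(a1, a2)
    }
    paf <- rbind(paf, do.call(rbind, spur))
  }
  rownames(paf) <- NULL
  list(paf = paf, read_truth = read_truth, n_true_contacts = n_contacts)
}

#' Compare recovered scaffold junctions with the ground truth
#'
#' A true junction counts as recovered when some scaffold path contains the
#' same unordered contig-end pair — which checks order *and* relative
#' orientation, since ends encode orientation. Emitted adjacencies absent
#' from the truth are false joins.
#'
#' @param paths Scaffold paths (see [extract_paths()]).
#' @param truth A fragmented `synthetic_truth`.
#' @return List: `n_true`, `n_found`, `n_recovered`, `n_false`,
#'   `recovery_pct`, `gaps` (emitted gaps of recovered junctions).
#' @export
junction_recovery <- function(paths, truth) {
  if (is.null(truth$junctions)) abort_input("truth has no junctions; run fragment_genome first")
  found_keys <- character(0)
  found_gaps <- numeric(0)
  for (p in paths) {
    k <- length(p$contigs)
    if (k < 2L) next
    for (j in seq_len(k - 1L)) {
      le <- if (p$orientations[j] == "+") "tail" else "head"
      re <- if (p$orientations[j + 1L] == "+") "head" else "tail"
      found_keys <- c(found_keys, pair_key(p$contigs[j], le, p$contigs[j + 1L], re))
      found_gaps <- c(found_gaps, p$gaps[j])
    }
  }
  true_keys <- truth$junctions$key
  hit <- found_keys %in% true_keys
  list(n_true = length(true_keys), n_found = length(found_keys),
       n_recovered = sum(unique(found_keys) %in% true_keys),
       n_false = sum(!hit),
       recovery_pct = if (length(true_keys)) 100 * sum(true_keys %in% found_keys) / length(true_keys) else NA_real_,
       gaps = found_gaps[hit])
}
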