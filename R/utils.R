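# Internal condition helpers and small numeric utilities.
#
# All package errors are classed conditions rooted at "ulscaf_error" so callers
# (and the CLI) can react to the failure category rather than match messages.

ul_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "ulscaf_error", "error")))
}

abort_malformed  <- function(msg) ul_abort(msg, "ulscaf_malformed_record")
abort_duplicate  <- function(msg) ul_abort(msg, "ulscaf_duplicate_id")
abort_alphabet   <- function(msg) ul_abort(msg, "ulscaf_alphabet_error")
abort_coordinate <- function(msg) ul_abort(msg, "ulscaf_coordinate_error")
abort_parameter  <- function(msg) ul_abort(msg, "ulscaf_parameter_error")
abort_input      <- function(msg) ul_abort(msg, "ulscaf_input_error")
abort_segment    <- function(msg) ul_abort(msg, "ulscaf_unknown_segment")
abort_graphstate <- function(msg) ul_abort(msg, "ulscaf_graph_state_error")

# round half away from zero (base round() is banker's rounding)
round_half_out <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# median with the half-away-from-zero rule for even cardinality
median_half_out <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) abort_input("median of an empty vector")
  if (n %% 2L == 1L) x[(n + 1L) %/% 2L] else round_half_out((x[n %/% 2L] + x[n %/% 2L + 1L]) / 2)
}

# reverse complement of short character units (long sequences go through Biostrings)
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# canonical storage key for a contig end, e.g. "ctg0001:tail"
end_key <- function(contig, end) paste0(contig, ":", end)

# canonical unordered key for a pair of contig ends
pair_key <- function(contig_a, end_a, contig_b, end_b) {
  ka <- end_key(contig_a, end_a)
  kb <- end_key(contig_b, end_b)
  ifelse(ka <= kb, paste(ka, kb, sep = "--"), paste(kb, ka, sep = "--"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
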