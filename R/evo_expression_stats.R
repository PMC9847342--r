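# Ks-distribution peak detection, ratio-based WGD dating and TPM computation.

#' Modes of a Ks distribution
#'
#' Fits a Gaussian kernel density (Silverman's rule bandwidth by default) on
#' a 512-point grid over `[0, max(values)]` and returns the `n_modes` highest
#' local maxima, sorted ascending. Peaks in a Ks distribution mark bursts of
#' gene duplication (whole-genome duplications) or speciation events.
#'
#' @param values Non-negative Ks values (at least 10).
#' @param bandwidth Kernel bandwidth, or `"auto"` for Silverman's rule.
#' @param n_modes Number of modes to return.
#' @param n_grid Density grid size.
#' @return Numeric vector of mode locations (ascending; fewer than `n_modes`
#'   when the density has fewer local maxima).
#' @export
ks_modes <- function(values, bandwidth = "auto", n_modes = 2, n_grid = 512) {
  if (length(values) < 10L) abort_input("ks_modes needs at least 10 values")
  if (any(!is.finite(values)) || any(values < 0)) abort_input("Ks values must be finite and >= 0")
  if (n_modes < 1) abort_parameter("n_modes must be >= 1")
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(values) else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) bw <- max(max(values), 1) * 1e-3  # degenerate sample
  d <- stats::density(values, bw = bw, n = n_grid, from = 0, to = max(values))
  y <- d$y
  n <- length(y)
  is_max <- logical(n)
  is_max[1] <- y[1] > y[2]
  is_max[n] <- y[n] > y[n - 1]
  mid <- 2:(n - 1)
  is_max[mid] <- y[mid] > y[mid - 1] & y[mid] >= y[mid + 1]
  peaks <- which(is_max)
  peaks <- peaks[order(-y[peaks])]
  sort(d$x[utils::head(peaks, n_modes)])
}

#' Date a whole-genome duplication from Ks peak positions
#'
#' Assuming clock-like Ks accumulation, the WGD age is the speciation time
#' scaled by the ratio of the WGD Ks peak to the speciation Ks peak:
#' `t_speciation * ks_wgd / ks_speciation`, rounded half away from zero to 2
#' decimals.
#'
#' @param t_speciation Speciation (divergence) time, Mya.
#' @param ks_wgd Ks peak of the WGD event.
#' @param ks_speciation Ks peak of the speciation event (> 0).
#' @return WGD age in Mya.
#' @export
wgd_age <- function(t_speciation, ks_wgd, ks_speciation) {
  if (any(c(t_speciation, ks_wgd, ks_speciation) < 0)) {
    abort_parameter("all inputs must be non-negative")
  }
  if (ks_speciation == 0) abort_parameter("ks_speciation must be > 0")
  round_half_out(t_speciation * ks_wgd / ks_speciation, 2)
}

#' Transcripts per million
#'
#' `rate_i = counts_i / lengths_i; tpm_i = 1e6 * rate_i / sum(rate)`. When
#' every count is zero the TPM vector is all zeros.
#'
#' @param counts Non-negative read counts.
#' @param lengths Positive effective feature lengths (bp).
#' @return Numeric vector of TPM values (sums to 1e6 when any count > 0).
#' @export
tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) abort_input("counts and lengths differ in size")
  if (any(lengths <= 0)) abort_parameter("lengths must be positive")
  if (any(counts < 0)) abort_input("counts must be non-negative")
  if (!length(counts) || all(counts == 0)) return(numeric(length(counts)))
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Add a TPM column to a counts table
#'
#' @param table data.frame with columns `gene_id`, `count`, `length`.
#' @return The table with a `tpm` column appended.
#' @export
tpm_table <- function(table) {
  need <- c("gene_id", "count", "length")
  if (!all(need %in% names(table))) {
    abort_input("counts table must have columns gene_id, count, length")
  }
  table$tpm <- tpm(table$count, table$length)
  table
}
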