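# Poisson local-background peak calling on raw binned counts.
#
# The caller scores, at every bin, the window of `origin_window` bp centered
# on it against the most conservative of the genome-wide rate and two local
# rates (5 kb and 10 kb windows), mirroring the local-lambda idea of the
# standard enrichment callers. Peaks are maximal runs of significant bins
# merged across gaps of at most `merge_gap` bp. Counts are raw (unsmoothed,
# un-normalized) because the Poisson model requires counts; replicates are
# pooled by summation upstream.

#' Poisson upper-tail probability
#'
#' Returns `P(X >= k)` for `X ~ Poisson(lambda)`, computed by log-space
#' accumulation of the probability mass (stable far into either tail).
#'
#' @param k Non-negative integer count (vectorized).
#' @param lambda Positive Poisson mean (vectorized, recycled against `k`).
#' @return Upper-tail probabilities in `[0, 1]`.
#' @export
poisson_upper_tail <- function(k, lambda) {
  n <- max(length(k), length(lambda))
  k <- rep_len(as.numeric(k), n)
  lambda <- rep_len(as.numeric(lambda), n)
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(k < 0 | k != floor(k))) stop("k must be a non-negative integer")
  vapply(seq_len(n), function(i) .pois_upper1(k[i], lambda[i]), numeric(1L))
}

.pois_upper1 <- function(k, lambda) {
  if (k == 0) return(1)
  log_pmf <- function(i) -lambda + i * log(lambda) - lgamma(i + 1)
  if (k <= lambda + 1) {
    # Lower tail is the smaller computation and p is large: 1 - P(X < k).
    lower <- logsumexp(log_pmf(seq.int(0, k - 1)))
    return(max(0, 1 - exp(lower)))
  }
  # Accumulate the upper tail directly; terms decay geometrically for
  # i > lambda.  Chunked summation with a relative-tail stopping rule.
  lp_k <- log_pmf(k)
  total <- 1  # sum of exp(log_pmf(i) - lp_k), i = k term included
  i <- k
  term <- 1
  while (TRUE) {
    i <- i + 1
    term <- term * lambda / i
    total <- total + term
    # ratio < 1 guaranteed; bound remaining tail by geometric series
    ratio <- lambda / (i + 1)
    if (term * ratio / (1 - ratio) < total * 1e-17) break
    if (i > k + 1e6) break
  }
  min(1, exp(lp_k + log(total)))
}

# Truncated centered window sums: S[i] = sum(x[max(1,i-h):min(n,i+h)]),
# plus the number of bins actually in each window.
window_sums <- function(x, h) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  list(sum = cs[hi + 1L] - cs[lo], nb = hi - lo + 1L)
}

#' Call BrdU-enriched peaks from raw binned counts
#'
#' Every bin's centered `origin_window` is scored with
#' [poisson_upper_tail()] against `lambda_local`, the maximum of the
#' genome-wide mean rate and the local rates in the
#' `local_background_windows` (5 and 10 kb by default), scaled to the scoring
#' window. Bins with `p < peak_p_threshold` are merged into peaks across gaps
#' of at most `merge_gap` bp; the summit is the midpoint of the maximal-count
#' bin of the run. No multiple-testing correction is applied at this stage
#' (origin-level FDR control happens in the differential module).
#'
#' @param raw_track A `binned_track` of raw counts (replicates pooled).
#' @param layout A `genome_layout`.
#' @param config An [analysis_config()].
#' @return `data.frame` of peaks: `chrom`, `start`, `end`, `summit`, `count`,
#'   `lambda_local`, `p_value` (0-based half-open intervals).
#' @export
call_peaks <- function(raw_track, layout, config = analysis_config()) {
  if (length(raw_track$values) == 0L) stop("empty track")
  bw <- raw_track$bin_width
  total <- sum(unlist(raw_track$values))
  total_bins <- sum(lengths(raw_track$values))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      summit = numeric(), count = numeric(),
                      lambda_local = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (total == 0) return(empty)
  genome_rate <- total / total_bins
  h_score <- (config$origin_window %/% bw) %/% 2L
  h_bg <- (config$local_background_windows %/% bw) %/% 2L
  gap_bins <- config$merge_gap %/% bw
  peaks <- list()
  for (chrom in names(raw_track$values)) {
    x <- raw_track$values[[chrom]]
    n <- length(x)
    if (n == 0L) next
    score <- window_sums(x, h_score)
    rate <- rep(genome_rate, n)
    for (h in h_bg) {
      bg <- window_sums(x, h)
      rate <- pmax(rate, bg$sum / bg$nb)
    }
    lam <- rate * score$nb
    p <- poisson_upper_tail(score$sum, lam)
    sig <- which(p < config$peak_p_threshold)
    if (length(sig) == 0L) next
    run_id <- cumsum(c(1L, diff(sig) > gap_bins + 1L))
    for (r in split(sig, run_id)) {
      b_max <- r[which.max(x[r])]
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chrom,
        start = (r[1L] - 1L) * bw,
        end = min(r[length(r)] * bw, raw_track$chrom_lengths[[chrom]]),
        summit = (b_max - 1L) * bw + bw %/% 2L,
        count = score$sum[b_max],
        lambda_local = lam[b_max],
        p_value = min(p[r]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(peaks) == 0L) return(empty)
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Cross-reference peaks against annotated origins
#'
#' An origin is called when any peak overlaps (by at least 1 bp, half-open
#' semantics) the `origin_window` centered on the origin midpoint. Peaks
#' overlapping no origin window are discarded.
#'
#' @param peaks Peak `data.frame` from [call_peaks()].
#' @param origins Origin `data.frame`.
#' @param layout A `genome_layout`.
#' @param config An [analysis_config()].
#' @return List with `called` (character vector of origin names, in origin
#'   table order) and `n_discarded` (peaks overlapping no origin window).
#' @export
peaks_to_origins <- function(peaks, origins, layout, config = analysis_config()) {
  if (nrow(peaks) == 0L)
    return(list(called = character(), n_discarded = 0L))
  win <- origin_windows(origins, layout, config$origin_window)
  ov <- overlaps_any(peaks, win)
  hit_origin <- overlaps_any(win, peaks)
  list(called = origins$name[hit_origin],
       n_discarded = sum(!ov))
}

# For each interval in `a` (0-based half-open), does any interval in `b`
# share >= 1 bp?  Backed by IRanges; the test suite checks it against a
# quadratic all-pairs oracle.
overlaps_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0L))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  gr_a <- GenomicRanges::GRanges(a$chrom,
                                 IRanges::IRanges(a$start + 1, a$end))
  gr_b <- GenomicRanges::GRanges(b$chrom,
                                 IRanges::IRanges(b$start + 1, b$end))
  IRanges::overlapsAny(gr_a, gr_b)
}
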