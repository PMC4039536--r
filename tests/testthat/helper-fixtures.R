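# Shared fixtures and independent brute-force oracles.
# Oracles are deliberately naive (quadratic loops, direct summation) and stay
# independent of the implementation paths they check.

set_log_level(0)

tiny_layout <- function(lengths = c(chrA = 10000, chrB = 8000),
                        centromeres = NULL) {
  genome_layout(data.frame(name = names(lengths), length = unname(lengths),
                           stringsAsFactors = FALSE),
                centromeres = centromeres)
}

make_track <- function(layout, values, bin_width = 50L) {
  track <- empty_track(layout, bin_width)
  for (chrom in names(values)) {
    stopifnot(length(values[[chrom]]) == length(track$values[[chrom]]))
    track$values[[chrom]] <- as.numeric(values[[chrom]])
  }
  track
}

random_fragments <- function(layout, n, seed, max_len = 300L) {
  set.seed(seed)
  chrom <- sample(layout$chromosomes$name, n, replace = TRUE)
  len <- chrom_length <- layout$chromosomes$length[
    match(chrom, layout$chromosomes$name)]
  flen <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, len - flen))
  data.frame(chrom = chrom, start = start, end = start + flen,
             stringsAsFactors = FALSE)
}

random_intervals <- function(chroms, n, max_pos, seed) {
  set.seed(seed)
  start <- floor(runif(n, 0, max_pos - 1))
  width <- sample.int(500L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = pmin(start + width, max_pos),
             stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# --- oracles -----------------------------------------------------------------

oracle_bin_counts <- function(frags, layout, bin_width) {
  out <- lapply(seq_len(nrow(layout$chromosomes)), function(i)
    numeric(ceiling(layout$chromosomes$length[i] / bin_width)))
  names(out) <- layout$chromosomes$name
  for (i in seq_len(nrow(frags))) {
    mid <- floor((frags$start[i] + frags$end[i]) / 2)
    b <- mid %/% bin_width + 1
    out[[frags$chrom[i]]][b] <- out[[frags$chrom[i]]][b] + 1
  }
  out
}

oracle_sliding_median <- function(x, k) {
  h <- (k - 1) / 2
  n <- length(x)
  sapply(seq_len(n), function(i) median(x[max(1, i - h):min(n, i + h)]))
}

oracle_poisson_upper <- function(k, lambda) {
  if (k == 0) return(1)
  # direct summation of the upper-tail mass, term by term
  i <- k:(k + 600)
  sum(exp(i * log(lambda) - lgamma(i + 1) - lambda))
}

oracle_overlaps_any <- function(a, b) {
  sapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  })
}

oracle_nearest_distance <- function(query, landmarks) {
  sapply(seq_len(nrow(query)), function(i) {
    sel <- landmarks$chrom == query$chrom[i]
    if (!any(sel)) return(NA_real_)
    min(pmax(landmarks$start[sel] - query$end[i],
             query$start[i] - landmarks$end[sel], 0))
  })
}

oracle_bh <- function(p) {
  n <- length(p)
  sapply(seq_len(n), function(i) {
    r <- rank(p, ties.method = "first")[i]
    min(1, min(sapply(r:n, function(j) sort(p)[j] * n / j)))
  })
}
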