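# Binned BrdU signal tracks.
#
# A binned_track holds, per chromosome, a vector of non-negative values in
# fixed-width non-overlapping bins (50 bp by default). The processing chain is
# bin -> median-smooth (1 kb) -> quantile-normalize between replicates ->
# average -> smooth again.

#' Create an all-zero binned track
#'
#' @param layout A `genome_layout`.
#' @param bin_width Bin width in bp.
#' @return A `binned_track`: list with `bin_width`, `chrom_lengths`, and
#'   `values` (named list of per-chromosome numeric vectors of length
#'   `ceiling(length / bin_width)`).
#' @export
empty_track <- function(layout, bin_width) {
  nb <- n_bins(layout, bin_width)
  values <- lapply(nb, numeric)
  names(values) <- layout$chromosomes$name
  chrom_lengths <- stats::setNames(layout$chromosomes$length,
                                   layout$chromosomes$name)
  structure(list(bin_width = as.integer(bin_width),
                 chrom_lengths = chrom_lengths,
                 values = values),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d chromosomes, %d bp bins, total signal %.6g\n",
              length(x$values), x$bin_width, sum(unlist(x$values))))
  invisible(x)
}

track_concat <- function(track) unlist(track$values, use.names = FALSE)

track_set_concat <- function(track, v) {
  lens <- lengths(track$values)
  stopifnot(length(v) == sum(lens))
  track$values <- stats::setNames(
    split(v, rep(seq_along(lens), lens)), names(track$values))
  track
}

check_same_layout <- function(tracks) {
  ref <- lengths(tracks[[1L]]$values)
  for (t in tracks[-1L]) {
    if (!identical(names(t$values), names(tracks[[1L]]$values)) ||
        !identical(lengths(t$values), ref))
      stop("tracks do not share one genome layout / bin grid")
  }
  invisible(TRUE)
}

#' Bin fragments into fixed-width bins by midpoint
#'
#' Each fragment contributes exactly 1 to the bin containing its midpoint
#' `floor((start + end) / 2) %/% bin_width`, so the total over all bins equals
#' the number of fragments.
#'
#' @param frags Fragment `data.frame` (`chrom`, `start`, `end`).
#' @param layout A `genome_layout`.
#' @param bin_width Bin width in bp.
#' @return A `binned_track` of counts.
#' @export
bin_fragments <- function(frags, layout, bin_width) {
  track <- empty_track(layout, bin_width)
  if (nrow(frags) == 0L) return(track)
  mid <- floor((frags$start + frags$end) / 2)
  bin <- mid %/% bin_width + 1L
  for (chrom in unique(frags$chrom)) {
    sel <- frags$chrom == chrom
    nb <- length(track$values[[chrom]])
    track$values[[chrom]] <- as.numeric(tabulate(bin[sel], nbins = nb))
  }
  track
}

# Sliding median of one vector with a centered window of k bins (k odd),
# truncated (asymmetric) at the vector ends. Interior windows match runmed;
# the first and last (k-1)/2 positions are recomputed with clipped windows.
sliding_median <- function(x, k) {
  n <- length(x)
  if (n == 0L || k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  if (n <= k) {
    return(vapply(seq_len(n),
                  function(i) stats::median(x[max(1L, i - h):min(n, i + h)]),
                  numeric(1L)))
  }
  y <- stats::runmed(x, k, endrule = "keep")
  edge <- c(seq_len(h), seq.int(n - h + 1L, n))
  y[edge] <- vapply(edge,
                    function(i) stats::median(x[max(1L, i - h):min(n, i + h)]),
                    numeric(1L))
  as.numeric(y)
}

#' Median-smooth a binned track
#'
#' Output bin i is the median of input bins within the centered window of
#' `2 * floor(window_bp / (2 * bin_width)) + 1` bins (21 bins for a 1 kb
#' window over 50 bp bins). Windows are truncated at chromosome ends, so no
#' signal is invented at telomeres.
#'
#' @param track A `binned_track`.
#' @param window_bp Smoothing window in bp (>= one bin).
#' @return The smoothed `binned_track`.
#' @export
median_smooth <- function(track, window_bp) {
  if (window_bp < track$bin_width)
    stop("smoothing window smaller than one bin")
  k <- 2L * (as.integer(window_bp) %/% (2L * track$bin_width)) + 1L
  track$values <- lapply(track$values, sliding_median, k = k)
  track
}

#' Quantile-normalize tracks between replicates
#'
#' Concatenates each track genome-wide, replaces the value at rank r in each
#' track with the across-track mean of rank-r values, and reassembles the
#' per-chromosome vectors in place. Tied values within a track receive the
#' mean of the reference values across their tied rank span (the standard
#' convention; count data guarantee heavy ties).
#'
#' @param tracks List of >= 2 `binned_track`s over one layout.
#' @return List of normalized `binned_track`s, same order.
#' @export
quantile_normalize <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  check_same_layout(tracks)
  mat <- vapply(tracks, track_concat, numeric(sum(lengths(tracks[[1L]]$values))))
  sorted <- apply(mat, 2L, sort)
  ref <- rowMeans(sorted)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    o <- order(mat[, j])
    s <- mat[o, j]
    grp <- cumsum(c(TRUE, s[-1L] != s[-length(s)]))
    out[o, j] <- stats::ave(ref, grp)
  }
  lapply(seq_along(tracks),
         function(j) track_set_concat(tracks[[j]], out[, j]))
}

#' Average replicate tracks and smooth again
#'
#' Bin-wise arithmetic mean of the (normalized) replicate tracks followed by
#' [median_smooth()] with the same window as the first pass.
#'
#' @param tracks List of >= 2 `binned_track`s over one layout.
#' @param window_bp Smoothing window in bp.
#' @return A single smoothed `binned_track`.
#' @export
average_and_resmooth <- function(tracks, window_bp) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  check_same_layout(tracks)
  avg <- tracks[[1L]]
  nms <- names(avg$values)
  for (chrom in nms) {
    avg$values[[chrom]] <- rowMeans(
      vapply(tracks, function(t) t$values[[chrom]],
             numeric(length(avg$values[[chrom]]))))
  }
  median_smooth(avg, window_bp)
}

#' Genome-wide background rate of a track
#'
#' Estimates the per-bin rate of the non-enriched (unreplicated) majority of
#' the genome: total signal over non-overlapping `window_bp` windows is
#' summarized by a masked mean - a median pilot estimate, then the mean of
#' windows not exceeding pilot + 3 * sqrt(pilot), iterated - so windows
#' carrying replication signal are excluded while the estimate keeps the
#' full precision of the clean windows. Under HU arrest the vast majority of
#' windows contain no replicated DNA, making this rate insensitive to how
#' many origins fire, unlike the total fragment count. Falls back to the
#' genome mean rate when everything is zero.
#'
#' @param track A `binned_track`.
#' @param window_bp Background window in bp (5 kb default).
#' @return Scalar rate per bin.
#' @export
background_rate <- function(track, window_bp = 5000L) {
  nb_win <- as.integer(window_bp) %/% track$bin_width
  stopifnot(nb_win >= 1L)
  t_win <- unlist(lapply(track$values, function(v) {
    n_full <- length(v) %/% nb_win
    if (n_full == 0L) return(sum(v))
    vapply(seq_len(n_full), function(i)
      sum(v[((i - 1L) * nb_win + 1L):(i * nb_win)]), numeric(1L))
  }), use.names = FALSE)
  m <- stats::median(t_win)
  kept <- t_win
  for (it in 1:2) {
    keep <- t_win <= m + 3 * sqrt(max(m, 1))
    if (!any(keep)) break
    kept <- t_win[keep]
    m <- mean(kept)
  }
  if (m > 0) {
    out <- m / nb_win
    # estimation uncertainty of the anchor, as a relative variance; callers
    # propagate it into the count model as extra overdispersion
    attr(out, "rel_var") <- stats::var(kept) / length(kept) / m^2
    return(out)
  }
  v <- track_concat(track)
  if (length(v) == 0L || sum(v) == 0) return(0)
  sum(v) / length(v)
}

#' Fully-replicated plateau level of a track
#'
#' A high quantile (98th percentile by default) of the per-bin values: in
#' every regime simulated or analyzed here, the cores of the
#' earliest-firing origins are replicated in essentially all cells, so the
#' upper quantile sits on that fully-replicated plateau and provides a
#' per-cell signal unit that is comparable across strains.
#'
#' @param track A `binned_track`.
#' @param q Quantile in (0, 1).
#' @return Scalar plateau level.
#' @export
plateau_level <- function(track, q = 0.98) {
  stopifnot(q > 0, q < 1)
  as.numeric(stats::quantile(track_concat(track), q, names = FALSE))
}

#' Scale a track to a per-cell reference unit
#'
#' Divides every bin by a per-track anchor so tracks from different strains
#' share one per-cell scale: the fully-replicated `"plateau"` level
#' (default; robust at any point of S-phase) or the unreplicated
#' `"background"` rate (natural under HU arrest, where most of the genome is
#' unreplicated). Equalizing raw genome-wide sums would instead be
#' confounded by the number of active origins.
#'
#' @param track A `binned_track`.
#' @param reference `"plateau"` or `"background"`.
#' @param ... Passed to [plateau_level()] or [background_rate()].
#' @return The rescaled `binned_track`.
#' @export
scale_track <- function(track, reference = c("plateau", "background"), ...) {
  reference <- match.arg(reference)
  anchor <- switch(reference,
                   plateau = plateau_level(track, ...),
                   background = background_rate(track, ...))
  if (anchor <= 0) stop("cannot scale: track has zero ", reference, " level")
  track$values <- lapply(track$values, `/`, anchor)
  track
}

#' Build the smoothed, normalized, averaged signal track for one strain
#'
#' Runs the full processing chain on a strain's replicate fragment sets:
#' bin by midpoint, median-smooth over `smooth_window`, quantile-normalize
#' between the replicates, average, and smooth again. Normalization is applied
#' within a strain's replicates only; cross-strain comparisons are made in
#' per-bin fragment-count units.
#'
#' @param fragment_sets List of fragment `data.frame`s, one per replicate.
#' @param layout A `genome_layout`.
#' @param config An [analysis_config()].
#' @return A `binned_track`.
#' @export
build_signal_track <- function(fragment_sets, layout, config = analysis_config()) {
  if (length(fragment_sets) < 2L)
    stop("need at least two replicate fragment sets")
  tracks <- lapply(fragment_sets, function(f) {
    median_smooth(bin_fragments(f, layout, config$bin_width),
                  config$smooth_window)
  })
  tracks <- quantile_normalize(tracks)
  average_and_resmooth(tracks, config$smooth_window)
}
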