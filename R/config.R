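#' Analysis configuration
#'
#' Bundles every numeric threshold used along the pipeline. Defaults follow the
#' standard BrdU-IP-Seq practice for budding yeast: 50 bp non-overlapping
#' bins, 1 kb median smoothing, peak significance at p < 0.01, differential
#' calls at FDR q < 0.05, 1 kb windows centered on origin midpoints, 20 kb
#' centromere/telomere proximity, and 40 kb / 5 kb metaprofile windows.
#'
#' @param bin_width Bin width in bp for coverage tracks.
#' @param smooth_window Median-smoothing window in bp (multiple of `bin_width`).
#' @param peak_p_threshold Poisson p-value cutoff for peak calling.
#' @param fdr_q_threshold BH q-value cutoff for the three-way origin
#'   classification.
#' @param origin_window Window in bp centered on an origin midpoint, used both
#'   for peak/origin cross-referencing and for differential counting (multiple
#'   of `bin_width`).
#' @param landmark_threshold Distance in bp defining pericentric/subtelomeric
#'   origins ("within 20 kb").
#' @param profile_window Default metaprofile full width in bp (40 kb for the
#'   temporal plots, 5 kb for the HU plots).
#' @param proximity_window Binding-site proximity window in bp (the 1 kb
#'   window centered on origin midpoints).
#' @param local_background_windows Window sizes in bp for the local Poisson
#'   background rate in peak calling.
#' @param merge_gap Maximum gap in bp between significant bins merged into one
#'   peak.
#' @param seed Integer seed for all randomized steps.
#' @return An object of class `analysis_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$bin_width
#' @export
analysis_config <- function(bin_width = 50L,
                            smooth_window = 1000L,
                            peak_p_threshold = 0.01,
                            fdr_q_threshold = 0.05,
                            origin_window = 1000L,
                            landmark_threshold = 20000L,
                            profile_window = 40000L,
                            proximity_window = 1000L,
                            local_background_windows = c(5000L, 10000L),
                            merge_gap = 500L,
                            seed = 1L) {
  cfg <- list(
    bin_width = as.integer(bin_width),
    smooth_window = as.integer(smooth_window),
    peak_p_threshold = peak_p_threshold,
    fdr_q_threshold = fdr_q_threshold,
    origin_window = as.integer(origin_window),
    landmark_threshold = as.integer(landmark_threshold),
    profile_window = as.integer(profile_window),
    proximity_window = as.integer(proximity_window),
    local_background_windows = as.integer(local_background_windows),
    merge_gap = as.integer(merge_gap),
    seed = as.integer(seed)
  )
  lens <- c(cfg$bin_width, cfg$smooth_window, cfg$origin_window,
            cfg$landmark_threshold, cfg$profile_window, cfg$proximity_window,
            cfg$local_background_windows, cfg$merge_gap)
  if (any(lens <= 0)) stop("all window/length parameters must be positive")
  for (p in c("peak_p_threshold", "fdr_q_threshold")) {
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1) stop(p, " must lie in (0, 1)")
  }
  if (cfg$smooth_window %% cfg$bin_width != 0L)
    stop("smooth_window must be a multiple of bin_width")
  if (cfg$origin_window %% cfg$bin_width != 0L)
    stop("origin_window must be a multiple of bin_width")
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  for (nm in names(x)) {
    cat(sprintf("  %-25s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
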