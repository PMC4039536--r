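# End-to-end convenience wrappers over the module functions.

#' Run the HU BrdU-IP-Seq pipeline on a simulated experiment
#'
#' Simulates the WT / rif1-deletion HU experiment (unless one is supplied),
#' pools each strain's replicate fragments, calls peaks on the raw pooled
#' counts, cross-references them against the origin annotation, classifies
#' the union of called origins with the differential module, and summarizes
#' recovery against the simulation truth.
#'
#' @param seed Master integer seed.
#' @param config An [analysis_config()].
#' @param experiment Optional result of [simulate_experiment()]; simulated
#'   at defaults from `seed` when missing.
#' @param ... Passed to [simulate_experiment()] when simulating here.
#' @return List with `experiment`, per-strain `peaks` and `called` origin
#'   names, `classification` (data.frame over the union of called origins),
#'   and `metrics` (named numeric vector, fractions in percent).
#' @export
run_hu_pipeline <- function(seed = 1L, config = analysis_config(),
                            experiment = NULL, ...) {
  if (is.null(experiment))
    experiment <- simulate_experiment(hu_regimes(), seed = seed,
                                      config = config, ...)
  layout <- experiment$layout
  origins <- experiment$origins
  truth <- experiment$truth
  strains <- names(experiment$fragments)
  peaks <- list(); called <- list()
  for (s in strains) {
    pooled <- do.call(rbind, experiment$fragments[[s]])
    raw <- bin_fragments(pooled, layout, config$bin_width)
    peaks[[s]] <- call_peaks(raw, layout, config)
    called[[s]] <- peaks_to_origins(peaks[[s]], origins, layout,
                                    config)$called
  }
  union_names <- origins$name[origins$name %in%
                                unique(c(called[[1L]], called[[2L]]))]
  union_origins <- origins[match(union_names, origins$name), , drop = FALSE]
  classification <- differential_analysis(
    experiment$fragments[[strains[1L]]], experiment$fragments[[strains[2L]]],
    union_origins, layout, config)
  metrics <- hu_recovery_metrics(called, classification, truth,
                                 strains = strains)
  list(experiment = experiment, peaks = peaks, called = called,
       classification = classification, metrics = metrics)
}

# Recovery metrics against the simulation truth (percentages).
hu_recovery_metrics <- function(called, classification, truth, strains) {
  wt <- strains[1L]; mut <- strains[2L]
  early <- truth$name[truth$mu_wt == min(truth$mu_wt)]
  late_unreg <- truth$name[truth$mu_wt > min(truth$mu_wt) & !truth$regulated]
  regulated <- truth$name[truth$regulated]
  pct <- function(x) 100 * mean(x)
  only_mut <- setdiff(called[[mut]], called[[wt]])
  cls <- classification$class[match(truth$name, classification$name)]
  cls[is.na(cls)] <- "uncalled"
  unregulated_truth <- truth$name[!truth$regulated]
  c(n_called_wt = length(called[[wt]]),
    n_called_mut = length(called[[mut]]),
    n_called_total = length(union(called[[wt]], called[[mut]])),
    early_called_wt_pct = pct(early %in% called[[wt]]),
    early_called_mut_pct = pct(early %in% called[[mut]]),
    late_unregulated_called_wt_pct =
      if (length(late_unreg)) pct(late_unreg %in% called[[wt]]) else NA_real_,
    regulated_called_only_mut_pct =
      if (length(regulated)) pct(regulated %in% only_mut) else NA_real_,
    n_repressed = sum(classification$class == "Rif1-repressed"),
    n_unregulated = sum(classification$class == "Rif1-unregulated"),
    n_activated = sum(classification$class == "Rif1-activated"),
    regulated_recovered_pct =
      if (length(regulated))
        pct(cls[match(regulated, truth$name)] == "Rif1-repressed")
      else NA_real_,
    unregulated_misclassified_pct =
      pct(cls[match(unregulated_truth, truth$name)] %in%
            c("Rif1-repressed", "Rif1-activated")))
}

#' Quartile metaprofile comparison between strains at S-phase timepoints
#'
#' Simulates the temporal experiment (both strains released into unperturbed
#' S-phase, harvested at the given timepoints), builds each strain's
#' smoothed/normalized/averaged track, and computes T_Rep-quartile
#' metaprofiles. Tracks are scaled to the fully-replicated plateau level
#' ([scale_track()]) before comparison, so strains with different numbers of
#' active origins share one per-cell scale (profile units are then
#' approximately the fraction of cells having replicated each position).
#'
#' @param seed Master integer seed.
#' @param timepoints Harvest times in minutes.
#' @param config An [analysis_config()].
#' @param window_bp Metaprofile window (40 kb default).
#' @param ... Passed to [simulate_experiment()].
#' @return List per timepoint: list per strain of quartile metaprofile
#'   `data.frame`s plus `quartile_means` (matrix strains x quartiles of
#'   origin-window profile means).
#' @export
run_timepoint_profiles <- function(seed = 1L, timepoints = c(25, 35),
                                   config = analysis_config(),
                                   window_bp = NULL, ...) {
  window_bp <- window_bp %||% config$profile_window
  seeds <- derive_seeds(seed, length(timepoints) + 2L)
  layout <- make_sim_genome(seed = seeds[length(timepoints) + 1L])
  placed <- place_origins(layout, seed = seeds[length(timepoints) + 2L], ...)
  out <- list()
  for (i in seq_along(timepoints)) {
    t_h <- timepoints[i]
    experiment <- simulate_experiment(timepoint_regimes(t_h),
                                      seed = seeds[i], layout = layout,
                                      origins = placed$origins,
                                      truth = placed$truth, config = config)
    profiles <- list()
    qmeans <- NULL
    for (s in names(experiment$fragments)) {
      track <- scale_track(
        build_signal_track(experiment$fragments[[s]], layout, config))
      prof <- quartile_metaprofiles(track, placed$origins, window_bp)
      profiles[[s]] <- prof
      m <- vapply(paste0("Q", 1:4), function(g)
        mean(prof$mean[prof$group == g], na.rm = TRUE), numeric(1L))
      qmeans <- rbind(qmeans, m)
    }
    rownames(qmeans) <- names(experiment$fragments)
    out[[as.character(t_h)]] <- list(profiles = profiles,
                                     quartile_means = qmeans)
  }
  out
}
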