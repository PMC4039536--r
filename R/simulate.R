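# Synthetic BrdU-IP-Seq experiments with known ground truth.
#
# The generator simulates population-level BrdU incorporation for wild-type
# and rif1-deletion cells, either arrested in hydroxyurea (HU) or harvested
# at fixed S-phase timepoints, then samples sequencing fragments from the
# expected incorporation density. Origin firing times are Normal(mu, sigma);
# a position is replicated in the fraction of cells in which some origin
# fired early enough for a fork to reach it by harvest, origins combining
# independently (passive replication). rif1-deletion advances a designated
# subset of late origins by `delta` minutes; everything else is untouched.
#
# HU is modeled as a harvest-time cutoff on the replication-program clock
# with slow forks: dNTP depletion stalls program progression in early
# S-phase, so a 45 min wall-clock HU arrest corresponds to roughly 25
# program-minutes, and forks crawl (~150 bp/min). Late origins (mu = 35 min)
# therefore remain unfired at harvest in wild type, while origins advanced
# below the cutoff in the mutant fire and become detectable - the behavior
# that makes HU a readout of origin timing. No explicit checkpoint mechanism
# is simulated.

#' Simulation regime
#'
#' Describes one strain x condition: genotype, arrest mode, harvest time on
#' the replication-program clock, fork speed, firing-time dispersion,
#' background fragment rate, sequencing depth and fragment length.
#'
#' @param label Regime label, e.g. `"WT"` or `"rif1d"`; labels containing
#'   `"rif1"` use the mutant firing times.
#' @param arrest `"HU"` (early S-phase arrest) or `"timepoint"` (synchronous
#'   S-phase harvest).
#' @param t_h Harvest time in program minutes. Defaults: 25 for HU (a 45 min
#'   wall-clock arrest), 25 for timepoint.
#' @param v Fork speed in bp/min. Defaults: 150 under HU (slow forks from
#'   dNTP depletion), 1500 in unperturbed S-phase.
#' @param sigma Firing-time standard deviation in minutes.
#' @param beta Background fragment rate (fragments per kb equivalent of
#'   replicated density).
#' @param depth Sequencing depth (fragments per library).
#' @param fragment_length Fragment length in bp.
#' @return Object of class `sim_regime`.
#' @export
sim_regime <- function(label,
                       arrest = c("HU", "timepoint"),
                       t_h = NULL,
                       v = NULL,
                       sigma = 4,
                       beta = 0.05,
                       depth = 2e5,
                       fragment_length = 250) {
  arrest <- match.arg(arrest)
  t_h <- t_h %||% 25
  v <- v %||% if (arrest == "HU") 150 else 1500
  stopifnot(t_h > 0, v > 0, sigma >= 0, beta >= 0, depth > 0,
            fragment_length > 0)
  structure(list(label = label,
                 genotype = if (grepl("rif1", label)) "rif1d" else "WT",
                 arrest = arrest, t_h = t_h, v = v, sigma = sigma,
                 beta = beta, depth = depth,
                 fragment_length = fragment_length),
            class = "sim_regime")
}

#' @export
print.sim_regime <- function(x, ...) {
  cat(sprintf(
    "sim_regime %s (%s): %s arrest, t_h = %g min, v = %g bp/min, sigma = %g\n",
    x$label, x$genotype, x$arrest, x$t_h, x$v, x$sigma))
  invisible(x)
}

#' The default HU experiment: WT and rif1-deletion regimes
#'
#' @param ... Passed to [sim_regime()] (e.g. `depth`).
#' @return Named list of two `sim_regime`s, wild type first.
#' @export
hu_regimes <- function(...) {
  list(WT = sim_regime("WT", "HU", ...),
       rif1d = sim_regime("rif1d", "HU", ...))
}

#' Timepoint regimes at a given harvest time
#'
#' @param t_h Harvest time in minutes after release (25 or 35 in the design
#'   this emulates).
#' @param ... Passed to [sim_regime()].
#' @return Named list of two `sim_regime`s, wild type first.
#' @export
timepoint_regimes <- function(t_h, ...) {
  list(WT = sim_regime("WT", "timepoint", t_h = t_h, ...),
       rif1d = sim_regime("rif1d", "timepoint", t_h = t_h, ...))
}

#' Simulate a genome layout
#'
#' Equal-length chromosomes with one 120 bp centromere placed at a seeded
#' uniform position per chromosome.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length Chromosome length in bp (>= 100 kb).
#' @param seed Integer seed.
#' @return A `genome_layout` with centromeres.
#' @export
make_sim_genome <- function(n_chrom = 4L, chrom_length = 5e5, seed = 1L) {
  stopifnot(n_chrom >= 1L, chrom_length >= 1e5)
  names <- paste0("chr", as.character(utils::as.roman(seq_len(n_chrom))))
  cen_start <- with_seed(seed,
                         floor(stats::runif(n_chrom, 0, chrom_length - 120)))
  genome_layout(
    data.frame(name = names, length = rep(chrom_length, n_chrom),
               stringsAsFactors = FALSE),
    centromeres = data.frame(chrom = names, start = cen_start,
                             end = cen_start + 120, stringsAsFactors = FALSE))
}

#' Place origins with firing-time ground truth
#'
#' Origins are distributed across chromosomes (round-robin), one per
#' equal-length segment with a seeded uniform jitter that keeps adjacent
#' origins at least 20 kb apart. A seeded subset of size
#' `round(early_fraction * n)` fires early (`mu_early`); the rest fire late
#' (`mu_late`). A seeded subset of late origins of size
#' `round(regulated_late_fraction * n_late)` is Rif1-regulated: its mutant
#' firing time is `mu - delta`. Each origin's `trep` is set to its wild-type
#' firing time so quartile analyses have a timing source.
#'
#' @param layout A `genome_layout`.
#' @param n_origins Total origins (>= 2 per chromosome).
#' @param early_fraction Fraction of origins firing early.
#' @param mu_early,mu_late Mean firing times in minutes (`mu_early <
#'   mu_late`).
#' @param regulated_late_fraction Fraction of late origins regulated by Rif1.
#' @param delta Advance in minutes applied to regulated origins in the
#'   mutant.
#' @param seed Integer seed.
#' @return List with `origins` (origin `data.frame`, status `"confirmed"`,
#'   `trep = mu_wt`) and `truth` (`data.frame`: `name`, `mu_wt`, `mu_rif1`,
#'   `regulated`).
#' @export
place_origins <- function(layout, n_origins = 40L, early_fraction = 0.5,
                          mu_early = 10, mu_late = 35,
                          regulated_late_fraction = 0.7, delta = 20,
                          seed = 1L) {
  n_chrom <- nrow(layout$chromosomes)
  stopifnot(n_origins >= 2L * n_chrom, mu_early < mu_late,
            early_fraction >= 0, early_fraction <= 1,
            regulated_late_fraction >= 0, regulated_late_fraction <= 1,
            delta >= 0)
  # allocate origins to chromosomes proportional to length
  # (largest-remainder rule), with at least 2 per chromosome
  quota <- n_origins * layout$chromosomes$length /
    sum(layout$chromosomes$length)
  per_chrom <- floor(quota)
  short <- n_origins - sum(per_chrom)
  if (short > 0) {
    bump <- order(quota - per_chrom, decreasing = TRUE)[seq_len(short)]
    per_chrom[bump] <- per_chrom[bump] + 1
  }
  while (any(per_chrom < 2L)) {
    i <- which.min(per_chrom); j <- which.max(per_chrom)
    per_chrom[i] <- per_chrom[i] + 1L
    per_chrom[j] <- per_chrom[j] - 1L
  }
  min_gap <- 20000
  with_seed(seed, {
    rows <- list()
    for (c_i in seq_len(n_chrom)) {
      chrom <- layout$chromosomes$name[c_i]
      len <- layout$chromosomes$length[c_i]
      n_c <- per_chrom[c_i]
      seg <- len / n_c
      if (seg < min_gap + 2000)
        stop("too many origins for the genome at the 20 kb spacing rule")
      # jitter inside the central (seg - min_gap) of each segment keeps
      # adjacent midpoints >= min_gap apart
      jitter_span <- seg - min_gap
      mids <- (seq_len(n_c) - 1) * seg + min_gap / 2 +
        stats::runif(n_c, 0, jitter_span)
      mids <- floor(pmin(pmax(mids, 1000), len - 1000))
      rows[[c_i]] <- data.frame(chrom = chrom, mid = mids,
                                stringsAsFactors = FALSE)
    }
    pos <- do.call(rbind, rows)
    n <- nrow(pos)
    n_early <- round(early_fraction * n)
    early_idx <- sample.int(n, n_early)
    mu_wt <- rep(mu_late, n)
    mu_wt[early_idx] <- mu_early
    late_idx <- setdiff(seq_len(n), early_idx)
    n_reg <- round(regulated_late_fraction * length(late_idx))
    reg_idx <- if (n_reg > 0L) sample(late_idx, n_reg) else integer()
    regulated <- seq_len(n) %in% reg_idx
    mu_rif1 <- mu_wt - delta * regulated
    name <- sprintf("simARS%03d", seq_len(n))
    origins <- data.frame(name = name, chrom = pos$chrom,
                          start = pos$mid - 100, end = pos$mid + 100,
                          status = "confirmed", trep = mu_wt,
                          stringsAsFactors = FALSE)
    validate_origins(origins, layout)
    truth <- data.frame(name = name, mu_wt = mu_wt, mu_rif1 = mu_rif1,
                        regulated = regulated, stringsAsFactors = FALSE)
    list(origins = origins, truth = truth)
  })
}

#' Expected per-bin BrdU incorporation density
#'
#' Deterministic expectation obtained by integrating over firing-time noise:
#' a position x is replicated by origin o in the fraction
#' `Phi((t_h - |x - mid(o)| / v - mu_o) / sigma)` of cells, and origins
#' combine independently as `1 - prod(1 - f_o)` (passive replication). The
#' density adds a uniform background of `beta * bin_width / 1000` per bin.
#' With `sigma = 0` the profile is an exact step: replicated within radius
#' `v * (t_h - mu)` (boundary included).
#'
#' @param layout A `genome_layout`.
#' @param origins Origin `data.frame`.
#' @param truth Truth `data.frame` from [place_origins()].
#' @param regime A [sim_regime()]; its genotype selects `mu_wt` or
#'   `mu_rif1`.
#' @param bin_width Bin width in bp.
#' @return A `binned_track` of expected densities (replicated fraction plus
#'   background, in cell-fraction units).
#' @export
replicated_fraction_profile <- function(layout, origins, truth, regime,
                                        bin_width = 50L) {
  stopifnot(identical(origins$name, truth$name))
  mu <- if (regime$genotype == "rif1d") truth$mu_rif1 else truth$mu_wt
  mids <- origin_midpoints(origins)
  track <- empty_track(layout, bin_width)
  bg <- regime$beta * bin_width / 1000
  for (chrom in names(track$values)) {
    nb <- length(track$values[[chrom]])
    if (nb == 0L) next
    x <- (seq_len(nb) - 1) * bin_width + bin_width / 2
    log_unrep <- numeric(nb)
    for (i in which(origins$chrom == chrom)) {
      t_fire_needed <- regime$t_h - abs(x - mids[i]) / regime$v
      f <- if (regime$sigma == 0) {
        as.numeric(t_fire_needed >= mu[i])
      } else {
        stats::pnorm((t_fire_needed - mu[i]) / regime$sigma)
      }
      log_unrep <- log_unrep + log1p(-f)
    }
    track$values[[chrom]] <- (1 - exp(log_unrep)) + bg
  }
  track
}

#' Sample sequencing fragments from a density profile
#'
#' Fragment start bins are drawn with probability proportional to the
#' density; the start position is uniform within the bin and the fragment
#' extends `fragment_length` bp (clipped at the chromosome end). Exactly
#' `depth` fragments are returned, reproducibly under the seed.
#'
#' @param density A `binned_track` of non-negative densities, not all zero.
#' @param depth Number of fragments (> 0).
#' @param fragment_length Fragment length in bp.
#' @param seed Integer seed.
#' @return Fragment `data.frame` (`chrom`, `start`, `end`).
#' @export
sample_fragments <- function(density, depth, fragment_length, seed) {
  stopifnot(depth > 0)
  v <- track_concat(density)
  if (any(v < 0)) stop("density must be non-negative")
  if (sum(v) == 0) stop("all-zero density")
  lens <- lengths(density$values)
  chrom_of_bin <- rep(names(density$values), lens)
  bin_in_chrom <- unlist(lapply(lens, seq_len), use.names = FALSE)
  bw <- density$bin_width
  with_seed(seed, {
    draws <- sample.int(length(v), size = depth, replace = TRUE, prob = v)
    offset <- floor(stats::runif(depth, 0, bw))
    chrom <- chrom_of_bin[draws]
    len <- unname(density$chrom_lengths[chrom])
    start <- pmin((bin_in_chrom[draws] - 1) * bw + offset, len - 1)
    end <- pmin(start + fragment_length, len)
    data.frame(chrom = chrom, start = start, end = end,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full BrdU-IP-Seq experiment
#'
#' Generates (or accepts) a genome and origin set, computes the expected
#' incorporation density of every regime, and samples replicate fragment
#' sets of exactly `depth` fragments each. Replicate seeds are derived
#' deterministically from the master seed. Note that BrdU-IP libraries are
#' compositional: when the mutant activates more origins, every locus's
#' share of a fixed-depth library shrinks, which is why the differential
#' module anchors its normalization on the genome-wide background rate
#' rather than on total fragment counts.
#'
#' @param regimes Named list of [sim_regime()]s with unique labels, the
#'   reference (wild-type) regime first.
#' @param n_replicates Replicates per regime.
#' @param seed Master integer seed.
#' @param layout,origins,truth Optional pre-built genome and origin set; by
#'   default [make_sim_genome()] and [place_origins()] run with their
#'   defaults and seeds derived from `seed`.
#' @param config An [analysis_config()] (bin width).
#' @param out_dir Optional directory: fragments are written as BED per
#'   regime x replicate, plus the origin table and the truth TSV.
#' @param ... Passed to [place_origins()] when origins are generated here
#'   (e.g. `n_origins`, `delta`).
#' @return List with `layout`, `origins`, `truth`, `regimes`, `depths`, and
#'   `fragments` (list: regime label -> list of fragment `data.frame`s).
#' @export
simulate_experiment <- function(regimes, n_replicates = 2L, seed = 1L,
                                layout = NULL, origins = NULL, truth = NULL,
                                config = analysis_config(), out_dir = NULL,
                                ...) {
  labels <- vapply(regimes, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) stop("duplicate regime labels")
  if (length(regimes) < 1L) stop("need at least one regime")
  seeds <- derive_seeds(seed, 2L + length(regimes) * n_replicates)
  if (is.null(layout)) layout <- make_sim_genome(seed = seeds[1L])
  if (is.null(origins)) {
    placed <- place_origins(layout, seed = seeds[2L], ...)
    origins <- placed$origins
    truth <- placed$truth
  }
  stopifnot(!is.null(truth))
  densities <- lapply(regimes, function(rg)
    replicated_fraction_profile(layout, origins, truth, rg, config$bin_width))
  depths <- vapply(regimes, `[[`, numeric(1L), "depth")
  fragments <- list()
  s <- 2L
  for (i in seq_along(regimes)) {
    reps <- list()
    for (r in seq_len(n_replicates)) {
      s <- s + 1L
      reps[[r]] <- sample_fragments(densities[[i]], depths[i],
                                    regimes[[i]]$fragment_length, seeds[s])
    }
    fragments[[labels[i]]] <- reps
  }
  result <- list(layout = layout, origins = origins, truth = truth,
                 regimes = regimes, depths = stats::setNames(depths, labels),
                 fragments = fragments)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (lab in labels) {
      for (r in seq_len(n_replicates)) {
        write_fragments_bed(fragments[[lab]][[r]],
                            file.path(out_dir,
                                      sprintf("%s_rep%d.bed", lab, r)))
      }
    }
    write_origin_table(origins, file.path(out_dir, "origins.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  result
}
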