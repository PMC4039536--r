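# Differential BrdU incorporation between strains at called origins.
#
# Two-group negative binomial exact conditional test with a single pooled
# dispersion, then Benjamini-Hochberg FDR and the three-way classification:
# Rif1-repressed (higher in the mutant), Rif1-unregulated, Rif1-activated
# (lower in the mutant). Two replicates per strain cannot support per-origin
# dispersion, so one common method-of-moments dispersion is shared.
#
# Fold-change sign convention: positive log2FC = higher signal in the mutant
# (i.e. repressed by Rif1 in wild type). Stated explicitly because the class
# names invert the sign.

#' Count fragments in origin windows
#'
#' Integer counts of fragment midpoints within the `origin_window` centered
#' on each origin midpoint, per sample, plus per-sample library sizes (total
#' fragments in the sample).
#'
#' @param fragment_sets Named list of two elements (wild type first, mutant
#'   second), each a list of replicate fragment `data.frame`s.
#' @param origins Origin `data.frame` (typically the union of origins called
#'   in either strain).
#' @param layout A `genome_layout`.
#' @param config An [analysis_config()].
#' @details Besides the raw per-sample totals, an effective library size is
#' estimated per sample from the genome-wide background rate
#' ([background_rate()] on the sample's binned track, scaled to the genome).
#' BrdU-IP libraries are compositional: activating more origins shrinks
#' every locus's share of a fixed sequencing depth, so total fragment counts
#' are confounded with the global firing change being tested, whereas the
#' non-replicated background rate is not. Downstream tests normalize by the
#' effective sizes.
#' @return List with `counts` (matrix origins x samples), `libsizes` (raw
#'   totals), `eff_libsizes` (background-anchored), `group` (factor of
#'   strain labels per sample).
#' @export
count_origin_windows <- function(fragment_sets, origins, layout,
                                 config = analysis_config()) {
  if (nrow(origins) == 0L) stop("empty origin list")
  if (length(fragment_sets) != 2L)
    stop("fragment_sets must name exactly two strains")
  win <- origin_windows(origins, layout, config$origin_window)
  samples <- list(); group <- character()
  libsizes <- numeric(); eff <- numeric(); eff_rel_var <- numeric()
  total_bins <- sum(n_bins(layout, config$bin_width))
  for (strain in names(fragment_sets)) {
    reps <- fragment_sets[[strain]]
    for (r in seq_along(reps)) {
      samples[[length(samples) + 1L]] <- reps[[r]]
      group <- c(group, strain)
      libsizes <- c(libsizes, nrow(reps[[r]]))
      rate <- background_rate(
        bin_fragments(reps[[r]], layout, config$bin_width))
      eff <- c(eff, rate * total_bins)
      eff_rel_var <- c(eff_rel_var, attr(rate, "rel_var") %||% 0)
    }
  }
  if (any(eff <= 0)) {
    log_info("zero background rate in some sample; ",
             "falling back to total-count library sizes")
    eff <- libsizes
    eff_rel_var <- rep(0, length(libsizes))
  }
  counts <- vapply(samples, function(frags) {
    count_midpoints_in_windows(frags, win)
  }, numeric(nrow(win)))
  counts <- matrix(counts, nrow = nrow(win))
  rownames(counts) <- origins$name
  colnames(counts) <- paste(group, stats::ave(seq_along(group), group,
                                              FUN = seq_along), sep = "_rep")
  list(counts = counts, libsizes = libsizes, eff_libsizes = eff,
       eff_rel_var = eff_rel_var,
       group = factor(group, levels = unique(group)))
}

count_midpoints_in_windows <- function(frags, win) {
  out <- numeric(nrow(win))
  if (nrow(frags) == 0L) return(out)
  mid <- floor((frags$start + frags$end) / 2)
  for (chrom in unique(win$chrom)) {
    wsel <- which(win$chrom == chrom)
    m <- mid[frags$chrom == chrom]
    if (length(m) == 0L) next
    for (i in wsel) {
      out[i] <- sum(m >= win$start[i] & m < win$end[i])
    }
  }
  out
}

#' Estimate a common negative binomial dispersion
#'
#' Method of moments on library-size-normalized counts: for each origin and
#' strain with at least two replicates, `phi_hat = (s^2 - m) / m^2`; the
#' common dispersion is the median over origin-strain pairs of
#' `max(phi_hat, 0)`, and 0 (Poisson) when every `phi_hat` is non-positive.
#' With two replicates this estimator is noisy and biased low; it is used
#' only as a shared overdispersion guard.
#'
#' @param counts Matrix origins x samples.
#' @param group Factor of strain labels per sample (>= 2 replicates each).
#' @param libsizes Per-sample library sizes.
#' @return Scalar dispersion `phi >= 0`.
#' @export
estimate_dispersion <- function(counts, group, libsizes) {
  group <- as.factor(group)
  if (any(table(group) < 2L))
    stop("need at least two replicates per strain")
  norm <- sweep(counts, 2L, mean(libsizes) / libsizes, `*`)
  phi_hat <- c()
  for (g in levels(group)) {
    sub <- norm[, group == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    ok <- m > 0
    phi_hat <- c(phi_hat, (v[ok] - m[ok]) / m[ok]^2)
  }
  if (length(phi_hat) == 0L) return(0)
  stats::median(pmax(phi_hat, 0))
}

#' Negative binomial exact conditional test for one origin
#'
#' Counts are scaled to the common effective library size (the mean library
#' size) and pooled per strain. Under the null that both strains share one
#' mean, the pooled wild-type count conditioned on the two-strain total is
#' free of the unknown mean: a negative hypergeometric split for `phi > 0`
#' (per-strain sizes `n_reps / phi`), a binomial split with probability
#' proportional to replicate numbers for `phi = 0`. The two-sided p-value
#' sums the probabilities of all splits at most as probable as the observed
#' one (minimum-likelihood rule), so `p` lies in `(0, 1]`; an all-zero origin
#' returns `p = 1` by convention.
#'
#' @param counts_wt,counts_mut Per-replicate counts for each strain.
#' @param libsizes_wt,libsizes_mut Matching library sizes.
#' @param phi Common dispersion from [estimate_dispersion()].
#' @return Two-sided p-value.
#' @export
nb_exact_test <- function(counts_wt, counts_mut, libsizes_wt, libsizes_mut,
                          phi = 0) {
  stopifnot(all(counts_wt >= 0), all(counts_mut >= 0), phi >= 0)
  common <- mean(c(libsizes_wt, libsizes_mut))
  a <- round(sum(counts_wt * common / libsizes_wt))
  b <- round(sum(counts_mut * common / libsizes_mut))
  total <- a + b
  if (total == 0) return(1)
  n1 <- length(counts_wt); n2 <- length(counts_mut)
  x <- 0:total
  if (phi <= .Machine$double.eps) {
    lp <- stats::dbinom(x, total, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    lp <- lgamma(x + r1) - lgamma(x + 1) - lgamma(r1) +
      lgamma(total - x + r2) - lgamma(total - x + 1) - lgamma(r2)
    lp <- lp - logsumexp(lp)
  }
  lobs <- lp[a + 1L]
  min(1, sum(exp(lp[lp <= lobs + 1e-10])))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min over j >= rank(i) of p_(j) * n / j`, capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n <- length(p)
  if (n == 0L) return(numeric())
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

#' Run the differential test and classify origins
#'
#' Applies [nb_exact_test()] per origin with a shared dispersion, corrects
#' with [bh_fdr()], and assigns the three-way class at `fdr_q_threshold`:
#' Rif1-repressed (`q < threshold` and log2FC > 0, i.e. higher in the
#' mutant), Rif1-activated (`q < threshold` and log2FC < 0), otherwise
#' Rif1-unregulated. Normalization uses the background-anchored effective
#' library sizes (see [count_origin_windows()]); the log2 fold change
#' compares normalized per-strain mean counts with a pseudocount of 0.5.
#'
#' @param counted Output of [count_origin_windows()].
#' @param origins Origin `data.frame`, rows matching `counted$counts`.
#' @param config An [analysis_config()].
#' @return Classification `data.frame` with columns `name`, `chrom`, `start`,
#'   `end`, `trep`, `count_wt`, `count_mut` (raw pooled counts), `log2fc`,
#'   `pvalue`, `qvalue`, `class`.
#' @export
classify_origins <- function(counted, origins, config = analysis_config()) {
  counts <- counted$counts
  group <- counted$group
  libsizes <- counted$eff_libsizes %||% counted$libsizes
  strains <- levels(group)
  if (length(strains) != 2L) stop("need exactly two strains")
  wt <- group == strains[1L]; mut <- group == strains[2L]
  phi <- estimate_dispersion(counts, group, libsizes)
  # Normalization divides by an estimated background rate; its relative
  # variance enters normalized counts as extra multiplicative noise,
  # equivalent to additional NB dispersion.
  phi <- phi + mean(counted$eff_rel_var %||% 0)
  log_debug("common dispersion phi = ", signif(phi, 3))
  pvals <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(counts[i, wt], counts[i, mut],
                  libsizes[wt], libsizes[mut], phi)
  }, numeric(1L))
  qvals <- bh_fdr(pvals)
  norm <- sweep(counts, 2L, mean(libsizes) / libsizes, `*`)
  mean_wt <- rowMeans(norm[, wt, drop = FALSE])
  mean_mut <- rowMeans(norm[, mut, drop = FALSE])
  log2fc <- log2((mean_mut + 0.5) / (mean_wt + 0.5))
  class <- ifelse(qvals < config$fdr_q_threshold & log2fc > 0, "Rif1-repressed",
           ifelse(qvals < config$fdr_q_threshold & log2fc < 0, "Rif1-activated",
                  "Rif1-unregulated"))
  data.frame(name = origins$name,
             chrom = origins$chrom,
             start = origins$start,
             end = origins$end,
             trep = origins$trep,
             count_wt = rowSums(counts[, wt, drop = FALSE]),
             count_mut = rowSums(counts[, mut, drop = FALSE]),
             log2fc = log2fc,
             pvalue = pvals,
             qvalue = qvals,
             class = class,
             stringsAsFactors = FALSE)
}

#' Full differential analysis from fragments to classes
#'
#' Convenience wrapper: count origin windows, estimate dispersion, test,
#' correct, classify.
#'
#' @param wt_fragments,mut_fragments Lists of replicate fragment
#'   `data.frame`s for the two strains.
#' @param origins Origin `data.frame` (the union of called origins).
#' @param layout A `genome_layout`.
#' @param config An [analysis_config()].
#' @return Classification `data.frame` (see [classify_origins()]).
#' @export
differential_analysis <- function(wt_fragments, mut_fragments, origins, layout,
                                  config = analysis_config()) {
  counted <- count_origin_windows(list(WT = wt_fragments, mut = mut_fragments),
                                  origins, layout, config)
  classify_origins(counted, origins, config)
}
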