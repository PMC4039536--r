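# Genomic-landscape statistics: T_Rep quartile metaprofiles, centromere /
# telomere proximity tables, distance-by-class tests, and binding-site
# overlap counts.

#' Assign replication-timing quartiles
#'
#' Origins are stably sorted by `(trep, name)` and split into four contiguous
#' rank blocks whose sizes differ by at most one; when `n mod 4 != 0` the
#' earlier quartiles receive the extra origins. Quartile 1 is the earliest.
#'
#' @param origins Origin `data.frame` with non-missing `trep`.
#' @return Integer vector of quartile labels (1-4) in input row order.
#' @export
assign_trep_quartiles <- function(origins) {
  n <- nrow(origins)
  if (n < 4L) stop("need at least 4 origins for quartiles")
  if (anyNA(origins$trep)) stop("origins with missing trep; filter them first")
  o <- order(origins$trep, origins$name)
  sizes <- n %/% 4L + as.integer(seq_len(4L) <= n %% 4L)
  lab <- integer(n)
  lab[o] <- rep.int(1:4, sizes)
  lab
}

#' Average signal profile centered on origin midpoints
#'
#' For each origin the track bins covering midpoint +/- `window_bp / 2` are
#' extracted at bin resolution; offsets reaching beyond a chromosome end
#' contribute nothing (the per-offset `n` is decremented there), and the mean
#' is taken over contributing origins per offset.
#'
#' @param track A `binned_track`.
#' @param origins Origin `data.frame` (the group to profile; must be
#'   non-empty).
#' @param window_bp Full profile window in bp (40 kb or 5 kb by default
#'   elsewhere).
#' @return `data.frame` with `offset_bp` (symmetric about 0), `mean` (NA
#'   where no origin contributes) and `n`.
#' @export
metaprofile <- function(track, origins, window_bp) {
  if (nrow(origins) == 0L) stop("empty origin group")
  bw <- track$bin_width
  K <- (as.integer(window_bp) %/% 2L) %/% bw
  offs <- (-K):K
  acc <- numeric(length(offs))
  nn <- integer(length(offs))
  mid <- origin_midpoints(origins)
  for (i in seq_len(nrow(origins))) {
    v <- track$values[[origins$chrom[i]]]
    center <- mid[i] %/% bw + 1L
    idx <- center + offs
    ok <- idx >= 1L & idx <= length(v)
    acc[ok] <- acc[ok] + v[idx[ok]]
    nn[ok] <- nn[ok] + 1L
  }
  data.frame(offset_bp = offs * bw,
             mean = ifelse(nn > 0L, acc / pmax(nn, 1L), NA_real_),
             n = nn)
}

#' Quartile metaprofiles for a track
#'
#' Convenience wrapper stacking [metaprofile()] over the four T_Rep
#' quartiles. Origins with missing `trep` are excluded (logged).
#'
#' @param track A `binned_track`.
#' @param origins Origin `data.frame`.
#' @param window_bp Full profile window in bp.
#' @return `data.frame` with columns `group` ("Q1".."Q4"), `offset_bp`,
#'   `mean`, `n`.
#' @export
quartile_metaprofiles <- function(track, origins, window_bp) {
  has_trep <- !is.na(origins$trep)
  if (any(!has_trep))
    log_info(sum(!has_trep), " origin(s) without T_Rep excluded from quartiles")
  origins <- origins[has_trep, , drop = FALSE]
  q <- assign_trep_quartiles(origins)
  out <- lapply(1:4, function(k) {
    prof <- metaprofile(track, origins[q == k, , drop = FALSE], window_bp)
    cbind(group = paste0("Q", k), prof, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Edge-gap distance to the nearest same-chromosome landmark
#'
#' Distance is 0 when intervals overlap, otherwise the gap between the
#' nearest edges (half-open semantics, the convention of the standard
#' interval tools). Cross-chromosome matches are never considered; queries on
#' chromosomes with no landmark get `NA` and a log line.
#'
#' @param query,landmarks `data.frame`s with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Numeric vector of distances in bp (NA where undefined).
#' @export
distance_to_nearest <- function(query, landmarks) {
  if (nrow(query) == 0L) return(numeric(0L))
  if (nrow(landmarks) == 0L) return(rep(NA_real_, nrow(query)))
  gq <- GenomicRanges::GRanges(query$chrom,
                               IRanges::IRanges(query$start + 1, query$end))
  gl <- GenomicRanges::GRanges(landmarks$chrom,
                               IRanges::IRanges(landmarks$start + 1,
                                                landmarks$end))
  # absent seqlevels in one set are expected (queries on chromosomes with
  # no landmark); the stock warning about them is noise here
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(gq, gl, ignore.strand = TRUE))
  d <- rep(NA_real_, nrow(query))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  if (anyNA(d))
    log_info(sum(is.na(d)), " quer(ies) on chromosomes without a landmark")
  d
}

# Midpoints of classified origins as 1-bp intervals.
midpoint_intervals <- function(origins) {
  mid <- origin_midpoints(origins)
  data.frame(chrom = origins$chrom, start = mid, end = mid + 1,
             stringsAsFactors = FALSE)
}

landmark_intervals <- function(layout, landmark = c("CEN", "TEL")) {
  landmark <- match.arg(landmark)
  if (landmark == "CEN") {
    if (is.null(layout$centromeres)) stop("layout has no centromeres")
    layout$centromeres[, c("chrom", "start", "end")]
  } else {
    telomere_intervals(layout)
  }
}

#' Per-class counts of origins within a distance of a landmark
#'
#' An origin is "within" when the edge-gap distance from its midpoint to the
#' nearest centromere interval (or chromosome-end position) is at most
#' `threshold` (the boundary itself counts as within).
#'
#' @param classified Classification `data.frame` (needs `class` plus
#'   coordinates).
#' @param layout A `genome_layout` (with centromeres for `landmark = "CEN"`).
#' @param landmark `"CEN"` or `"TEL"`.
#' @param threshold Distance in bp (20 kb by default elsewhere).
#' @return `data.frame` with `class`, `within`, `beyond` (within + beyond =
#'   class size).
#' @export
proximity_class_counts <- function(classified, layout,
                                   landmark = c("CEN", "TEL"),
                                   threshold = 20000) {
  landmark <- match.arg(landmark)
  d <- distance_to_nearest(midpoint_intervals(classified),
                           landmark_intervals(layout, landmark))
  within <- !is.na(d) & d <= threshold
  cls <- origin_class_levels(classified$class)
  data.frame(class = cls,
             within = vapply(cls, function(k)
               sum(within & classified$class == k), numeric(1L)),
             beyond = vapply(cls, function(k)
               sum(!within & classified$class == k), numeric(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

origin_class_levels <- function(x) {
  std <- c("Rif1-repressed", "Rif1-unregulated", "Rif1-activated")
  c(std[std %in% unique(x)], setdiff(unique(x), std))
}

#' Mean centromere distance per class, excluding landmark-proximal origins
#'
#' Origins within `threshold` of a centromere or a telomere are excluded
#' first (pericentric and subtelomeric origins would skew the means). For the
#' remaining origins the midpoint edge-gap distance to the nearest centromere
#' is summarized per class, and every class pair is compared with a Welch
#' two-sided t-test. Degenerate pairs (identical constant samples) get p = 1
#' by convention; classes with fewer than two members are flagged and
#' skipped.
#'
#' @param classified Classification `data.frame`.
#' @param layout A `genome_layout` with centromeres.
#' @param threshold Exclusion distance in bp.
#' @return List with `summary` (`class`, `n`, `mean_bp`), `tests`
#'   (`class_a`, `class_b`, `p_value`), and `n_excluded`.
#' @export
mean_distance_by_class <- function(classified, layout, threshold = 20000) {
  mids <- midpoint_intervals(classified)
  d_cen <- distance_to_nearest(mids, landmark_intervals(layout, "CEN"))
  d_tel <- distance_to_nearest(mids, landmark_intervals(layout, "TEL"))
  keep <- !is.na(d_cen) & d_cen > threshold &
    !is.na(d_tel) & d_tel > threshold
  cls <- origin_class_levels(classified$class)
  dist_by_class <- lapply(cls, function(k) d_cen[keep & classified$class == k])
  names(dist_by_class) <- cls
  summary <- data.frame(
    class = cls,
    n = vapply(dist_by_class, length, integer(1L)),
    mean_bp = vapply(dist_by_class, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(cls, 2L)
  tests <- data.frame(class_a = pairs[1L, ], class_b = pairs[2L, ],
                      p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    va <- dist_by_class[[pairs[1L, i]]]
    vb <- dist_by_class[[pairs[2L, i]]]
    if (length(va) < 2L || length(vb) < 2L) {
      log_info("t-test skipped for ", pairs[1L, i], " vs ", pairs[2L, i],
               " (class with n < 2)")
      next
    }
    if (stats::var(va) == 0 && stats::var(vb) == 0) {
      tests$p_value[i] <- if (mean(va) == mean(vb)) 1 else 0
    } else {
      tests$p_value[i] <- stats::t.test(va, vb, var.equal = FALSE)$p.value
    }
  }
  list(summary = summary, tests = tests, n_excluded = sum(!keep))
}

#' Read a binding-site table
#'
#' Tab-delimited with header columns `name`, `type` (`ORF` or `intergenic`),
#' `chrom`, `start`, `end` (1-based inclusive) and, for intergenic rows,
#' `gene_side` (`left` or `right`): the end of the intergenic interval that
#' abuts the gene for which the intergenic region is named. ORF sites keep
#' their whole coordinates; intergenic sites are reduced to the 1 kb of the
#' intergenic sequence nearest to the naming gene.
#'
#' @param path Path to the site TSV.
#' @param layout A `genome_layout`.
#' @return `data.frame` with `name`, `type`, `chrom`, `start`, `end` (0-based
#'   half-open effective windows).
#' @export
read_sites_table <- function(path, layout) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("name", "type", "chrom", "start", "end")
  if (!all(need %in% names(tab)))
    stop("site table must have columns ", paste(need, collapse = ", "))
  if (!all(tab$type %in% c("ORF", "intergenic")))
    stop("malformed feature type: ",
         tab$type[!tab$type %in% c("ORF", "intergenic")][1L])
  sites <- data.frame(name = tab$name, type = tab$type, chrom = tab$chrom,
                      start = as.numeric(tab$start) - 1,
                      end = as.numeric(tab$end), stringsAsFactors = FALSE)
  ig <- sites$type == "intergenic"
  if (any(ig)) {
    if (!"gene_side" %in% names(tab) || anyNA(tab$gene_side[ig]))
      stop("intergenic rows need a gene_side column (left/right)")
    side <- tab$gene_side[ig]
    if (!all(side %in% c("left", "right")))
      stop("gene_side must be 'left' or 'right'")
    s <- sites$start[ig]; e <- sites$end[ig]
    sites$start[ig] <- ifelse(side == "left", s, pmax(s, e - 1000))
    sites$end[ig] <- ifelse(side == "left", pmin(e, s + 1000), e)
  }
  validate_origins(sites, layout, what = "site table row")
  sites
}

#' Per-class counts of origins proximal to binding sites
#'
#' An origin is proximal when its `proximity_window` (1 kb, centered on the
#' midpoint) shares at least 1 bp with any effective site window (half-open
#' semantics). Subtelomeric origins (within `landmark_threshold` of a
#' chromosome end) can be excluded, as done when focusing on internal loci.
#'
#' @param classified Classification `data.frame`.
#' @param sites Site `data.frame` from [read_sites_table()].
#' @param layout A `genome_layout`.
#' @param config An [analysis_config()].
#' @param exclude_subtelomeric Drop subtelomeric origins first?
#' @return List with `per_class` (`class`, `n_class`, `proximal`), `total`
#'   proximal count, and `n_origins` analyzed.
#' @export
overlap_with_sites <- function(classified, sites, layout,
                               config = analysis_config(),
                               exclude_subtelomeric = FALSE) {
  origins <- classified
  if (exclude_subtelomeric) {
    d_tel <- distance_to_nearest(midpoint_intervals(origins),
                                 landmark_intervals(layout, "TEL"))
    origins <- origins[!is.na(d_tel) & d_tel > config$landmark_threshold, ,
                       drop = FALSE]
  }
  win <- origin_windows(origins, layout, config$proximity_window)
  prox <- overlaps_any(win, sites)
  cls <- origin_class_levels(origins$class)
  per_class <- data.frame(
    class = cls,
    n_class = vapply(cls, function(k) sum(origins$class == k), numeric(1L)),
    proximal = vapply(cls, function(k)
      sum(prox & origins$class == k), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_class = per_class, total = sum(prox), n_origins = nrow(origins))
}

#' Full genomic-landscape report
#'
#' Bundles the per-class counts, the centromere and telomere 20 kb proximity
#' tables, the distance-by-class summary with pairwise Welch tests, and
#' (optionally) binding-site overlap counts.
#'
#' @param classified Classification `data.frame`.
#' @param layout A `genome_layout` with centromeres.
#' @param config An [analysis_config()].
#' @param sites Optional site `data.frame` from [read_sites_table()].
#' @param exclude_subtelomeric Passed to [overlap_with_sites()].
#' @return List with `class_counts`, `cen_proximity`, `tel_proximity`,
#'   `cen_distance` and (if sites given) `site_overlap`.
#' @export
landscape_report <- function(classified, layout, config = analysis_config(),
                             sites = NULL, exclude_subtelomeric = TRUE) {
  cls <- origin_class_levels(classified$class)
  class_counts <- data.frame(
    class = cls,
    n = vapply(cls, function(k) sum(classified$class == k), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(
    n_origins = nrow(classified),
    class_counts = class_counts,
    cen_proximity = proximity_class_counts(classified, layout, "CEN",
                                           config$landmark_threshold),
    tel_proximity = proximity_class_counts(classified, layout, "TEL",
                                           config$landmark_threshold),
    cen_distance = mean_distance_by_class(classified, layout,
                                          config$landmark_threshold))
  if (!is.null(sites)) {
    out$site_overlap <- overlap_with_sites(classified, sites, layout, config,
                                           exclude_subtelomeric)
  }
  out
}
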