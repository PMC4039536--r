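# On-disk writers (and their round-trip readers).
#
# All numeric columns are written with full (17 significant digit) precision
# so a write-then-read round trip reproduces values exactly and re-writing
# reproduces the file text bit-for-bit.

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      sprintf("%.0f", v)
    } else {
      sprintf("%.17g", v)
    }
  }, character(1L))
  out
}

#' Write a binned track as bedGraph
#'
#' Emits one line per maximal run of equal-valued adjacent bins. The final
#' bin of each chromosome is clipped to the chromosome length.
#'
#' @param track A `binned_track` (see [bin_fragments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bw <- track$bin_width
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0, ends_bin[-length(ends_bin)])
    start <- starts_bin * bw
    end <- pmin(ends_bin * bw, track$chrom_lengths[[chrom]])
    writeLines(paste(chrom, format_num(start), format_num(end),
                     format_num(r$values), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] back into a binned track
#'
#' Requires interval boundaries to fall on bin boundaries (the final interval
#' of each chromosome may be clipped to the chromosome length).
#'
#' @param path Path to the bedGraph file.
#' @param layout A `genome_layout`.
#' @param bin_width Bin width in bp.
#' @return A `binned_track`.
#' @export
read_bedgraph <- function(path, layout, bin_width) {
  track <- empty_track(layout, bin_width)
  if (file.size(path) == 0L) return(track)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  chrom <- as.character(tab[[1L]])
  i <- match(chrom, layout$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome in bedGraph: ",
                     chrom[which(is.na(i))[1L]])
  start <- as.numeric(tab[[2L]]); end <- as.numeric(tab[[3L]])
  val <- as.numeric(tab[[4L]])
  if (any(start %% bin_width != 0)) stop("bedGraph not aligned to bin grid")
  for (r in seq_along(chrom)) {
    v <- track$values[[chrom[r]]]
    b0 <- start[r] / bin_width + 1L
    b1 <- ceiling(end[r] / bin_width)
    v[b0:b1] <- val[r]
    track$values[[chrom[r]]] <- v
  }
  track
}

classification_columns <- c("name", "chrom", "start", "end", "trep",
                            "count_wt", "count_mut", "log2fc",
                            "pvalue", "qvalue", "class")

#' Write an origin classification table
#'
#' Tab-delimited with header columns `name`, `chrom`, `start`, `end`, `trep`,
#' `count_wt`, `count_mut`, `log2fc`, `pvalue`, `qvalue`, `class`
#' (coordinates 0-based half-open, counts pooled over replicates). An empty
#' record set yields a header-only file.
#'
#' @param records Classification `data.frame` (see [classify_origins()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(records, path) {
  missing_cols <- setdiff(classification_columns, names(records))
  if (length(missing_cols))
    stop("classification records lack columns: ",
         paste(missing_cols, collapse = ", "))
  out <- records[, classification_columns, drop = FALSE]
  for (col in c("start", "end", "trep", "count_wt", "count_mut",
                "log2fc", "pvalue", "qvalue")) {
    out[[col]] <- format_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an origin classification table
#'
#' @param path Path written by [write_classification_tsv()].
#' @return Classification `data.frame`.
#' @export
read_classification_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = c(name = "character",
                                          chrom = "character",
                                          class = "character"))
  missing_cols <- setdiff(classification_columns, names(tab))
  if (length(missing_cols))
    stop("classification file lacks columns: ",
         paste(missing_cols, collapse = ", "))
  tab[, classification_columns, drop = FALSE]
}

#' Write a metaprofile table
#'
#' Tab-delimited with header columns `group`, `offset_bp`, `mean`, `n`.
#'
#' @param profile Metaprofile `data.frame` (see [metaprofile()]); may carry a
#'   `group` column when several groups are stacked.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metaprofile_tsv <- function(profile, path) {
  if (!"group" %in% names(profile)) profile$group <- "all"
  out <- data.frame(group = profile$group,
                    offset_bp = format_num(profile$offset_bp),
                    mean = format_num(profile$mean),
                    n = format_num(profile$n),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
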