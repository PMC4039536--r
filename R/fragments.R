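# Aligned read fragments.
#
# The pipeline starts from fragment intervals (BED3+, 0-based half-open);
# alignment-format handling happens upstream. Strand is ignored throughout:
# BrdU incorporation marks nascent DNA on both strands.

#' Read aligned fragments from a BED file
#'
#' BED3 or wider; only the first three columns are used. Coordinates are
#' native (0-based half-open). Row order is preserved.
#'
#' @param path Path to the BED file. A zero-length file yields an empty
#'   fragment set.
#' @param layout A `genome_layout` for validation.
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_fragments_bed <- function(path, layout) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(tab) < 3L) stop("BED file must have at least 3 columns: ", path)
  frags <- data.frame(chrom = as.character(tab[[1L]]),
                      start = as.numeric(tab[[2L]]),
                      end = as.numeric(tab[[3L]]),
                      stringsAsFactors = FALSE)
  validate_fragments(frags, layout)
  frags
}

validate_fragments <- function(frags, layout) {
  i <- match(frags$chrom, layout$chromosomes$name)
  if (anyNA(i)) {
    bad <- which(is.na(i))[1L]
    stop("unknown chromosome '", frags$chrom[bad], "' in fragment ", bad)
  }
  len <- layout$chromosomes$length[i]
  bad <- frags$start < 0 | frags$end > len | frags$end <= frags$start
  if (any(bad))
    stop("invalid fragment interval at row ", which(bad)[1L],
         " (need 0 <= start < end <= chromosome length)")
  invisible(frags)
}

#' Write fragments as BED3
#'
#' @param frags Fragment `data.frame` (`chrom`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path) {
  out <- data.frame(frags$chrom, format_num(frags$start),
                    format_num(frags$end))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
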