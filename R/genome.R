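# Genome layout: the coordinate frame shared by every module.
#
# All coordinates inside the package are 0-based half-open ([start, end)),
# matching BED semantics. Readers of 1-based inclusive tables (OriDB-style
# origin tables, centromere tables) perform the conversion on input.

#' Construct a genome layout
#'
#' A genome layout holds the ordered chromosome set, optional centromere
#' intervals, and implicit telomere positions (position 0 and the chromosome
#' length at each end).
#'
#' @param chromosomes `data.frame` with columns `name` (unique) and `length`
#'   (bp, > 0), in the desired chromosome order.
#' @param centromeres Optional `data.frame` with columns `chrom`, `start`,
#'   `end` in 0-based half-open coordinates, one row per chromosome at most;
#'   every interval must lie inside its chromosome.
#' @return Object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, centromeres = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes <- data.frame(name = as.character(chromosomes$name),
                            length = as.numeric(chromosomes$length),
                            stringsAsFactors = FALSE)
  if (nrow(chromosomes) == 0L) stop("no chromosomes")
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome name: ",
         chromosomes$name[duplicated(chromosomes$name)][1L])
  if (any(!is.finite(chromosomes$length) | chromosomes$length <= 0))
    stop("non-positive chromosome length")
  layout <- structure(list(chromosomes = chromosomes, centromeres = NULL),
                      class = "genome_layout")
  if (!is.null(centromeres)) layout <- set_centromeres(layout, centromeres)
  layout
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %.3f Mb total, %s centromeres\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              if (is.null(x$centromeres)) "no" else nrow(x$centromeres)))
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", chrom[which(is.na(i))[1L]])
  layout$chromosomes$length[i]
}

n_bins <- function(layout, bin_width) {
  ceiling(layout$chromosomes$length / bin_width)
}

set_centromeres <- function(layout, centromeres) {
  stopifnot(is.data.frame(centromeres),
            all(c("chrom", "start", "end") %in% names(centromeres)))
  centromeres <- data.frame(chrom = as.character(centromeres$chrom),
                            start = as.numeric(centromeres$start),
                            end = as.numeric(centromeres$end),
                            stringsAsFactors = FALSE)
  len <- chrom_length(layout, centromeres$chrom)
  bad <- centromeres$start < 0 | centromeres$end > len |
    centromeres$start >= centromeres$end
  if (any(bad))
    stop("centromere interval outside chromosome bounds for ",
         centromeres$chrom[which(bad)[1L]])
  if (anyDuplicated(centromeres$chrom))
    stop("more than one centromere for chromosome ",
         centromeres$chrom[duplicated(centromeres$chrom)][1L])
  layout$centromeres <- centromeres
  layout
}

#' Read a chrom.sizes file
#'
#' Two-column whitespace-delimited text: chromosome name, then length in bp.
#' Chromosome order follows file order; telomere positions are implicitly 0
#' and the chromosome length.
#'
#' @param path Path to the chrom.sizes file.
#' @return A `genome_layout` without centromeres.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no chromosomes in ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop("malformed chrom.sizes line ", which(nf != 2L)[1L], " in ", path)
  name <- vapply(fields, `[[`, character(1L), 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 2L)))
  if (anyNA(len))
    stop("malformed chrom.sizes line ", which(is.na(len))[1L], " in ", path)
  genome_layout(data.frame(name = name, length = len, stringsAsFactors = FALSE))
}

#' Read a centromere coordinate table
#'
#' Tab-delimited with a header naming columns `chrom`, `start`, `end`.
#' Coordinates are 1-based inclusive (annotation-table dialect) and are
#' converted to the internal 0-based half-open convention.
#'
#' @param path Path to the centromere TSV.
#' @param layout A `genome_layout`; centromeres are validated against it.
#' @return The layout with centromeres attached.
#' @export
read_centromeres <- function(path, layout) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(tab)))
    stop("centromere table must have columns ", paste(need, collapse = ", "))
  set_centromeres(layout, data.frame(chrom = tab$chrom,
                                     start = tab$start - 1,
                                     end = tab$end,
                                     stringsAsFactors = FALSE))
}

# Telomere landmarks: the terminal base pair of each chromosome end,
# as 0-based half-open 1-bp intervals.
telomere_intervals <- function(layout) {
  chr <- layout$chromosomes
  data.frame(chrom = rep(chr$name, each = 2L),
             start = as.vector(rbind(0, chr$length - 1)),
             end = as.vector(rbind(1, chr$length)),
             stringsAsFactors = FALSE)
}
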