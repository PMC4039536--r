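# Replication origin tables.
#
# Origins follow the OriDB convention on disk: 1-based inclusive coordinates,
# a status column restricted to "confirmed"/"likely" (other rows, e.g.
# "dubious", are dropped), and a T_Rep column in minutes (may be missing).
# In memory, coordinates are 0-based half-open like everything else.

#' Read an origin annotation table
#'
#' Tab-delimited with a header naming columns `name`, `chrom`, `start`, `end`,
#' `status`, `trep`. Coordinates are 1-based inclusive and converted to the
#' internal 0-based half-open convention (start - 1, end). Rows whose status
#' is not `confirmed` or `likely` are dropped; the drop count is logged and
#' attached as attribute `n_dropped`.
#'
#' @param path Path to the origin TSV.
#' @param layout A `genome_layout` used to validate chromosome names and
#'   bounds.
#' @return `data.frame` with columns `name`, `chrom`, `start`, `end`,
#'   `status`, `trep` (0-based half-open; `trep` may contain `NA`).
#' @export
read_origin_table <- function(path, layout) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("name", "chrom", "start", "end", "status", "trep")
  if (!all(need %in% names(tab)))
    stop("origin table must have columns ", paste(need, collapse = ", "))
  keep <- tab$status %in% c("confirmed", "likely")
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    log_info(n_dropped, " origin(s) dropped (status not confirmed/likely)")
  tab <- tab[keep, , drop = FALSE]
  origins <- data.frame(name = as.character(tab$name),
                        chrom = as.character(tab$chrom),
                        start = as.numeric(tab$start) - 1,
                        end = as.numeric(tab$end),
                        status = as.character(tab$status),
                        trep = as.numeric(tab$trep),
                        stringsAsFactors = FALSE)
  validate_origins(origins, layout, what = "origin table row")
  attr(origins, "n_dropped") <- n_dropped
  origins
}

validate_origins <- function(origins, layout, what = "origin") {
  i <- match(origins$chrom, layout$chromosomes$name)
  if (anyNA(i)) {
    bad <- which(is.na(i))[1L]
    stop("unknown chromosome '", origins$chrom[bad], "' in ", what, " ", bad)
  }
  len <- layout$chromosomes$length[i]
  bad <- origins$start < 0 | origins$end > len | origins$start >= origins$end
  if (any(bad)) {
    b <- which(bad)[1L]
    stop(what, " ", b, " ('", origins$name[b],
         "') outside chromosome bounds or start >= end")
  }
  invisible(origins)
}

#' Write an origin annotation table
#'
#' Inverse of [read_origin_table()]: converts the internal 0-based half-open
#' coordinates back to the 1-based inclusive on-disk dialect.
#'
#' @param origins Origin `data.frame` (internal convention).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_origin_table <- function(origins, path) {
  out <- data.frame(name = origins$name,
                    chrom = origins$chrom,
                    start = format_num(origins$start + 1),
                    end = format_num(origins$end),
                    status = origins$status,
                    trep = format_num(origins$trep),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Origin midpoints (0-based position of the central base).
origin_midpoints <- function(origins) {
  floor((origins$start + origins$end) / 2)
}

# The window of `window_bp` centered on each origin midpoint, clipped to the
# chromosome, 0-based half-open.
origin_windows <- function(origins, layout, window_bp) {
  mid <- origin_midpoints(origins)
  half <- window_bp / 2
  len <- chrom_length(layout, origins$chrom)
  data.frame(name = origins$name,
             chrom = origins$chrom,
             start = pmax(0, mid - half),
             end = pmin(len, mid + half),
             stringsAsFactors = FALSE)
}
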