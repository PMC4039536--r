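# Internal helpers shared across modules.

# Logging goes to standard error so that stdout stays clean for data.
# Levels: 0 = quiet, 1 = info (default), 2 = debug.
.log_level <- new.env(parent = emptyenv())
.log_level$level <- 1L

#' Set the package log verbosity
#'
#' @param level 0 (quiet), 1 (info) or 2 (debug). Messages are written to
#'   standard error.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L, level >= 0)
  old <- .log_level$level
  .log_level$level <- as.integer(level)
  invisible(old)
}

log_info <- function(...) {
  if (.log_level$level >= 1L) message("[repliscape] ", ...)
}

log_debug <- function(...) {
  if (.log_level$level >= 2L) message("[repliscape:debug] ", ...)
}

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `n` child seeds (< 2^31) deterministically from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Stable log(sum(exp(x))) for vectors possibly containing -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
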