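# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals do not
#' perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Timestamped diagnostic logging to stderr
#'
#' Level-controlled via `options(driverGCN.verbose = )`: 0 silences
#' everything, 1 (default) emits info messages, 2 adds debug detail.
#' An optional log file mirrors the stream
#' (`options(driverGCN.logfile = "path")`).
#'
#' @param ... message parts, pasted without separator.
#' @param level "info" or "debug".
#' @return invisibly, the formatted line.
#' @export
dg_log <- function(..., level = "info") {
  verbosity <- getOption("driverGCN.verbose", 1L)
  threshold <- if (identical(level, "debug")) 2L else 1L
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(...))
  if (verbosity >= threshold) {
    message(line)
    logfile <- getOption("driverGCN.logfile", NULL)
    if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  }
  invisible(line)
}

# stop() with a consistent prefix and no call noise
dg_stop <- function(...) stop(paste0(...), call. = FALSE)

# clamp probabilities away from 0/1 before taking logs
clamp_prob <- function(x, eps = 1e-7) pmin(pmax(x, eps), 1 - eps)
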