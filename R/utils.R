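## Internal helpers shared across modules.

#' Derive a stage-specific RNG seed from a master seed
#'
#' Each pipeline stage draws from its own RNG substream, derived
#' deterministically from the master seed and the stage name, so that adding
#' or reordering stages never perturbs the random numbers seen by another
#' stage. The result is always a valid 32-bit integer seed.
#'
#' @param masterSeed single integer master seed.
#' @param stage character stage name (e.g. `"radseq"`).
#' @return an integer seed.
#' @examples
#' stageSeed(1L, "quartet")
#' @export
stageSeed <- function(masterSeed, stage) {
  stopifnot(length(masterSeed) == 1L, is.finite(masterSeed),
            is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 1000000007
  as.integer((abs(masterSeed) %% 65536 * 32749 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## set.seed without clobbering the caller's RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## stop() with a subclassed condition so callers can distinguish
## "statistic undefined on this input" from programming errors
undefinedStat <- function(msg) {
  stop(structure(class = c("radelim_undefined", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## inclusive interval membership with a small tolerance for standardized
## ratios that went through decimal rounding
inInterval <- function(x, lo, hi, tol = 1e-9) {
  x >= lo - tol & x <= hi + tol
}

## length of the intersection of [a1,a2] and [b1,b2]; 0 when disjoint
intervalIntersection <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}
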