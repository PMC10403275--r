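#' @importFrom stats cor cooks.distance lm coef vcov pt qt rnorm runif rpois
#'   sd predict model.matrix setNames complete.cases
#' @importFrom methods new validObject is slot show
#' @importFrom utils read.csv write.csv read.delim packageVersion
NULL

## clamp x into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a child RNG seed from a master seed
#'
#' Counter-based fan-out so that independent pipeline stages (and independent
#' subjects within a stage) get reproducible, non-overlapping seeds from one
#' master seed. Purely arithmetic; does not touch the global RNG state.
#'
#' @param master integer master seed.
#' @param stage stage counter (integer, >= 0); by convention one per module.
#' @param unit unit counter within the stage (e.g. subject index), default 0.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
fanSeed <- function(master, stage, unit = 0L) {
  m <- 2147483629 # largest prime below 2^31
  s <- (as.double(master) %% m) * 48271 + as.double(stage) * 1299709 +
    as.double(unit) * 7919
  as.integer(s %% m)
}

## run expr with a local RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
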