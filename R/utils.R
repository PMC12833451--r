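#' @importFrom methods new validObject is as slot
#' @importFrom stats kmeans dist rnorm runif rpois rnbinom sd var
#' @importFrom utils head read.csv write.csv
NULL

## Classed conditions so callers (and the CLI) can map failures to exit codes.
stopValidation <- function(...) {
  stop(errorCondition(paste0(...), class = c("spaFuse_validation_error", "error")))
}

stopIO <- function(...) {
  stop(errorCondition(paste0(...), class = c("spaFuse_io_error", "error")))
}

stopNumerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("spaFuse_numerical_error", "error")))
}

#' Derive a stage seed from a top-level seed
#'
#' A single integer seed reproduces a whole run: every stage that consumes
#' randomness derives its own seed from the top-level seed plus a string tag
#' via a 31-multiplier polynomial hash reduced modulo 2^31 - 1. The mapping is
#' stable across platforms and documented so external tools can reproduce any
#' stage in isolation.
#'
#' @param seed integer top-level seed.
#' @param ... character or numeric tags naming the stage (e.g. `"encoder"`,
#'   a quality level, a run index); concatenated with `"/"`.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' deriveSeed(1, "encoder", "Q1", 3)
deriveSeed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

## Evaluate expr with a local RNG state; the caller's stream is untouched.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Case-folded, whitespace-stripped gene symbol keys. Originals are kept for
## output; matching is always done on the folded form.
foldSymbols <- function(x) {
  toupper(trimws(as.character(x)))
}

asMatrix <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else x
}
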