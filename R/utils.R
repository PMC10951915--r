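# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
# All generators route their randomness through this so that a seed plus
# parameters fully determines the output, with no hidden global state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Dropped/excluded entity counts are reported via message() so pipeline logs
# capture them; callers that need the counts get them from attributes.
logNote <- function(fmt, ...) message(sprintf(fmt, ...))

stopIfNot <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

# assay shortcut
exprValues <- function(x) SummarizedExperiment::assay(x, 1L)
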