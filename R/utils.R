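## internal helpers

## Evaluate expr with a temporarily seeded RNG, restoring the caller's
## RNG state afterwards. seed = NULL leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive n child seeds from one parent seed, all below 2^31.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Longest run of TRUE (ties -> earliest). Returns c(start, length) or NULL.
longestRun <- function(flag) {
  if (!any(flag)) return(NULL)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  c(start = starts[best], length = r$lengths[best])
}

## Maximum run length of TRUE in a logical vector (0 if none).
maxRunLength <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

stopifnotScalarCount <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop(what, " must be a single positive integer")
  invisible(as.integer(x))
}
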