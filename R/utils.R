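#' @import methods
#' @importFrom stats rnorm runif rgamma fft sd var cor lm shapiro.test qnorm median aggregate complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

# Deterministic 32-bit stream mixing: derives independent sub-seeds from a
# master seed so every subject/chain gets its own reproducible stream.
# splitmix-style integer hash, kept below 2^31.
mixSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (i in idx) {
    h <- (h * 48271 + as.numeric(i) * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

# withSeed: evaluate expr under a local RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# segment lengths -> start indices of each contiguous segment
segmentStarts <- function(segments) {
  cumsum(c(1L, head(segments, -1L)))
}

stopIfNot <- function(cond, msg, class = "microstatesError") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}
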