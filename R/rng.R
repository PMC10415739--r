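#' Derive a reproducible sub-seed from a master seed
#'
#' A single master seed fans out to named substreams (e.g. "pool", "radii",
#' "partition", "noise") so that the individual simulation stages are
#' independently reproducible: changing the number of droplets does not
#' perturb the pool, and vice versa.
#'
#' The mapping is a small deterministic integer hash of the stream name
#' folded into the master seed, reduced modulo 2^31 - 1 so the result is
#' always a valid R integer seed.
#'
#' @param seed master seed, a single non-negative integer.
#' @param stream character scalar naming the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(1, "pool")
#' substream_seed(1, "noise")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0,
            is.character(stream), length(stream) == 1, nzchar(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% m
  }
  as.integer((seed %% m + h * 2654435.0) %% m)
}

with_substream <- function(seed, stream, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(substream_seed(seed, stream))
  }
  force(expr)
}
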