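#' Derive a named seed stream from a master seed
#'
#' Deterministically maps a (master seed, stream name) pair to an integer
#' seed. Each simulation stage draws from its own named stream, so adding or
#' reordering stages never perturbs another stage's pseudo-random draws.
#'
#' @param master Integer master seed.
#' @param stream Character stream name (e.g. `"coverage/wt/me3"`).
#' @return A single integer seed in `[0, 2^31)`.
#' @examples
#' stream_seed(1, "features") != stream_seed(1, "coverage")
#' @export
stream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stream), length(stream) == 1L)
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 2147483647
  # all arithmetic stays below 2^53, so doubles are exact
  as.integer(((abs(master) %% 2147483647) * 69621 + h) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG state seeded from (master, stream);
# the caller's RNG state is restored afterwards.
with_stream <- function(master, stream, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(master, stream))
  expr
}
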