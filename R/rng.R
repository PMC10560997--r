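#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows through named, counter-indexed
#' sub-streams derived from one master seed. Deriving per-image / per-batch
#' seeds from `(master, stream, counter)` rather than drawing from one rolling
#' stream means that changing the number of images, Monte-Carlo samples or
#' discriminators never reshuffles the randomness used by earlier items, and
#' that two training loops consuming different subsets of streams (e.g. the
#' ensemble framework and the single-discriminator baseline) still see
#' identical draws for the streams they share.
#'
#' The hash folds the stream label and counter into `[0, 2^31 - 2]` with exact
#' double-precision integer arithmetic (a 31-bit multiplicative string hash),
#' so results are identical across platforms.
#'
#' @param master integer master seed.
#' @param stream character label of the random stream (e.g. `"init"`, `"z"`).
#' @param counter non-negative integer index within the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(7, "z", 0)
#' substream_seed(7, "z", 1)
#' @export
substream_seed <- function(master, stream, counter = 0) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(master) + 11) %% m
  key <- paste0(stream, "#", format(counter, scientific = FALSE))
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# run expr under a derived seed, restoring the caller's RNG state
with_stream <- function(master, stream, counter, expr) {
  withr::with_seed(substream_seed(master, stream, counter), expr)
}
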