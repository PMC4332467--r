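#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one master seed through named
#' sub-streams, so that e.g. fold shuffling, SMO tie-breaking, permutation
#' draws and each simulated subject consume disjoint, individually
#' reproducible streams. Adding a subject to a cohort therefore never
#' perturbs the draws of earlier subjects.
#'
#' The derivation is a small multiplicative hash over the stream name and
#' index, reduced modulo 2^31 - 1 so the result is always a valid R integer
#' seed.
#'
#' @param master integer master seed.
#' @param stream character stream name (e.g. `"folds"`, `"subject"`).
#' @param index non-negative integer distinguishing draws within a stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(1, "folds")
#' substream_seed(1, "subject", 7)
#' @export
substream_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1; 31 * m < 2^53 so double arithmetic is exact
  h <- abs(as.numeric(master)) %% m
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% m
  h <- (h * 31 + (abs(as.numeric(index)) %% m)) %% m
  as.integer(h)
}
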