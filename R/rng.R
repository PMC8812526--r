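#' Derive a named substream seed from a master seed
#'
#' Hashes a master seed together with an arbitrary sequence of labels into a
#' 32-bit integer seed (FNV-1a over the label string). Substreams keep every
#' stochastic unit of work (a participant, a draw, a model fit) on its own
#' reproducible stream, so that e.g. adding participants to a cohort does not
#' perturb the phantoms generated for earlier ones.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) naming the substream.
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' substream_seed(42, "cohort")
#' substream_seed(42, "draw", 10, 3)
#' @export
substream_seed <- function(master, ...) {
  label <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                 collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 2166136261
  for (b in bytes) {
    # XOR the low byte only (codepoints < 256 after utf8 expansion of ASCII
    # labels; wider codepoints fold onto their low byte, which is fine for
    # stream separation)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime, split to stay inside 2^53
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# Run code under a temporary seed, restoring the caller's RNG state.
with_substream <- function(seed, code) {
  withr::with_seed(seed, code)
}
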