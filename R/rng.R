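#' Derive a reproducible sub-stream seed
#'
#' Hashes a global integer seed together with a path of string labels
#' (e.g. `"tracks", "P1", "rep2"`) into a new seed below 2^31. Simulation
#' functions seed each logical sub-stream (per TF, per repeat, per stage)
#' independently, so adding repeats or TFs to a scenario does not perturb
#' the draws of earlier ones.
#'
#' @param seed integer global seed.
#' @param ... character or numeric labels identifying the sub-stream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(42, "tracks", "P1", 1)
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  tokens <- paste(vapply(list(...), function(x) paste(x, collapse = ","),
                         character(1)), collapse = "/")
  h <- as.double(abs(seed) %% 2147483647)
  for (code in utf8ToInt(tokens)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}
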