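#' Derive an independent sub-seed from a master seed and a stream name
#'
#' One master seed drives every stochastic component (topology, delays,
#' background, oscillation, initial conditions, ...). Each component derives
#' its own seed from the master seed and a short stream label, so that e.g.
#' redrawing the background noise leaves the topology untouched. The
#' derivation is a small integer hash (splitmix-style mixing of the label
#' bytes into the seed), kept strictly below 2^31.
#'
#' @param seed master seed (integer)
#' @param stream stream label (character scalar)
#' @return an integer in \[0, 2^31)
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(length(stream) == 1, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(stream)) {
    h <- (h * 31 + b) %% 2147483647
    h <- (h * 2654435761) %% 2147483647  # Knuth multiplicative mix
  }
  as.integer(h)
}

with_stream_seed <- function(seed, stream, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(derive_seed(seed, stream))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
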