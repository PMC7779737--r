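#' Derive a reproducible substream seed from a master seed
#'
#' Mixes a master seed with an arbitrary sequence of integer or string
#' tokens (cluster size, RR level, iteration index, purpose tag ...) into
#' a single 31-bit seed, so that any cell of a factorial experiment can be
#' re-run in isolation with exactly the stream it had inside the full run.
#'
#' The mix is a Lehmer-style multiplicative congruential hash computed in
#' double precision; all intermediates stay below 2^48 so the arithmetic
#' is exact.
#'
#' @param ... integer or character tokens; the first is conventionally the
#'   master seed.
#' @return a single integer in `[0, 2147483562]`.
#' @export
#' @examples
#' mix_seed(42, 5, "cases", 17)
mix_seed <- function(...) {
  tokens <- list(...)
  h <- 0
  for (x in tokens) {
    if (is.character(x)) {
      x <- sum(utf8ToInt(x) * seq_along(utf8ToInt(x)))
    }
    for (xi in as.numeric(x)) {
      if (!is.finite(xi)) stop("mix_seed tokens must be finite")
      xi <- abs(xi)
      # fold non-integers (e.g. RR = 1.5) to an integer grid first
      xi <- round(xi * 1000) %% 2147483563
      h <- (h * 69069 + xi + 1) %% 2147483563
    }
  }
  as.integer(h)
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
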