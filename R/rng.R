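# Seed plumbing. All user-facing stochastic functions take an explicit seed
# and restore the caller's RNG state on exit, so package calls never perturb
# the global random stream. Named substreams are derived deterministically
# from (seed, label) so pipeline stages draw from independent streams.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a named random substream seed
#'
#' Deterministically maps a master seed and a stream label (plus an optional
#' index, e.g. a subject number) to a seed in \code{[0, 2^31 - 2]}, so that
#' pipeline stages (schedule, agents, feedback, optimizer restarts,
#' Monte-Carlo draws, bootstrap) consume independent, reproducible streams.
#'
#' @param seed Master integer seed.
#' @param label Stream label (any string).
#' @param index Optional integer sub-index within the stream.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 2147483563
  as.integer((seed + h + 7919 * index) %% 2147483647)
}
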