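# Named RNG substreams: wiring, delays, episodes, tie-breaks and evolution
# noise each get an independent seed derived from one master seed, so
# changing one stream never perturbs the others.

#' Derive a named substream seed from a master seed
#'
#' @param master Integer master seed.
#' @param name Stream name (e.g. `"wiring"`, `"testing"`, `"evol-noise"`).
#' @param index Optional integer index (iteration, episode, ...).
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(master, name, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 131 + ch) %% 2147483647
  s <- (abs(as.numeric(master)) %% 2147483647) * 48271 %% 2147483647
  s <- (s + h * 69621 + as.numeric(index) * 16807) %% 2147483647
  as.integer(s %% 2147483645 + 1)
}

# Evaluate expr with a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
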