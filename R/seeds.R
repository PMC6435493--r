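# Deterministic seed derivation and scoped RNG use.
#
# One user-facing base seed; every randomized stage derives its own seed by
# hashing the base seed together with a stage/replicate tag, so adding a
# stage never reshuffles the randomness of earlier ones.

#' Derive a reproducible child seed
#'
#' Hashes a base seed together with any number of tags (stage names,
#' replicate indices, grid coordinates) into an integer seed below 2^31.
#'
#' @param base_seed integer base seed.
#' @param ... tags coerced to character and folded into the hash.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, ...) {
  tag <- paste(c(as.character(base_seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- 0
  m <- 2147483629 # largest prime < 2^31 leaves headroom for +1
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% m
  as.integer(h + 1)
}

# evaluate expr with the RNG seeded, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
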