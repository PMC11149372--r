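# Deterministic seed streams: one master seed expands into independent
# per-stage seeds so that e.g. adding a scheme to a session never perturbs the
# random stream of another stage.

#' Derive a child seed from a master seed
#'
#' Hashes `(seed, stage, index)` into a new seed in `[0, 2^31 - 1)` using a
#' splitmix-style integer mix. Used internally so every stage of a simulation
#' or experiment (frequencies, effects, genotypes, noise, splits, per-run model
#' initialization) draws from its own reproducible stream.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label (hashed).
#' @param index Integer index within the stage (e.g. run number).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "effects")
#' derive_seed(1, "effects", 2)
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed %% 2147483647)
  # fold the stage label and index in, character by character
  codes <- c(utf8ToInt(stage), as.integer(index %% 65536), 17L)
  for (k in codes) {
    h <- (h * 69069 + k * 2654435761) %% 2147483647
    h <- (h * 1103515245 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# run `expr` under a local RNG state seeded with `seed`; restores the caller's
# RNG so package internals never disturb the user's random stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
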