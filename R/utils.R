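`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a fixed RNG seed without disturbing the caller's stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stable sub-seed (< 2^31) from a base seed and a stage label, so
# one global seed fans out to independent per-module streams.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}
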