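# Internal helpers shared across modules.

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

#' Derive a stage seed from a global seed
#'
#' Stage seeds decouple the randomness of pipeline stages: changing one
#' stage's draws never perturbs another's. The derivation is a 32-bit
#' FNV-1a hash of the global seed concatenated with the stage name,
#' folded into the valid range for [set.seed()].
#'
#' @param seed Integer global seed.
#' @param stage Character stage tag, e.g. `"split"`, `"train"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- fnv1a32(paste0(format(seed, scientific = FALSE), "/", stage))
  as.integer(h %% (2^31 - 1))
}

# 32-bit FNV-1a hash of a string, returned as a double in [0, 2^32).
# The multiply is split into 16-bit halves so it stays exact in doubles.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * p + ((h_hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

# Short hex digest of an R object (via its JSON form); used to stamp
# pipeline artifacts with the configuration that produced them.
config_hash <- function(x) {
  strip <- function(v) {
    v <- unclass(v)
    if (is.list(v)) lapply(v, strip) else v
  }
  s <- jsonlite::toJSON(strip(x), auto_unbox = TRUE, digits = NA,
                        null = "null")
  h <- fnv1a32(as.character(s)) # double in [0, 2^32): split for sprintf
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
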