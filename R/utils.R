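# Internal helpers: seeded evaluation and deterministic sub-stream seeds.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Deterministic sub-stream seed in [1, 2^31 - 2]. `stage` is a short label so
# different pipeline stages sharing one master seed draw independent streams.
derive_seed <- function(master, stage = "", index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- sum(utf8ToInt(as.character(stage)) * seq_len(nchar(as.character(stage))))
  if (length(h) == 0L) h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(master) %% m)
  s <- (s * 48271 + h * 69621 + index * 16807) %% m
  as.integer(s %% (m - 1) + 1)
}

stop_ <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
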