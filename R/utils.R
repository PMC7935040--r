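#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: polynomial hash of the master seed and any
# number of labels (integers or strings), kept inside R's 32-bit integer
# range. Used so that replicate r / subject s randomness is reproducible and
# independent of loop order or parallel scheduling.
seed_stream <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    codes <- if (is.character(p)) utf8ToInt(p) else as.numeric(p)
    for (v in codes) h <- (h * 1000003 + (v %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctrl <- function(...) stop(..., call. = FALSE)
warn_ctrl <- function(...) warning(..., call. = FALSE)
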