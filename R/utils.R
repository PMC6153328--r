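# Internal helpers shared across modules.

# Wrap angles (degrees) to (-180, 180], counterclockwise positive.
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ..., class = "vmradapt_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
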