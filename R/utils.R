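# internal helpers shared across modules

# Deterministic sub-stream seeds derived from one user seed. Kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647
}

# Round half away from zero (display convention for reported tables;
# base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

run_seeded <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
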