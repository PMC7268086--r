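# Internal helpers: seeded evaluation and seed derivation.

# Evaluate expr with a temporary RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}

# Deterministic 32-bit stream split: one master seed, many independent
# sub-seeds indexed by (index, salt). Plain LCG-style mixing, kept < 2^31.
derive_seed <- function(master, index, salt = 0L) {
  m <- 2147483647
  x <- (as.numeric(master) %% m + 1) * 48271 %% m
  x <- (x + as.numeric(index) * 104729 + as.numeric(salt) * 7919) %% m
  x <- (x * 69621) %% m
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_megdmn <- function(fmt, ..., class) {
  stop(structure(class = c(class, "megdmn_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
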