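# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All generators funnel through this so that
# identical seeds give bit-identical output regardless of call order.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Wrap values into [0, L).
wrap_box <- function(x, L) x - floor(x / L) * L

# Wrap values into [-L/2, L/2).
wrap_centered <- function(x, L) wrap_box(x + L / 2, L) - L / 2

# Minimal-image convention for displacements.
min_image <- function(d, L) d - round(d / L) * L

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
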