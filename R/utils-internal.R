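# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller-visible RNG state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministically derive a child seed from a base seed and integer tags
# (epoch index, graph index, ...). Kept below 2^31 so it is a valid R seed;
# the multiplier is the classic Lehmer constant and all arithmetic stays
# exact in double precision.
derive_seed <- function(seed, ...) {
  x <- as.double(as.integer(seed) %% 2147483629L)
  for (k in c(...)) {
    x <- (x * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(x)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

assert_square_matrix <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square numeric matrix", name), call. = FALSE)
  }
  invisible(m)
}

# Symmetry up to numerical noise; returns the exactly symmetrized matrix.
symmetrize_checked <- function(m, name = deparse(substitute(m)), tol = 1e-8) {
  assert_square_matrix(m, name)
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("`%s` must be symmetric (max asymmetry exceeds %g)", name, tol),
         call. = FALSE)
  }
  (m + t(m)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
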