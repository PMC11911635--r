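# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All randomness in the package flows through this so
# no function touches global random state unless the user asked it to.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a reproducible child seed so that sub-simulations (one per animal,
# one per restart, ...) stay independent but deterministic.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 1009 + 7919 * as.double(index)) %% 2147483647
}

stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "phenocage_input_error")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_input("`%s` must be a probability in [0, 1].", name)
  }
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(if (strict) x > 0 else x >= 0)
  if (!ok) stop_input("`%s` must be %s.", name,
                      if (strict) "positive and finite" else "non-negative and finite")
  invisible(x)
}

# Runs of TRUE in a logical vector -> integer matrix of (start, end) indices.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Interval overlap in seconds between event [s, e) and window [w0, w1).
overlap_len <- function(s, e, w0, w1) {
  pmax(0, pmin(e, w1) - pmax(s, w0))
}
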