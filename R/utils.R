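# Internal numeric and validation helpers.

#' Numerically stable logistic function
#' @param x numeric vector or matrix
#' @return values in (0, 1), same shape as `x`
#' @keywords internal
sigmoid <- function(x) stats::plogis(x)

# log(1 + exp(x)) without overflow
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs on the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(seed, expr)
}

# Derive a reproducible child seed (< 2^31) from a base seed and an index.
child_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + 7919L * as.integer(i) %% 1000003L
}

stop_dims <- function(what, expected, got) {
  stop(sprintf("%s: expected %s, got %s", what, expected, got), call. = FALSE)
}

assert_binary <- function(x, what = "values") {
  bad <- which(!(x == 0 | x == 1))
  if (length(bad) > 0) {
    idx <- arrayInd(bad[seq_len(min(5L, length(bad)))], dim(x))
    stop(sprintf(
      "%s must be 0/1; offending entries at (row, col): %s",
      what, paste(apply(idx, 1L, paste, collapse = ","), collapse = "; ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s must be finite", what), call. = FALSE)
  invisible(TRUE)
}

# All 2^n binary column vectors as an n x 2^n matrix (enumeration oracle support).
binary_states <- function(n) {
  if (n == 0L) return(matrix(numeric(0), nrow = 0L, ncol = 1L))
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t(unname(states))
}
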