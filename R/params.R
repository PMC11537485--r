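#' RBM parameter container
#'
#' Holds the static restricted Boltzmann machine parameters. Weights are
#' stored hidden-major: `W` is `Nh x Nv`, so that the interaction energy is
#' `h' W v`. Both layers are Bernoulli (0/1) units.
#'
#' @param W numeric matrix, hidden x visible (`Nh x Nv`)
#' @param bv visible bias, length `Nv`
#' @param bh hidden bias, length `Nh`
#' @return an object of class `rbm_params`
#' @export
rbm_params <- function(W, bv, bh) {
  W <- as.matrix(W)
  bv <- as.numeric(bv)
  bh <- as.numeric(bh)
  if (length(bv) != ncol(W)) stop_dims("bv", ncol(W), length(bv))
  if (length(bh) != nrow(W)) stop_dims("bh", nrow(W), length(bh))
  assert_finite(W, "W"); assert_finite(bv, "bv"); assert_finite(bh, "bh")
  structure(list(W = W, bv = bv, bh = bh), class = "rbm_params")
}

#' RTRBM parameter container
#'
#' Extends [rbm_params()] with the temporal hidden-to-hidden weight matrix
#' `U` (`Nh x Nh`, asymmetric allowed: temporal connections are directed) and
#' the learnable initial hidden bias `binit` used at the first time-step.
#'
#' @inheritParams rbm_params
#' @param U numeric `Nh x Nh` matrix of temporal weights
#' @param binit initial hidden bias, length `Nh`
#' @return an object of class `rtrbm_params` (also inherits `rbm_params`)
#' @export
rtrbm_params <- function(W, U, bv, bh, binit) {
  base <- rbm_params(W, bv, bh)
  U <- as.matrix(U)
  binit <- as.numeric(binit)
  Nh <- nrow(base$W)
  if (nrow(U) != Nh || ncol(U) != Nh) {
    stop_dims("U", sprintf("%d x %d", Nh, Nh), paste(dim(U), collapse = " x "))
  }
  if (length(binit) != Nh) stop_dims("binit", Nh, length(binit))
  assert_finite(U, "U"); assert_finite(binit, "binit")
  structure(list(W = base$W, U = U, bv = base$bv, bh = base$bh, binit = binit),
            class = c("rtrbm_params", "rbm_params"))
}

#' @export
print.rbm_params <- function(x, ...) {
  kind <- if (inherits(x, "rtrbm_params")) "rtrbm_params" else "rbm_params"
  cat(sprintf("%s: Nh = %d, Nv = %d\n", kind, nrow(x$W), ncol(x$W)))
  invisible(x)
}

n_visible <- function(params) ncol(params$W)
n_hidden <- function(params) nrow(params$W)

#' Conditional RBM of an RTRBM at one time-step
#'
#' The RTRBM at time t, conditioned on the previous mean-field hidden state
#' `r_prev`, is an ordinary RBM whose hidden bias is shifted by `U r_prev`
#' (or replaced by `binit` at the first time-step). The returned object can
#' be fed to any static-RBM operation (energy, conditionals, Gibbs, exact
#' partition).
#'
#' @param params an [rtrbm_params()]
#' @param r_prev previous mean-field hidden state, length `Nh`, entries in
#'   `[0, 1]`; ignored when `t1 = TRUE`
#' @param t1 logical; `TRUE` selects the first-time-step conditional (hidden
#'   bias `binit`)
#' @return an [rbm_params()]
#' @export
conditional_rbm_at_t <- function(params, r_prev = NULL, t1 = FALSE) {
  stopifnot(inherits(params, "rtrbm_params"))
  if (t1) return(rbm_params(params$W, params$bv, params$binit))
  r_prev <- as.numeric(r_prev)
  if (length(r_prev) != n_hidden(params)) {
    stop_dims("r_prev", n_hidden(params), length(r_prev))
  }
  if (any(r_prev < 0 | r_prev > 1)) stop("r_prev entries must lie in [0, 1]", call. = FALSE)
  rbm_params(params$W, params$bv, params$bh + drop(params$U %*% r_prev))
}

# Random small-weight initialization shared by both trainers.
init_params <- function(n_hidden, n_visible, temporal = FALSE, scale = NULL) {
  if (is.null(scale)) scale <- 0.01 / sqrt(n_visible)
  W <- matrix(stats::rnorm(n_hidden * n_visible, sd = scale), n_hidden, n_visible)
  if (!temporal) {
    rbm_params(W, numeric(n_visible), numeric(n_hidden))
  } else {
    rtrbm_params(W, matrix(0, n_hidden, n_hidden),
                 numeric(n_visible), numeric(n_hidden), numeric(n_hidden))
  }
}
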