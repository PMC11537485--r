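# Static RBM probabilistic core: energy, conditionals, Gibbs transitions and
# exact enumeration oracles for small models.

#' RBM energy of a joint configuration
#'
#' `E(v, h) = -(bv.v + bh.h + h' W v)` for Bernoulli visible and hidden
#' units; the joint distribution is `P(v, h) = exp(-E) / Z`.
#'
#' @param v binary visible vector, length `Nv`
#' @param h binary hidden vector, length `Nh`
#' @param params an [rbm_params()]
#' @return scalar energy
#' @export
rbm_energy <- function(v, h, params) {
  v <- as.numeric(v); h <- as.numeric(h)
  if (length(v) != n_visible(params)) stop_dims("v", n_visible(params), length(v))
  if (length(h) != n_hidden(params)) stop_dims("h", n_hidden(params), length(h))
  -(sum(params$bv * v) + sum(params$bh * h) + drop(h %*% params$W %*% v))
}

#' Hidden-unit activation probabilities given visible states
#'
#' `P(h_j = 1 | v) = sigmoid(bh_j + (W v)_j + extra_j)`. The
#' `extra_hidden_bias` hook is how the RTRBM injects `U r[t-1]` into the
#' static machinery.
#'
#' @param v binary visible vector (length `Nv`) or matrix (`Nv x T`)
#' @param params an [rbm_params()]
#' @param extra_hidden_bias optional additional hidden bias: a length-`Nh`
#'   vector, or an `Nh x T` matrix when `v` is a matrix
#' @return probabilities, `Nh`-vector or `Nh x T` matrix matching `v`
#' @export
p_h_given_v <- function(v, params, extra_hidden_bias = NULL) {
  vec_in <- is.null(dim(v))
  V <- if (vec_in) matrix(as.numeric(v), ncol = 1L) else as.matrix(v)
  if (nrow(V) != n_visible(params)) stop_dims("v", n_visible(params), nrow(V))
  act <- params$W %*% V + params$bh
  if (!is.null(extra_hidden_bias)) {
    if (is.null(dim(extra_hidden_bias))) {
      if (length(extra_hidden_bias) != n_hidden(params)) {
        stop_dims("extra_hidden_bias", n_hidden(params), length(extra_hidden_bias))
      }
      act <- act + extra_hidden_bias
    } else {
      if (!all(dim(extra_hidden_bias) == dim(act))) {
        stop_dims("extra_hidden_bias", paste(dim(act), collapse = " x "),
                  paste(dim(extra_hidden_bias), collapse = " x "))
      }
      act <- act + extra_hidden_bias
    }
  }
  p <- sigmoid(act)
  if (vec_in) drop(p) else p
}

#' Visible-unit activation probabilities given hidden states
#'
#' `P(v_i = 1 | h) = sigmoid(bv_i + (W' h)_i)`.
#'
#' @param h binary hidden vector (length `Nh`) or matrix (`Nh x T`)
#' @param params an [rbm_params()]
#' @return probabilities matching the shape of `h` transposed onto visibles
#' @export
p_v_given_h <- function(h, params) {
  vec_in <- is.null(dim(h))
  H <- if (vec_in) matrix(as.numeric(h), ncol = 1L) else as.matrix(h)
  if (nrow(H) != n_hidden(params)) stop_dims("h", n_hidden(params), nrow(H))
  p <- sigmoid(crossprod(params$W, H) + params$bv)
  if (vec_in) drop(p) else p
}

# One blockwise Gibbs sweep on a matrix of visible states (columns are
# independent chains). `extra` shifts the hidden bias (RTRBM conditionals).
# Returns samples and the conditional probabilities of the sweep.
gibbs_sweep <- function(V, params, extra = NULL) {
  ph <- p_h_given_v(V, params, extra_hidden_bias = extra)
  H <- matrix(stats::rbinom(length(ph), 1L, ph), nrow(ph), ncol(ph))
  pv <- p_v_given_h(H, params)
  Vn <- matrix(stats::rbinom(length(pv), 1L, pv), nrow(pv), ncol(pv))
  list(v = Vn, h = H, p_v = pv, p_h = ph)
}

#' K-step Gibbs chain from a visible configuration
#'
#' Alternately samples `h ~ P(h|v)` and `v ~ P(v|h)` for `K` sweeps and
#' returns the final samples together with the final-sweep conditional
#' probabilities.
#'
#' @param v0 binary visible vector (or `Nv x n` matrix of independent chains)
#' @param params an [rbm_params()]
#' @param K number of Gibbs sweeps, `>= 1`
#' @param seed optional integer seed for a local RNG stream
#' @return list with `v`, `h` (final samples) and `p_v`, `p_h`
#'   (final conditional probabilities)
#' @export
gibbs_chain <- function(v0, params, K = 1L, seed = NULL) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  vec_in <- is.null(dim(v0))
  V <- if (vec_in) matrix(as.numeric(v0), ncol = 1L) else as.matrix(v0)
  if (nrow(V) != n_visible(params)) stop_dims("v0", n_visible(params), nrow(V))
  out <- with_seed(seed, {
    res <- NULL
    for (k in seq_len(K)) {
      res <- gibbs_sweep(V, params)
      V <- res$v
    }
    res
  })
  if (vec_in) lapply(out, drop) else out
}

#' Exact partition function of a small RBM
#'
#' Enumerates the visible states and marginalizes the Bernoulli hidden units
#' analytically: `Z = sum_v exp(bv.v) prod_j (1 + exp(bh_j + (W v)_j))`,
#' accumulated in log space. Intended as a test oracle; refuses models with
#' `Nv + Nh > 24`.
#'
#' @param params an [rbm_params()] (use [conditional_rbm_at_t()] to obtain
#'   the partition of an RTRBM step conditioned on `r[t-1]`)
#' @return list with `Z` and `logZ`
#' @export
exact_partition <- function(params) {
  Nv <- n_visible(params); Nh <- n_hidden(params)
  if (Nv + Nh > 24L) stop("model too large for enumeration (Nv + Nh > 24)", call. = FALSE)
  V <- binary_states(Nv)                         # Nv x 2^Nv
  # log unnormalized marginal of each visible state
  lw <- drop(params$bv %*% V) + colSums(softplus(params$W %*% V + params$bh))
  logZ <- logsumexp(lw)
  list(Z = exp(logZ), logZ = logZ)
}

# Exact joint moments of a small RBM by enumeration of visible states:
# E[v], E[h], E[h v'] under P(v, h). Oracle for gradient tests.
exact_rbm_moments <- function(params) {
  Nv <- n_visible(params); Nh <- n_hidden(params)
  if (Nv + Nh > 24L) stop("model too large for enumeration", call. = FALSE)
  V <- binary_states(Nv)
  lw <- drop(params$bv %*% V) + colSums(softplus(params$W %*% V + params$bh))
  p <- exp(lw - logsumexp(lw))                   # P(v) over all states
  R <- sigmoid(params$W %*% V + params$bh)       # E[h | v]
  list(
    Ev = drop(V %*% p),
    Eh = drop(R %*% p),
    Ehv = R %*% (t(V) * p),
    p_v = p,
    states = V
  )
}

# Exact marginal P(v) over enumerated visible states (chi-squared oracle).
exact_visible_marginal <- function(params) {
  m <- exact_rbm_moments(params)
  list(states = m$states, p = m$p_v)
}
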