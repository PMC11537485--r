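# RTRBM forward recursion, sequence likelihood, and sequential generation.

#' Mean-field hidden trace of an RTRBM on observed data
#'
#' Runs the deterministic recursion
#' `r[1] = sigmoid(W v[1] + binit)`,
#' `r[t] = sigmoid(W v[t] + bh + U r[t-1])` for `t > 1`.
#' The real-valued expectations `r[t]`, never binary hidden samples, are
#' propagated forward — the mean-field approximation the RTRBM is built on.
#'
#' @param v_seq a [spike_raster()] or binary `Nv x T` matrix
#' @param params an [rtrbm_params()]
#' @return `Nh x T` matrix of mean-field hidden states in `[0, 1]`
#' @export
hidden_trace <- function(v_seq, params) {
  stopifnot(inherits(params, "rtrbm_params"))
  V <- if (inherits(v_seq, "spike_raster")) v_seq$values else as.matrix(v_seq)
  if (nrow(V) != n_visible(params)) stop_dims("v_seq", n_visible(params), nrow(V))
  T <- ncol(V)
  WV <- params$W %*% V
  r <- matrix(0, n_hidden(params), T)
  r[, 1L] <- sigmoid(WV[, 1L] + params$binit)
  if (T > 1L) {
    for (t in 2:T) {
      r[, t] <- sigmoid(WV[, t] + params$bh + params$U %*% r[, t - 1L])
    }
  }
  r
}

#' Exact log-likelihood of a visible sequence under a small RTRBM
#'
#' Factorizes the sequence probability as the product of per-step conditional
#' RBM likelihoods, `prod_t P(v[t] | r[t-1])`, each normalized by the exact
#' partition function of [conditional_rbm_at_t()]. Enumeration-based; only
#' for small models (test oracle).
#'
#' @inheritParams hidden_trace
#' @return scalar log-likelihood of the whole sequence
#' @export
exact_sequence_loglik <- function(v_seq, params) {
  V <- if (inherits(v_seq, "spike_raster")) v_seq$values else as.matrix(v_seq)
  r <- hidden_trace(V, params)
  T <- ncol(V)
  ll <- 0
  for (t in seq_len(T)) {
    cond <- if (t == 1L) conditional_rbm_at_t(params, t1 = TRUE)
            else conditional_rbm_at_t(params, r_prev = r[, t - 1L])
    lup <- sum(cond$bv * V[, t]) +
      sum(softplus(cond$bh + drop(cond$W %*% V[, t])))
    ll <- ll + lup - exact_partition(cond)$logZ
  }
  ll
}

#' Generate sequences from an RTRBM
#'
#' Sequential generative inference: at each time-step the visible state is
#' drawn by a K-step Gibbs chain under the conditional RBM whose hidden bias
#' is shifted by `U r[t-1]`, after which the mean-field state `r[t]` is
#' updated from the sampled visibles. `n_chains` rollouts run in parallel;
#' the per-step mean visible probability across chains is the model's
#' prediction of the state at that step.
#'
#' @param params an [rtrbm_params()]
#' @param T number of time-steps to generate
#' @param v_init optional binary visible vector seeding `r[1]` (and taken as
#'   the state at t = 1); when absent, `v[1]` is sampled by `burn_in` Gibbs
#'   sweeps under the first-step conditional (hidden bias `binit`)
#' @param K Gibbs sweeps per generated time-step
#' @param n_chains number of independent rollouts
#' @param burn_in Gibbs sweeps used to draw `v[1]` when `v_init` is absent
#' @param seed optional seed
#' @return list with `v` (`Nv x T x n_chains` binary array), `r`
#'   (`Nh x T x n_chains` mean-field traces), and `p_v` (`Nv x T` across-chain
#'   mean visible probabilities)
#' @export
sample_sequence <- function(params, T, v_init = NULL, K = 15L, n_chains = 100L,
                            burn_in = 100L, seed = NULL) {
  stopifnot(inherits(params, "rtrbm_params"))
  T <- as.integer(T); K <- as.integer(K); n_chains <- as.integer(n_chains)
  if (T < 1L || K < 1L || n_chains < 1L) stop("T, K, n_chains must be >= 1", call. = FALSE)
  Nv <- n_visible(params); Nh <- n_hidden(params)
  with_seed(seed, {
    v_arr <- array(0, c(Nv, T, n_chains))
    r_arr <- array(0, c(Nh, T, n_chains))
    p_v <- matrix(0, Nv, T)
    cond1 <- conditional_rbm_at_t(params, t1 = TRUE)
    if (is.null(v_init)) {
      V <- matrix(stats::rbinom(Nv * n_chains, 1L, 0.5), Nv, n_chains)
      out <- gibbs_chain(V, cond1, K = max(burn_in, K))
      V <- if (is.null(dim(out$v))) matrix(out$v, ncol = 1L) else out$v
      p_v[, 1L] <- rowMeans(if (is.null(dim(out$p_v))) matrix(out$p_v) else out$p_v)
    } else {
      V <- matrix(as.numeric(v_init), Nv, n_chains)
      p_v[, 1L] <- as.numeric(v_init)
    }
    R <- sigmoid(params$W %*% V + params$binit)
    v_arr[, 1L, ] <- V
    r_arr[, 1L, ] <- R
    if (T > 1L) {
      for (t in 2:T) {
        extra <- params$U %*% R    # per-chain bias shift; p_h_given_v adds bh
        pvt <- NULL
        for (k in seq_len(K)) {
          sw <- gibbs_sweep(V, params, extra = extra)
          V <- sw$v
          pvt <- sw$p_v
        }
        R <- sigmoid(params$W %*% V + params$bh + extra)
        v_arr[, t, ] <- V
        r_arr[, t, ] <- R
        p_v[, t] <- rowMeans(pvt)
      }
    }
    list(v = v_arr, r = r_arr, p_v = p_v)
  })
}
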