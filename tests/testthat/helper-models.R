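# Shared fixtures: tiny random models and enumeration-based oracles.

random_rbm <- function(Nv, Nh, scale = 0.8, seed = NULL) {
  rtrbm:::with_seed(seed, rbm_params(
    W = matrix(rnorm(Nh * Nv, sd = scale), Nh, Nv),
    bv = rnorm(Nv, sd = 0.5),
    bh = rnorm(Nh, sd = 0.5)
  ))
}

random_rtrbm <- function(Nv, Nh, scale = 0.8, seed = NULL) {
  rtrbm:::with_seed(seed, rtrbm_params(
    W = matrix(rnorm(Nh * Nv, sd = scale), Nh, Nv),
    U = matrix(rnorm(Nh * Nh, sd = scale), Nh, Nh),
    bv = rnorm(Nv, sd = 0.5),
    bh = rnorm(Nh, sd = 0.5),
    binit = rnorm(Nh, sd = 0.5)
  ))
}

random_raster <- function(Nv, T, p = 0.5, seed = NULL) {
  rtrbm:::with_seed(seed, spike_raster(matrix(rbinom(Nv * T, 1, p), Nv, T)))
}

# Exact joint probabilities P(v, h) over all 2^(Nv+Nh) states via the energy.
enumerate_joint <- function(params) {
  Nv <- ncol(params$W); Nh <- nrow(params$W)
  Vs <- rtrbm:::binary_states(Nv)
  Hs <- rtrbm:::binary_states(Nh)
  grid <- expand.grid(v = seq_len(ncol(Vs)), h = seq_len(ncol(Hs)))
  e <- mapply(function(iv, ih) rbm_energy(Vs[, iv], Hs[, ih], params),
              grid$v, grid$h)
  w <- exp(-e)
  list(v_idx = grid$v, h_idx = grid$h, p = w / sum(w), Vs = Vs, Hs = Hs,
       Z = sum(w))
}

# Directly computed exact log-likelihood of a data set under a small RBM.
exact_rbm_loglik <- function(params, V) {
  lz <- exact_partition(params)$logZ
  lup <- colSums(params$bv * V) +
    colSums(rtrbm:::softplus(params$W %*% V + params$bh))
  mean(lup) - lz
}
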