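# RTRBM training: contrastive divergence per time-step plus
# backpropagation through time over the mean-field recursion.

#' CD + BPTT gradients of the RTRBM sequence log-likelihood
#'
#' Computes gradients of `sum_t log P(v[t] | r[t-1])` for one sequence. The
#' static part treats each step as an RBM with hidden bias `bh + U r[t-1]`
#' (teacher forcing: `r` is computed from data). The temporal part
#' backpropagates through the deterministic recursion: with
#' `dh[t] = r[t] - r_model[t]`, the adjoint satisfies
#' `D[t] = U' (D[t+1] * r[t+1] * (1 - r[t+1]) + dh[t+1])`, `D[T] = 0`,
#' and `e[t] = D[t] * r[t] * (1 - r[t])` chains into the parameter blocks.
#'
#' The negative-phase statistics `r_model`, `v_model` come from a K-step
#' Gibbs chain per step (`method = "cd"`), from damped mean-field
#' iterations started at a neutral visible state (`method = "mean_field"`,
#' deterministic), or from exact enumeration of each conditional RBM
#' (`method = "exact"`, small models only) in which case the result is the
#' exact analytic gradient of [exact_sequence_loglik()].
#'
#' @param v_seq a [spike_raster()] or binary `Nv x T` matrix
#' @param params an [rtrbm_params()]
#' @param K Gibbs sweeps for the CD negative phase
#' @param method `"cd"` (stochastic), `"mean_field"` (deterministic), or
#'   `"exact"` (enumeration)
#' @param mf_iters mean-field iterations for `method = "mean_field"`
#' @param seed optional seed
#' @param mean_over_time divide gradients by `T` (default TRUE; tests of the
#'   exact gradient use FALSE to compare against the summed log-likelihood)
#' @return list with `dW`, `dU`, `dbv`, `dbh`, `dbinit`
#' @export
bptt_gradients <- function(v_seq, params,
                           K = 1L, method = c("cd", "mean_field", "exact"),
                           mf_iters = 10L, seed = NULL,
                           mean_over_time = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(params, "rtrbm_params"))
  V <- if (inherits(v_seq, "spike_raster")) v_seq$values else as.matrix(v_seq)
  if (ncol(V) < 1L) stop("empty sequence", call. = FALSE)
  if (nrow(V) != n_visible(params)) stop_dims("v_seq", n_visible(params), nrow(V))
  T <- ncol(V)
  Nh <- n_hidden(params)

  with_seed(seed, {
    r <- hidden_trace(V, params)
    # per-step hidden bias of the conditional RBMs (teacher forced)
    B <- matrix(params$bh, Nh, T)
    B[, 1L] <- params$binit
    if (T > 1L) B[, 2:T] <- B[, 2:T] + params$U %*% r[, 1:(T - 1L), drop = FALSE]

    if (method == "cd") {
      Vn <- V
      for (k in seq_len(K)) {
        ph <- sigmoid(params$W %*% Vn + B)
        H <- matrix(stats::rbinom(length(ph), 1L, ph), Nh, T)
        pv <- sigmoid(crossprod(params$W, H) + params$bv)
        Vn <- matrix(stats::rbinom(length(pv), 1L, pv), nrow(pv), T)
      }
      r_model <- sigmoid(params$W %*% Vn + B)
      v_model <- Vn
      EhvT <- tcrossprod(r_model, v_model)
    } else if (method == "mean_field") {
      Vn <- matrix(sigmoid(params$bv), nrow(V), T)
      r_model <- sigmoid(params$W %*% Vn + B)
      for (i in seq_len(mf_iters)) {
        Vn <- 0.5 * Vn + 0.5 * sigmoid(crossprod(params$W, r_model) + params$bv)
        r_model <- 0.5 * r_model + 0.5 * sigmoid(params$W %*% Vn + B)
      }
      v_model <- Vn
      EhvT <- tcrossprod(r_model, v_model)
    } else {
      r_model <- matrix(0, Nh, T)
      v_model <- matrix(0, nrow(V), T)
      EhvT <- matrix(0, Nh, nrow(V))
      for (t in seq_len(T)) {
        cond <- rbm_params(params$W, params$bv, B[, t])
        mom <- exact_rbm_moments(cond)
        r_model[, t] <- mom$Eh
        v_model[, t] <- mom$Ev
        EhvT <- EhvT + mom$Ehv
      }
    }

    dh <- r - r_model
    dv <- V - v_model

    dW <- tcrossprod(r, V) - EhvT
    dbv <- rowSums(dv)
    dbinit <- dh[, 1L]
    dbh <- if (T > 1L) rowSums(dh[, 2:T, drop = FALSE]) else numeric(Nh)
    dU <- if (T > 1L) {
      tcrossprod(dh[, 2:T, drop = FALSE], r[, 1:(T - 1L), drop = FALSE])
    } else matrix(0, Nh, Nh)

    # backward pass: adjoint of r[t] w.r.t. all later-step likelihood terms
    if (T > 1L) {
      D <- matrix(0, Nh, T)
      for (t in (T - 1L):1L) {
        D[, t] <- crossprod(params$U,
                            D[, t + 1L] * r[, t + 1L] * (1 - r[, t + 1L]) + dh[, t + 1L])
      }
      E <- D[, 1:(T - 1L), drop = FALSE] *
        r[, 1:(T - 1L), drop = FALSE] * (1 - r[, 1:(T - 1L), drop = FALSE])
      dW <- dW + tcrossprod(E, V[, 1:(T - 1L), drop = FALSE])
      dbinit <- dbinit + E[, 1L]
      if (T > 2L) {
        dbh <- dbh + rowSums(E[, 2:(T - 1L), drop = FALSE])
        dU <- dU + tcrossprod(E[, 2:(T - 1L), drop = FALSE],
                              r[, 1:(T - 2L), drop = FALSE])
      }
    }

    g <- list(dW = dW, dU = dU, dbv = dbv, dbh = dbh, dbinit = dbinit)
    if (mean_over_time) g <- lapply(g, `/`, T) else g
    g
  })
}

#' Train an RTRBM
#'
#' Gradient ascent on the sequence log-likelihood via CD + BPTT over
#' contiguous time batches. With `init_W` the model starts from a donor
#' visible-to-hidden weight matrix (transfer learning, e.g. from a
#' compositional RBM); the `W` block then moves at a learning rate reduced by
#' `config$w_learning_rate_factor` (default `1e-2` in transfer mode) under
#' the L1 penalty `config$l1_weight`, while `U` and the biases train at the
#' full rate. Deterministic given `config$seed`.
#'
#' @param data a [spike_raster()] (or binary matrix)
#' @param config a [train_config()]
#' @param init_W optional `Nh x Nv` donor weight matrix; switches on
#'   transfer mode
#' @param init optional [rtrbm_params()] to resume from
#' @return list with `params` (an [rtrbm_params()]) and `log` (per-epoch
#'   data.frame: reconstruction MSE, step norm)
#' @export
train_rtrbm <- function(data, config = train_config(), init_W = NULL, init = NULL) {
  data <- as_raster(data)
  train_energy_model(data, config, init = init, init_W = init_W, temporal = TRUE)
}

#' One-step Gibbs reconstruction error
#'
#' Reconstructs every time column by a K-step Gibbs chain under its
#' conditional RBM (teacher-forced `r[t-1]` for an RTRBM; the static model
#' for an RBM) and returns the mean squared difference to the data over all
#' units and time-steps.
#'
#' @param data a [spike_raster()] or binary matrix
#' @param params an [rbm_params()] or [rtrbm_params()]
#' @param K Gibbs sweeps
#' @param seed optional seed
#' @param probabilities reconstruct with the final visible probabilities
#'   instead of binary samples (default TRUE; lower-variance monitor)
#' @return scalar mean squared reconstruction error
#' @export
reconstruction_mse <- function(data, params, K = 1L, seed = NULL,
                               probabilities = TRUE) {
  V <- if (inherits(data, "spike_raster")) data$values else as.matrix(data)
  T <- ncol(V)
  Nh <- n_hidden(params)
  with_seed(seed, {
    if (inherits(params, "rtrbm_params")) {
      r <- hidden_trace(V, params)
      B <- matrix(params$bh, Nh, T)
      B[, 1L] <- params$binit
      if (T > 1L) B[, 2:T] <- B[, 2:T] + params$U %*% r[, 1:(T - 1L), drop = FALSE]
    } else {
      B <- matrix(params$bh, Nh, T)
    }
    Vn <- V
    pv <- NULL
    for (k in seq_len(K)) {
      ph <- sigmoid(params$W %*% Vn + B)
      H <- matrix(stats::rbinom(length(ph), 1L, ph), Nh, T)
      pv <- sigmoid(crossprod(params$W, H) + params$bv)
      Vn <- matrix(stats::rbinom(length(pv), 1L, pv), nrow(pv), T)
    }
    Vhat <- if (probabilities) pv else Vn
    mean((V - Vhat)^2)
  })
}
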