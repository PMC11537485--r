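# Contrastive-divergence training of the static RBM.

#' Training configuration
#'
#' Shared configuration for RBM and RTRBM training. Batches are contiguous
#' time windows of `batch_length` columns; gradients are accumulated over
#' `batches_per_update` batches before a parameter update. `n_updates`, when
#' given, fixes the total number of parameter updates regardless of data
#' length (batches are then drawn at random), which is how an equal
#' gradient-update budget is enforced across down-sampling rates.
#'
#' @param n_hidden number of hidden units (ignored when an initial model is
#'   supplied)
#' @param epochs sweeps through the data (ignored when `n_updates` is set)
#' @param learning_rate gradient-ascent step size eta
#' @param cd_steps Gibbs sweeps K per contrastive-divergence estimate
#' @param batch_length time-steps per contiguous batch
#' @param batches_per_update batches accumulated per parameter update
#' @param l1_weight L1 sparsity penalty lambda on `W`
#' @param w_learning_rate_factor multiplier on `learning_rate` for the `W`
#'   block. The default `1e-2` keeps the assembly structure (from the warm
#'   start or a donor matrix) nearly frozen while the temporal weights and
#'   biases train at the full rate — the transfer-learning scheme. Set to 1
#'   for fully free training.
#' @param init_method de-novo initialization: `"assembly"` (default)
#'   warm-starts `W` from a Ward clustering of the neuron correlation
#'   matrix into `n_hidden` groups; `"random"` draws small Gaussian weights
#' @param negative_phase `"gibbs"` (default; the K-step contrastive
#'   divergence chain) or `"mean_field"` (damped mean-field iterations from
#'   a neutral visible state — a deterministic negative phase that presses
#'   the model to reproduce each time-step from its temporal bias alone,
#'   which yields better-calibrated free-running predictions at equal
#'   update budgets)
#' @param mf_iters mean-field iterations when `negative_phase = "mean_field"`
#' @param momentum SGD momentum (0 disables; ignored by Adam)
#' @param optimizer `"adam"` (default) or plain `"sgd"`; Adam's moment decay
#'   rates are the conventional 0.9 / 0.999
#' @param n_updates optional total number of parameter updates
#' @param seed integer seed making the run deterministic
#' @param early_stop_tol stop when the epoch reconstruction-MSE improvement
#'   falls below this (0 disables)
#' @return a `train_config` list
#' @export
train_config <- function(n_hidden = 10L, epochs = 50L, learning_rate = 5e-3,
                         cd_steps = 1L, batch_length = 16L,
                         batches_per_update = 20L, l1_weight = 0,
                         w_learning_rate_factor = 1e-2, momentum = 0,
                         optimizer = c("adam", "sgd"),
                         init_method = c("assembly", "random"),
                         negative_phase = c("gibbs", "mean_field"),
                         mf_iters = 10L,
                         n_updates = NULL, seed = 1L, early_stop_tol = 0) {
  optimizer <- match.arg(optimizer)
  init_method <- match.arg(init_method)
  negative_phase <- match.arg(negative_phase)
  stopifnot(epochs >= 1L, learning_rate > 0, cd_steps >= 1L, batch_length >= 1L,
            batches_per_update >= 1L, l1_weight >= 0, w_learning_rate_factor >= 0,
            momentum >= 0, momentum < 1, early_stop_tol >= 0)
  structure(list(
    n_hidden = as.integer(n_hidden), epochs = as.integer(epochs),
    learning_rate = learning_rate, cd_steps = as.integer(cd_steps),
    batch_length = as.integer(batch_length),
    batches_per_update = as.integer(batches_per_update),
    l1_weight = l1_weight, w_learning_rate_factor = w_learning_rate_factor,
    momentum = momentum, optimizer = optimizer, init_method = init_method,
    negative_phase = negative_phase, mf_iters = as.integer(mf_iters),
    n_updates = if (is.null(n_updates)) NULL else as.integer(n_updates),
    seed = as.integer(seed), early_stop_tol = early_stop_tol
  ), class = "train_config")
}

#' Contrastive-divergence gradient on a batch
#'
#' Estimates the log-likelihood gradient `<grad(-E)>_data - <grad(-E)>_model`
#' for a static RBM. The data-side hidden terms use the conditional means
#' `sigmoid(bh + W v)`; the model side is a K-step Gibbs chain started at
#' each data column.
#'
#' @param batch binary `Nv x B` matrix (or [spike_raster()]) of data columns
#' @param params an [rbm_params()]
#' @param K Gibbs sweeps for the negative phase
#' @param seed optional seed
#' @param mean_over_batch divide by the number of columns (default TRUE)
#' @return list with `dW`, `dbv`, `dbh`
#' @export
cd_gradient <- function(batch, params, K = 1L, seed = NULL, mean_over_batch = TRUE) {
  V <- if (inherits(batch, "spike_raster")) batch$values else as.matrix(batch)
  if (ncol(V) < 1L) stop("empty batch", call. = FALSE)
  if (nrow(V) != n_visible(params)) stop_dims("batch", n_visible(params), nrow(V))
  with_seed(seed, {
    r_data <- p_h_given_v(V, params)
    neg <- gibbs_chain(V, params, K = K)
    Vn <- if (is.null(dim(neg$v))) matrix(neg$v, ncol = 1L) else neg$v
    r_model <- p_h_given_v(Vn, params)
    denom <- if (mean_over_batch) ncol(V) else 1
    list(
      dW = (tcrossprod(r_data, V) - tcrossprod(r_model, Vn)) / denom,
      dbv = (rowSums(V) - rowSums(Vn)) / denom,
      dbh = (rowSums(r_data) - rowSums(r_model)) / denom
    )
  })
}

# Warm start from a Ward clustering of the neuron correlation matrix into
# n_hidden putative assemblies. Per-neuron weights and visible biases are
# moment-matched: with a_j(t) the putative assembly-active indicator,
# bv_i = logit P(v_i = 1 | assembly off) and W_ji = logit P(v_i = 1 | on) -
# bv_i, so the one-hidden-unit-on conditional reproduces each neuron's
# empirical on/off rates. Intended for desk-scale data (the correlation
# matrix is Nv x Nv); large recordings should supply a donor W instead.
assembly_init_W <- function(V, n_hidden) {
  C <- suppressWarnings(stats::cor(t(V)))
  C[!is.finite(C)] <- 0
  cl <- stats::cutree(stats::hclust(stats::dist(C), method = "ward.D2"),
                      k = n_hidden)
  W <- matrix(0, n_hidden, ncol(C))
  bv <- numeric(ncol(C))
  clamp <- function(p, lo = 0.01, hi = 0.95) pmin(pmax(p, lo), hi)
  for (j in seq_len(n_hidden)) {
    members <- which(cl == j)
    frac <- colMeans(V[members, , drop = FALSE])
    on <- frac > 0.25
    if (sum(on) < 5L || sum(!on) < 5L) {            # degenerate cluster
      W[j, members] <- 5
      p <- clamp(rowMeans(V[members, , drop = FALSE]))
      bv[members] <- log(p / (1 - p)) - 1
      next
    }
    p_on <- clamp(rowMeans(V[members, on, drop = FALSE]), lo = 0.05)
    p_off <- clamp(rowMeans(V[members, !on, drop = FALSE]))
    bv[members] <- log(p_off / (1 - p_off))
    W[j, members] <- log(p_on / (1 - p_on)) - bv[members]
  }
  list(W = W, bv = bv, clusters = cl)
}

# Contiguous batch start columns for a raster of T columns.
batch_starts <- function(T, batch_length) {
  if (T < batch_length) stop("data shorter than one batch", call. = FALSE)
  seq(1L, T - batch_length + 1L, by = batch_length)
}

#' Train a static RBM by contrastive divergence
#'
#' Stochastic gradient ascent on the data log-likelihood using CD-K over
#' contiguous time batches. Deterministic given `config$seed`.
#'
#' @param data a [spike_raster()] (or binary matrix)
#' @param config a [train_config()]
#' @param init optional [rbm_params()] to start from
#' @return list with `params` (the trained [rbm_params()]) and `log`, a
#'   data.frame with per-epoch reconstruction MSE and gradient norm
#' @export
train_rbm <- function(data, config = train_config(), init = NULL) {
  data <- as_raster(data)
  fit <- train_energy_model(data, config, init = init, temporal = FALSE)
  fit
}

# Shared SGD loop for RBM (temporal = FALSE) and RTRBM (temporal = TRUE).
train_energy_model <- function(data, config, init = NULL, init_W = NULL,
                               temporal = FALSE) {
  V <- data$values
  Nv <- nrow(V); T <- ncol(V)
  L <- min(config$batch_length, T)
  if (temporal && L < 2L) stop("RTRBM batches need at least 2 time-steps", call. = FALSE)
  flagged <- which(rowMeans(V) %in% c(0, 1))

  with_seed(config$seed, {
    params <- init
    if (is.null(params)) {
      Nh <- if (!is.null(init_W)) nrow(init_W) else config$n_hidden
      params <- init_params(Nh, Nv, temporal = temporal, scale = 0.1)
      # visible bias near the data log-odds; negative hidden bias favours a
      # sparse hidden code, which helps the units specialize to assemblies
      p <- pmin(pmax(rowMeans(V), 1 / T), 1 - 1 / T)
      params$bv <- log(p / (1 - p)) - 1
      params$bh <- rep(-3, Nh)
      if (temporal) params$binit <- rep(-3, Nh)
      if (!is.null(init_W)) {
        if (ncol(init_W) != Nv) stop_dims("init_W", Nv, ncol(init_W))
        params$W <- as.matrix(init_W)
      } else if (identical(config$init_method, "assembly") && Nv <= 2000L &&
                 Nv >= 2L * Nh) {
        ws <- assembly_init_W(V, Nh)
        params$W <- ws$W
        params$bv <- ws$bv
      }
    }
    starts <- batch_starts(T, L)
    n_per_epoch <- max(1L, length(starts) %/% config$batches_per_update)
    total_updates <- if (!is.null(config$n_updates)) config$n_updates
                     else config$epochs * n_per_epoch
    epochs <- ceiling(total_updates / n_per_epoch)

    blocks <- intersect(names(params), c("W", "U", "bv", "bh", "binit"))
    vel <- lapply(params[blocks], function(x) x * 0)   # SGD momentum / Adam m
    msq <- lapply(params[blocks], function(x) x * 0)   # Adam second moment
    adam <- is.null(config$optimizer) || config$optimizer == "adam"
    log_rows <- vector("list", epochs)
    updates_done <- 0L
    last_mse <- Inf

    for (ep in seq_len(epochs)) {
      ord <- if (is.null(config$n_updates)) starts[sample.int(length(starts))] else
        starts[sample.int(length(starts), n_per_epoch * config$batches_per_update,
                          replace = TRUE)]
      gnorm <- 0
      i <- 1L
      while (i <= length(ord) && updates_done < total_updates) {
        take <- ord[i:min(length(ord), i + config$batches_per_update - 1L)]
        i <- i + config$batches_per_update
        mf <- if (identical(config$negative_phase, "mean_field"))
          config$mf_iters else 0L
        grad <- NULL
        for (s in take) {
          batch <- V[, s:(s + L - 1L), drop = FALSE]
          g <- if (temporal) {
            .rtrbm_batch_gradient_cpp(batch, params$W, params$U, params$bv,
                                      params$bh, params$binit,
                                      config$cd_steps, mf)
          } else {
            .rbm_batch_gradient_cpp(batch, params$W, params$bv, params$bh,
                                    config$cd_steps, mf)
          }
          grad <- if (is.null(grad)) g else Map(`+`, grad, g)
        }
        grad <- lapply(grad, `/`, length(take))
        grad$dW <- grad$dW - config$l1_weight * sign(params$W)
        names(grad) <- sub("^d", "", names(grad))
        eta <- stats::setNames(rep(config$learning_rate, length(blocks)), blocks)
        eta["W"] <- eta["W"] * config$w_learning_rate_factor
        updates_done <- updates_done + 1L
        gnorm <- gnorm + sqrt(sum(unlist(grad)^2))
        for (nm in blocks) {
          g <- grad[[nm]]
          if (!all(is.finite(g))) {
            stop(sprintf("non-finite gradient in block %s at epoch %d", nm, ep),
                 call. = FALSE)
          }
          if (adam) {
            vel[[nm]] <- 0.9 * vel[[nm]] + 0.1 * g
            msq[[nm]] <- 0.999 * msq[[nm]] + 0.001 * g^2
            mhat <- vel[[nm]] / (1 - 0.9^updates_done)
            vhat <- msq[[nm]] / (1 - 0.999^updates_done)
            params[[nm]] <- params[[nm]] + eta[[nm]] * mhat / (sqrt(vhat) + 1e-8)
          } else {
            vel[[nm]] <- config$momentum * vel[[nm]] + eta[[nm]] * g
            params[[nm]] <- params[[nm]] + vel[[nm]]
          }
        }
      }
      # monitor on a bounded window to keep the epoch cost independent of T
      mon <- if (T > 512L) spike_raster(V[, 1:512, drop = FALSE]) else data
      mse <- reconstruction_mse(mon, params, K = 1L)
      log_rows[[ep]] <- data.frame(epoch = ep, recon_mse = mse,
                                   step_norm = gnorm, updates = updates_done)
      if (config$early_stop_tol > 0 && is.finite(last_mse) &&
          abs(last_mse - mse) < config$early_stop_tol) break
      last_mse <- mse
      if (updates_done >= total_updates) break
    }
    log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1L))])
    if (length(flagged)) {
      attr(log, "flagged_units") <- flagged
    }
    list(params = params, log = log)
  })
}
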