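# Moment statistics, model-vs-data comparison, prediction error with
# normalized bounds, significance testing, and the timescale scan.

#' Concurrent and time-shifted moments of a raster
#'
#' Time-averaged first- and second-order statistics: `<v_i>`, `<v_i v_j>`
#' (symmetric), and the lag-1 shifted moments `<v_i[t] v_j[t+1]>` (generally
#' asymmetric: directed temporal co-activation). When a model is supplied,
#' the same statistics are computed for the hidden layer from the mean-field
#' trace `r` (the expected hidden state conditioned on the visibles).
#'
#' @param raster a [spike_raster()], binary matrix, or probability matrix
#' @param params optional [rbm_params()] / [rtrbm_params()] supplying hidden
#'   traces
#' @param provenance label stored in the report (`"data"` or `"model"`)
#' @return a `moment_report` list: `mean_v`, `pair_vv`, `shifted_vv`, and
#'   (with a model) `mean_h`, `pair_hh`, `shifted_hh`; plus `n_samples`
#' @export
compute_moments <- function(raster, params = NULL, provenance = "data") {
  V <- if (inherits(raster, "spike_raster")) raster$values else as.matrix(raster)
  T <- ncol(V)
  if (T < 2L) stop("need at least 2 time-steps for shifted moments", call. = FALSE)
  rep_ <- list(
    mean_v = rowMeans(V),
    pair_vv = tcrossprod(V) / T,
    shifted_vv = tcrossprod(V[, 1:(T - 1L), drop = FALSE],
                            V[, 2:T, drop = FALSE]) / (T - 1L),
    mean_h = NULL, pair_hh = NULL, shifted_hh = NULL,
    provenance = provenance, n_samples = T
  )
  if (!is.null(params)) {
    R <- if (inherits(params, "rtrbm_params")) hidden_trace(V, params)
         else p_h_given_v(V, params)
    if (is.null(dim(R))) R <- matrix(R, ncol = T)
    rep_$mean_h <- rowMeans(R)
    rep_$pair_hh <- tcrossprod(R) / T
    rep_$shifted_hh <- tcrossprod(R[, 1:(T - 1L), drop = FALSE],
                                  R[, 2:T, drop = FALSE]) / (T - 1L)
  }
  structure(rep_, class = "moment_report")
}

#' Moments of model-generated samples
#'
#' Estimates the model's own statistics by Gibbs sampling: chains are
#' started at `n_start_points` random time columns of the test data, burned
#' in, and then advanced for `chain_len` recorded time-steps. For a static
#' RBM every recorded step is separated by `gibbs_steps` sweeps; for an
#' RTRBM the chain advances sequentially (one model time-step per recorded
#' step, `gibbs_steps` sweeps each) so shifted moments are meaningful.
#' Moments are pooled over chains.
#'
#' @param params an [rbm_params()] or [rtrbm_params()]
#' @param test a [spike_raster()] providing chain start states
#' @param gibbs_steps Gibbs sweeps between recorded samples (default 15)
#' @param burn_in Gibbs sweeps before the first recorded sample (default 4000)
#' @param n_start_points number of chains (default 100)
#' @param chain_len recorded time-steps per chain (default 20)
#' @param context observed columns preceding each start over which the
#'   mean-field recursion warms up `r` (RTRBM only)
#' @param seed optional seed
#' @return a `moment_report` with `provenance = "model"`
#' @export
sample_model_moments <- function(params, test, gibbs_steps = 15L,
                                 burn_in = 4000L, n_start_points = 100L,
                                 chain_len = 20L, context = 8L, seed = NULL) {
  V <- if (inherits(test, "spike_raster")) test$values else as.matrix(test)
  T <- ncol(V)
  context <- max(0L, as.integer(context))
  if (T < chain_len + context + 1L) {
    stop("test raster too short for chain placement", call. = FALSE)
  }
  Nv <- n_visible(params); Nh <- n_hidden(params)
  temporal <- inherits(params, "rtrbm_params")
  with_seed(seed, {
    avail <- T - chain_len - context
    starts <- context + sample.int(avail, n_start_points,
                                   replace = n_start_points > avail)
    Vc <- V[, starts, drop = FALSE]                     # Nv x n_chains
    n <- ncol(Vc)
    if (temporal) {
      R <- vapply(starts, function(s) {
        hidden_trace(V[, (s - context):s, drop = FALSE], params)[, context + 1L]
      }, numeric(Nh))
      if (is.null(dim(R))) R <- matrix(R, nrow = Nh)
      # burn in the first generated step, then advance sequentially
      v_rec <- array(0, c(Nv, chain_len, n))
      r_rec <- array(0, c(Nh, chain_len, n))
      for (t in seq_len(chain_len)) {
        extra <- params$U %*% R          # p_h_given_v adds bh itself
        sweeps <- if (t == 1L) max(burn_in, gibbs_steps) else gibbs_steps
        for (k in seq_len(sweeps)) {
          sw <- gibbs_sweep(Vc, params, extra = extra)
          Vc <- sw$v
        }
        R <- sigmoid(params$W %*% Vc + params$bh + extra)
        v_rec[, t, ] <- Vc
        r_rec[, t, ] <- R
      }
    } else {
      for (k in seq_len(burn_in)) Vc <- gibbs_sweep(Vc, params)$v
      v_rec <- array(0, c(Nv, chain_len, n))
      r_rec <- array(0, c(Nh, chain_len, n))
      for (t in seq_len(chain_len)) {
        for (k in seq_len(gibbs_steps)) Vc <- gibbs_sweep(Vc, params)$v
        v_rec[, t, ] <- Vc
        r_rec[, t, ] <- p_h_given_v(Vc, params)
      }
    }
    pool_moments(v_rec, r_rec)
  })
}

# Pool per-chain moment statistics from Nv x T x n arrays.
pool_moments <- function(v_rec, r_rec) {
  n <- dim(v_rec)[3L]; Tc <- dim(v_rec)[2L]
  Vflat <- matrix(v_rec, nrow = dim(v_rec)[1L])         # chains concatenated
  Rflat <- matrix(r_rec, nrow = dim(r_rec)[1L])
  acc_vv <- 0; acc_hh <- 0
  for (c in seq_len(n)) {
    vc <- v_rec[, , c, drop = FALSE]; dim(vc) <- dim(v_rec)[1:2]
    rc <- r_rec[, , c, drop = FALSE]; dim(rc) <- dim(r_rec)[1:2]
    acc_vv <- acc_vv + tcrossprod(vc[, 1:(Tc - 1L), drop = FALSE],
                                  vc[, 2:Tc, drop = FALSE]) / (Tc - 1L)
    acc_hh <- acc_hh + tcrossprod(rc[, 1:(Tc - 1L), drop = FALSE],
                                  rc[, 2:Tc, drop = FALSE]) / (Tc - 1L)
  }
  structure(list(
    mean_v = rowMeans(Vflat),
    pair_vv = tcrossprod(Vflat) / ncol(Vflat),
    shifted_vv = acc_vv / n,
    mean_h = rowMeans(Rflat),
    pair_hh = tcrossprod(Rflat) / ncol(Rflat),
    shifted_hh = acc_hh / n,
    provenance = "model", n_samples = ncol(Vflat)
  ), class = "moment_report")
}

# Flatten one field of a moment report for comparison: upper triangle for
# symmetric pair moments, full matrix for shifted moments, vector otherwise.
moment_field <- function(report, field, units = NULL) {
  x <- report[[field]]
  if (is.null(x)) stop(sprintf("field %s absent from report", field), call. = FALSE)
  if (!is.null(units) && !is.null(dim(x))) x <- x[units, units, drop = FALSE]
  if (!is.null(units) && is.null(dim(x))) x <- x[units]
  if (is.null(dim(x))) return(as.numeric(x))
  if (field %in% c("pair_vv", "pair_hh")) x[upper.tri(x)] else as.numeric(x)
}

#' Spearman rank correlation between two moment sets
#'
#' Standard rank correlation with average ranks for ties, applied to a
#' matched pair of flattened moment fields (or plain numeric vectors).
#'
#' @param a,b `moment_report`s (with `field`) or numeric vectors
#' @param field which moment to compare when reports are given
#' @return rank correlation in `[-1, 1]`
#' @export
spearman_compare <- function(a, b, field = "mean_v") {
  x <- if (inherits(a, "moment_report")) moment_field(a, field) else as.numeric(a)
  y <- if (inherits(b, "moment_report")) moment_field(b, field) else as.numeric(b)
  if (length(x) != length(y)) stop_dims("b", length(x), length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Bootstrap comparison of two models against data moments
#'
#' Splits the neurons into non-overlapping random subsets (each neuron
#' sampled at most once), computes the Spearman correlation between data and
#' model moments within each subset, and declares a model better when the
#' mean +/- 2 SD intervals of the two models do not overlap.
#'
#' @param moments_data data `moment_report`
#' @param momentsA,momentsB model `moment_report`s on the same units
#' @param subset_size neurons per subset (default 1000)
#' @param fields moment fields to compare
#' @param seed optional seed
#' @return data.frame with per-field means, SDs, interval bounds and a
#'   decision in `{"A better", "B better", "indistinguishable"}`
#' @export
bootstrap_model_comparison <- function(moments_data, momentsA, momentsB,
                                       subset_size = 1000L,
                                       fields = c("mean_v", "pair_vv", "shifted_vv"),
                                       seed = NULL) {
  Nv <- length(moments_data$mean_v)
  subset_size <- as.integer(subset_size)
  if (Nv < subset_size) stop("fewer neurons than subset_size", call. = FALSE)
  n_subsets <- Nv %/% subset_size
  if (n_subsets < 2L) stop("need at least 2 non-overlapping subsets", call. = FALSE)
  with_seed(seed, {
    perm <- sample.int(Nv)
    subsets <- split(perm[seq_len(n_subsets * subset_size)],
                     rep(seq_len(n_subsets), each = subset_size))
    rows <- lapply(fields, function(f) {
      rsA <- vapply(subsets, function(u) {
        stats::cor(moment_field(moments_data, f, u), moment_field(momentsA, f, u),
                   method = "spearman")
      }, numeric(1))
      rsB <- vapply(subsets, function(u) {
        stats::cor(moment_field(moments_data, f, u), moment_field(momentsB, f, u),
                   method = "spearman")
      }, numeric(1))
      loA <- mean(rsA) - 2 * stats::sd(rsA); hiA <- mean(rsA) + 2 * stats::sd(rsA)
      loB <- mean(rsB) - 2 * stats::sd(rsB); hiB <- mean(rsB) + 2 * stats::sd(rsB)
      decision <- if (loA > hiB) "A better" else if (loB > hiA) "B better"
                  else "indistinguishable"
      data.frame(field = f, mean_A = mean(rsA), sd_A = stats::sd(rsA),
                 mean_B = mean(rsB), sd_B = stats::sd(rsB),
                 lo_A = loA, hi_A = hiA, lo_B = loB, hi_B = hiB,
                 n_subsets = n_subsets, decision = decision)
    })
    do.call(rbind, rows)
  })
}

#' Multi-step-ahead prediction error
#'
#' For each start column, the model is initialized on the observed state and
#' rolled forward by Gibbs sampling. With the default `estimator = "mean"`
#' the prediction at horizon `h` is the across-chain mean visible
#' probability after `h` model time-steps. With `estimator = "sample"` each
#' chain's sampled binary state is scored and the error averaged over
#' chains; binary predictions make MSE equal to the mean absolute error and
#' 1 - accuracy (checked on every call), and a model that samples each unit
#' at its marginal rate then attains exactly the naive bound
#' `mean(2 p (1 - p))`.
#'
#' Before the rollout the mean-field state is warmed up by running the
#' observed recursion over `context` preceding columns — predictions start
#' from an informed hidden state, as when test batches are scanned
#' sequentially.
#'
#' @param params an [rbm_params()] or [rtrbm_params()]; a static RBM
#'   advances one time-step per `K` Gibbs sweeps from the current sample
#' @param test a [spike_raster()]
#' @param horizons integer prediction horizons (model time-steps ahead)
#' @param n_starts number of start columns (sampled without replacement when
#'   possible)
#' @param n_chains rollouts averaged per start
#' @param K Gibbs sweeps per generated time-step
#' @param estimator `"mean"` (across-chain mean probability, default) or
#'   `"sample"` (stochastic binary prediction)
#' @param rollout `"gibbs"` (stochastic chains, default) or `"mean_field"`
#'   (deterministic damped mean-field inference from a neutral visible
#'   state at every step — the same fixed point the mean-field negative
#'   phase trains against, hence the calibrated choice for models trained
#'   with `negative_phase = "mean_field"`; `n_chains` is then irrelevant)
#' @param mf_iters mean-field iterations per step for the
#'   `"mean_field"` rollout
#' @param context observed columns preceding each start over which the
#'   mean-field recursion is run to initialize `r` (RTRBM only); start
#'   columns are drawn so that the context fits
#' @param seed optional seed
#' @return list: `mse_per_horizon` (named numeric), `horizons`, `n_starts`
#' @export
prediction_mse <- function(params, test, horizons = 1L, n_starts = 100L,
                           n_chains = 100L, K = 15L,
                           estimator = c("mean", "sample"),
                           rollout = c("gibbs", "mean_field"),
                           mf_iters = 10L, context = 8L,
                           seed = NULL) {
  estimator <- match.arg(estimator)
  rollout <- match.arg(rollout)
  V <- if (inherits(test, "spike_raster")) test$values else as.matrix(test)
  T <- ncol(V)
  horizons <- sort(unique(as.integer(horizons)))
  if (any(horizons < 1L)) stop("horizons must be >= 1", call. = FALSE)
  H <- max(horizons)
  if (H >= T) stop("horizon must be smaller than the test length", call. = FALSE)
  Nv <- nrow(V)
  temporal <- inherits(params, "rtrbm_params")
  context <- max(0L, as.integer(context))
  if (T - H - context < 1L) stop("test raster too short for context + horizon",
                                 call. = FALSE)
  if (rollout == "mean_field") n_chains <- 1L
  with_seed(seed, {
    n_starts <- min(n_starts, T - H - context)
    starts <- context + sample.int(T - H - context, n_starts)
    idx <- rep(starts, each = n_chains)
    Vc <- V[, idx, drop = FALSE]                  # Nv x (n_starts * n_chains)
    if (temporal) {
      # teacher-forced warm-up of the mean-field state over the context
      r_start <- vapply(starts, function(s) {
        hidden_trace(V[, (s - context):s, drop = FALSE], params)[, context + 1L]
      }, numeric(n_hidden(params)))
      R <- r_start[, rep(seq_along(starts), each = n_chains), drop = FALSE]
    }
    mse <- stats::setNames(numeric(length(horizons)), paste0("h", horizons))
    for (h in seq_len(H)) {
      # p_h_given_v adds bh itself; the extra term is only U r[t-1]
      extra <- if (temporal) params$U %*% R else NULL
      if (rollout == "mean_field") {
        bias <- if (temporal) params$bh + extra else params$bh
        vn <- matrix(sigmoid(params$bv), Nv, ncol(Vc))
        hn <- sigmoid(params$W %*% vn + bias)
        for (i in seq_len(mf_iters)) {
          vn <- 0.5 * vn + 0.5 * sigmoid(crossprod(params$W, hn) + params$bv)
          hn <- 0.5 * hn + 0.5 * sigmoid(params$W %*% vn + bias)
        }
        pvt <- vn
        Vc <- if (estimator == "sample") {
          matrix(stats::rbinom(length(vn), 1L, vn), Nv, ncol(vn))
        } else vn
        if (temporal) R <- hn
      } else {
        pvt <- NULL
        for (k in seq_len(K)) {
          sw <- gibbs_sweep(Vc, params, extra = extra)
          Vc <- sw$v
          pvt <- sw$p_v
        }
        if (temporal) R <- sigmoid(params$W %*% Vc + params$bh + extra)
      }
      if (h %in% horizons) {
        truth_rep <- V[, idx + h, drop = FALSE]
        if (estimator == "sample") {
          err <- mean((truth_rep - Vc)^2)
          mae <- mean(abs(truth_rep - Vc))
          acc <- mean(truth_rep == Vc)
          stopifnot(isTRUE(all.equal(err, mae)), isTRUE(all.equal(err, 1 - acc)))
        } else {
          dim3 <- c(Nv, n_chains, n_starts)
          pred <- apply(array(pvt, dim3), c(1L, 3L), mean)
          err <- mean((V[, starts + h, drop = FALSE] - pred)^2)
        }
        mse[paste0("h", h)] <- err
      }
    }
    list(mse_per_horizon = mse, horizons = horizons, n_starts = n_starts,
         estimator = estimator, rollout = rollout)
  })
}

#' MSE of the naive unbiased estimator
#'
#' The naive estimator predicts each unit as an independent Bernoulli draw
#' with that unit's mean activity `p_i`; its expected squared error is
#' exactly `mean_i 2 p_i (1 - p_i)`.
#'
#' @param raster a [spike_raster()] or binary matrix
#' @return scalar upper-bound MSE
#' @export
naive_mse <- function(raster) {
  V <- if (inherits(raster, "spike_raster")) raster$values else as.matrix(raster)
  p <- rowMeans(V)
  mean(2 * p * (1 - p))
}

#' Variance-limited lower bound on the prediction MSE
#'
#' Empirical lower bound for the simulated-data generator: an ideal
#' predictor knows the assembly state one interaction delay back exactly and
#' is limited only by the randomness of the intrinsic rates and the Poisson
#' observation. Per sampled initial assembly state, the deterministic
#' interaction term is propagated `delta_tA` steps, pairs of independent
#' intrinsic-rate draws are added, both states of each pair are
#' Poisson-observed once, and the MSE between the paired observations is
#' recorded. The grand mean is `MSEvar`; the SEM treats each initial state's
#' mean as one estimate.
#'
#' @param sim a `sim_output` from [simulate_assemblies()] (supplies the
#'   generator config, realized neuron scales, and the assembly states to
#'   sample from)
#' @param n_states number of sampled initial assembly states (default 10000)
#' @param n_instances intrinsic-rate draw pairs per state (default 200)
#' @param seed optional seed
#' @return list with `mse_var` and `sem`
#' @export
lower_bound_mse <- function(sim, n_states = 10000L, n_instances = 200L,
                            seed = NULL) {
  stopifnot(inherits(sim, "sim_output"))
  cfg <- sim$config
  T <- ncol(sim$rates)
  with_seed(seed, {
    state_idx <- sample.int(T, n_states, replace = n_states > T)
    # deterministic interaction input delta_tA ahead of each sampled state
    drive <- cfg$U %*% sim$rates[, state_idx, drop = FALSE]   # Nh x n_states
    # pool of intrinsic-rate columns to draw instances from
    intr_pool <- sim$intrinsic_rates
    membership <- sim$membership
    scales <- sim$scales
    per_state <- numeric(n_states)
    for (s in seq_len(n_states)) {
      cols <- sample.int(ncol(intr_pool), 2L * n_instances, replace = TRUE)
      lam <- rate_limiter(intr_pool[, cols, drop = FALSE] + drive[, s],
                          cfg$fmax, cfg$limiter)
      lam_v <- lam[membership, , drop = FALSE] * scales
      obs <- matrix(stats::rpois(length(lam_v), lam_v) >= 1L, nrow(lam_v))
      a <- obs[, seq_len(n_instances), drop = FALSE]
      b <- obs[, n_instances + seq_len(n_instances), drop = FALSE]
      per_state[s] <- mean((a - b)^2)
    }
    list(mse_var = mean(per_state),
         sem = stats::sd(per_state) / sqrt(n_states))
  })
}

#' Normalized MSE
#'
#' Rescales raw prediction MSEs so that the variance-limited optimal
#' estimator scores 0 and the naive unbiased mean-rate estimator scores 1:
#' `nMSE = (MSE - MSEvar) / (MSEnaive - MSEvar)`.
#'
#' @param mse numeric vector of raw MSEs (e.g. per horizon)
#' @param mse_naive naive-estimator MSE ([naive_mse()])
#' @param mse_var variance-limited lower bound ([lower_bound_mse()])
#' @return an `nmse_report`: `mse_per_horizon`, `mse_naive`, `mse_var`,
#'   `nmse_per_horizon`
#' @export
nmse <- function(mse, mse_naive, mse_var) {
  if (mse_naive <= mse_var) {
    stop("degenerate normalization: mse_naive <= mse_var", call. = FALSE)
  }
  structure(list(
    mse_per_horizon = mse,
    mse_naive = mse_naive,
    mse_var = mse_var,
    nmse_per_horizon = (mse - mse_var) / (mse_naive - mse_var)
  ), class = "nmse_report")
}

#' Hypothesis tests for model comparisons
#'
#' Dispatches to the standard tests used for model comparison: one- or
#' two-sided Mann-Whitney U (`"mannwhitney"`), Wilcoxon signed rank
#' (`"wilcoxon"`, paired), per-horizon two-group t-tests with Bonferroni
#' correction (`"ttest_bonferroni"`; `a` and `b` are then matrices with one
#' column per horizon), or a two-way ANOVA with horizon and model as factors
#' (`"anova2"`).
#'
#' @param a,b numeric sample vectors (matrices for the per-horizon schemes)
#' @param scheme test to run
#' @param alternative passed to the underlying test where applicable
#' @return for the scalar schemes, a list with `statistic` and `p_value`;
#'   for `"ttest_bonferroni"`, a data.frame per horizon with adjusted
#'   p-values (factor = number of horizons); for `"anova2"`, the model-factor
#'   row of the ANOVA table as a list
#' @export
model_comparison_tests <- function(a, b,
                                   scheme = c("mannwhitney", "wilcoxon",
                                              "ttest_bonferroni", "anova2"),
                                   alternative = "two.sided") {
  scheme <- match.arg(scheme)
  if (scheme %in% c("mannwhitney", "wilcoxon")) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) < 3L || length(b) < 3L) stop("need >= 3 samples per group", call. = FALSE)
    ht <- stats::wilcox.test(a, b, paired = (scheme == "wilcoxon"),
                             alternative = alternative, exact = TRUE)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value))
  }
  A <- as.matrix(a); B <- as.matrix(b)
  if (scheme == "ttest_bonferroni") {
    if (ncol(A) != ncol(B)) stop_dims("b", ncol(A), ncol(B))
    n_h <- ncol(A)
    rows <- lapply(seq_len(n_h), function(j) {
      ht <- stats::t.test(A[, j], B[, j], alternative = alternative)
      data.frame(horizon = j, statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 p_adjusted = min(1, ht$p.value * n_h))
    })
    return(do.call(rbind, rows))
  }
  # anova2: samples x horizons matrices, factors = horizon and model
  df <- rbind(
    data.frame(y = as.numeric(A), horizon = factor(col(A)), model = "A"),
    data.frame(y = as.numeric(B), horizon = factor(col(B)), model = "B")
  )
  fit <- stats::aov(y ~ horizon + model, data = df)
  tab <- summary(fit)[[1L]]
  i <- which(trimws(rownames(tab)) == "model")
  list(statistic = tab[i, "F value"], p_value = tab[i, "Pr(>F)"], table = tab)
}

#' Scan down-sampling rates to identify the interaction timescale
#'
#' For each candidate rate, independent datasets are generated from the same
#' interaction structure, decimated by the rate, and an RTRBM is trained on
#' each with an identical gradient-update budget; the one-step-ahead nMSE on
#' a held-out decimated test set and the cosine similarity of the aligned
#' estimated `U` are recorded. The rate minimizing the mean nMSE estimates
#' the assembly interaction delay.
#'
#' @param config a [sim_config()] (its `delta_tA` is the ground truth the
#'   scan should recover)
#' @param rates integer down-sampling rates to scan
#' @param tc a [train_config()]; set its `n_updates` for an equal budget
#' @param n_seeds independent training datasets/models per rate; each run's
#'   dataset is shared across all rates, and a single held-out test dataset
#'   is used throughout, so rates are compared on common data
#' @param n_states,n_instances lower-bound estimation sizes (see
#'   [lower_bound_mse()])
#' @param n_starts,n_chains,K prediction settings (see [prediction_mse()])
#' @param estimator prediction estimator (see [prediction_mse()]); the
#'   default `"mean"` scores the across-chain mean probability, the
#'   lower-variance choice when comparing rates on common data
#' @param rollout prediction rollout (see [prediction_mse()]); the default
#'   `"mean_field"` matches the scan's mean-field-trained models
#' @param seed base seed; all per-rate/per-seed streams derive from it
#' @param min_train_columns guard: a rate leaving fewer decimated training
#'   columns than this is an error
#' @return list with `table` (per rate x seed: nmse, cosine, mse, bounds),
#'   `summary` (per rate means), `best_rate` (argmin of mean nMSE), and
#'   `best_rate_cosine` (argmax of mean cosine similarity)
#' @export
timescale_scan <- function(config, rates = 1:10, tc = train_config(),
                           n_seeds = 3L, n_states = 500L, n_instances = 50L,
                           n_starts = 100L, n_chains = 50L, K = 15L,
                           estimator = "mean", rollout = "mean_field",
                           seed = 1L, min_train_columns = 50L) {
  rates <- as.integer(rates)
  if (length(rates) == 0L || any(rates < 1L)) stop("rates must be >= 1", call. = FALSE)
  test_sim <- simulate_assemblies(config, seed = child_seed(seed, 999L))
  lb <- lower_bound_mse(test_sim, n_states = n_states,
                        n_instances = n_instances,
                        seed = child_seed(seed, 998L))
  train_sims <- lapply(seq_len(n_seeds), function(si) {
    simulate_assemblies(config, seed = child_seed(seed, si))
  })
  rows <- list()
  for (ri in seq_along(rates)) {
    rate <- rates[ri]
    te <- downsample_raster(test_sim$raster, rate)
    for (si in seq_len(n_seeds)) {
      s0 <- child_seed(seed, 1000L * ri + si)
      train_sim <- train_sims[[si]]
      tr <- downsample_raster(train_sim$raster, rate)
      if (ncol(tr$values) < min_train_columns) {
        stop(sprintf("rate %d leaves only %d training columns", rate,
                     ncol(tr$values)), call. = FALSE)
      }
      tc_run <- tc
      tc_run$seed <- s0 + 1L
      fit <- train_rtrbm(tr, tc_run)
      pm <- prediction_mse(fit$params, te, horizons = 1L, n_starts = n_starts,
                           n_chains = n_chains, K = K, estimator = estimator,
                           rollout = rollout, seed = s0 + 3L)
      nm <- nmse(pm$mse_per_horizon[["h1"]], naive_mse(te), lb$mse_var)
      map <- match_assemblies(fit$params$W, train_sim$membership)
      cs <- cosine_similarity_U(train_sim$U_true, align_U(fit$params$U, map))
      rows[[length(rows) + 1L]] <- data.frame(
        rate = rate, seed_index = si, mse = pm$mse_per_horizon[["h1"]],
        mse_naive = nm$mse_naive, mse_var = nm$mse_var,
        nmse = nm$nmse_per_horizon, cosine = cs
      )
    }
  }
  table <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(table, table$rate), function(d) {
    data.frame(rate = d$rate[1L], nmse = mean(d$nmse), cosine = mean(d$cosine))
  }))
  summary <- summary[order(summary$rate), ]
  list(table = table, summary = summary,
       best_rate = summary$rate[which.min(summary$nmse)],
       best_rate_cosine = summary$rate[which.max(summary$cosine)])
}
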