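# Ground-truth generator: Nh latent assemblies with intrinsic Gaussian-bump
# firing rates, delayed pairwise interactions through U, and per-neuron
# Poisson observation binarized to a spike raster.

#' Simulator configuration
#'
#' Parameters of the assembly-activity generator. Intrinsic rates are built
#' from randomly timed peaks (inter-peak intervals uniform on `[t1, t2]`)
#' convolved with unit-sum Gaussian kernels (widths uniform on
#' `[sigma1, sigma2]`); assemblies interact through `U` at a delay of
#' `delta_tA` time-steps; each neuron observes its assembly's rate through an
#' independent Poisson draw scaled by a per-neuron constant in `[c1, c2]`.
#' All time quantities are in time-steps; `fmax` is on the per-time-step
#' Poisson-rate scale.
#'
#' @param Nh number of assemblies
#' @param Nv_per_assembly neurons observing each assembly
#' @param t1,t2 inter-peak-interval bounds (`t1 < t2`)
#' @param sigma1,sigma2 Gaussian-bump width bounds (`sigma1 < sigma2`)
#' @param c1,c2 per-neuron rate-scale bounds (`c1 < c2`)
#' @param t_settle burn-in time-steps removed from the output
#' @param fmax peak intrinsic rate; total rates are limited to `[0, 3 fmax]`
#' @param delta_tA interaction delay in time-steps (`>= 1`)
#' @param U `Nh x Nh` interaction matrix (defaults to [default_U()])
#' @param T output length after burn-in removal
#' @param limiter range limiter applied to the interacting rates: hard
#'   clamping to `[0, 3 fmax]` (default) or a scaled Gaussian-CDF squashing
#' @return a `sim_config` list
#' @export
sim_config <- function(Nh = 10L, Nv_per_assembly = 20L, t1 = 5, t2 = 10,
                       sigma1 = 0.1, sigma2 = 0.5, c1 = 0.6, c2 = 1.4,
                       t_settle = 25L, fmax = 0.8, delta_tA = 1L,
                       U = NULL, T = 5000L,
                       limiter = c("clamp", "gauss_cdf")) {
  limiter <- match.arg(limiter)
  stopifnot(t1 < t2, sigma1 < sigma2, c1 < c2, fmax >= 0, delta_tA >= 1L,
            t_settle >= 0L, Nh >= 1L, Nv_per_assembly >= 1L, T >= 1L)
  if (is.null(U)) U <- default_U(Nh)
  U <- as.matrix(U)
  if (!all(dim(U) == Nh)) stop_dims("U", sprintf("%d x %d", Nh, Nh),
                                    paste(dim(U), collapse = " x "))
  assert_finite(U, "U")
  structure(list(
    Nh = as.integer(Nh), Nv_per_assembly = as.integer(Nv_per_assembly),
    t1 = t1, t2 = t2, sigma1 = sigma1, sigma2 = sigma2, c1 = c1, c2 = c2,
    t_settle = as.integer(t_settle), fmax = fmax,
    delta_tA = as.integer(delta_tA), U = U, T = as.integer(T),
    limiter = limiter
  ), class = "sim_config")
}

#' Default simulator configuration
#'
#' The reference parameter set for the assembly generator: 10 assemblies of
#' 20 neurons, inter-peak intervals on `[5, 10]`, bump widths on
#' `[0.1, 0.5]`, neuron scales on `[0.6, 1.4]`, 25 burn-in steps,
#' `fmax = 0.8`, and the standard interaction structure of [default_U()].
#'
#' @param delta_tA interaction delay (1 for the recovery experiments, 4 for
#'   the timescale scan)
#' @param T output length
#' @param ... overrides passed to [sim_config()]
#' @return a [sim_config()]
#' @export
default_sim_config <- function(delta_tA = 1L, T = 5000L, ...) {
  base <- list(Nh = 10L, Nv_per_assembly = 20L, t1 = 5, t2 = 10,
               sigma1 = 0.1, sigma2 = 0.5, c1 = 0.6, c2 = 1.4,
               t_settle = 25L, fmax = 0.8, delta_tA = delta_tA, T = T)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Default assembly interaction matrix
#'
#' Each assembly is excited by exactly one other assembly and inhibited by
#' exactly one further assembly, and likewise sends one excitatory and one
#' inhibitory connection: assembly `i` excites its cyclic successor
#' (`U[i+1, i] = +magnitude`) and inhibits its predecessor
#' (`U[i-1, i] = -magnitude`), zero elsewhere — the motif in which activity
#' travels around the ring as a sequence while back-propagation is
#' suppressed. Restricted to its excitatory part with `Nh = 3` this is the
#' 1 -> 2 -> 3 -> 1 cycle.
#'
#' @param Nh number of assemblies (`>= 3` so excitation and inhibition come
#'   from distinct sources)
#' @param magnitude interaction strength
#' @return `Nh x Nh` matrix
#' @export
default_U <- function(Nh, magnitude = 1) {
  Nh <- as.integer(Nh)
  if (Nh < 3L) stop("default_U needs Nh >= 3", call. = FALSE)
  U <- matrix(0, Nh, Nh)
  idx <- seq_len(Nh)
  U[cbind(idx %% Nh + 1L, idx)] <- magnitude
  U[cbind((idx - 2L) %% Nh + 1L, idx)] <- -magnitude
  U
}

# Unit-sum Gaussian kernel on the integer grid, truncated at +/- ceiling(4 sigma).
gauss_kernel <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  x <- -half:half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# One bump-train instance of given length: peaks at a Uniform(0, t2) offset
# followed by Uniform(t1, t2) gaps, convolved with a Gaussian kernel.
bump_train <- function(len, t1, t2, sigma1, sigma2) {
  times <- stats::runif(1, 0, t2)
  repeat {
    nxt <- times[length(times)] + stats::runif(1, t1, t2)
    if (nxt > len) break
    times <- c(times, nxt)
  }
  train <- numeric(len)
  bins <- pmin(pmax(1L, as.integer(round(times))), len)
  train[bins] <- train[bins] + 1
  k <- gauss_kernel(stats::runif(1, sigma1, sigma2))
  half <- (length(k) - 1L) %/% 2L
  conv <- stats::convolve(c(numeric(half), train, numeric(half)), rev(k), type = "filter")
  conv[seq_len(len)]
}

minmax_to <- function(x, upper) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(numeric(length(x)))
  (x - rng[1]) / (rng[2] - rng[1]) * upper
}

#' Intrinsic assembly firing rates
#'
#' Per assembly, two independent bump-train instances are generated and
#' min-max renormalized to `[0, fmax/10]` and `[0, fmax]` respectively; the
#' intrinsic rate is their sum (a weak background plus dominant peaks).
#' Includes the burn-in period: output has `T + t_settle` columns.
#'
#' @param config a [sim_config()]
#' @param seed optional seed
#' @return `Nh x (T + t_settle)` matrix of nonnegative rates
#' @export
intrinsic_rate <- function(config, seed = NULL) {
  len <- config$T + config$t_settle
  if (len < config$t2) stop("T + t_settle must be at least t2", call. = FALSE)
  with_seed(seed, {
    out <- matrix(0, config$Nh, len)
    for (i in seq_len(config$Nh)) {
      a <- minmax_to(bump_train(len, config$t1, config$t2, config$sigma1, config$sigma2),
                     config$fmax / 10)
      b <- minmax_to(bump_train(len, config$t1, config$t2, config$sigma1, config$sigma2),
                     config$fmax)
      out[i, ] <- a + b
    }
    out
  })
}

# The range limiter phi of the interaction update.
rate_limiter <- function(x, fmax, limiter = "clamp") {
  if (limiter == "clamp") {
    pmin(pmax(x, 0), 3 * fmax)
  } else {
    3 * fmax * stats::pnorm(x / fmax - 1.5)
  }
}

#' Delayed recurrent assembly dynamics
#'
#' Applies the interaction update forward in time:
#' `lambda_i(t) = phi(lambda_init_i(t) + sum_j U[i, j] lambda_j(t - delta_tA))`,
#' with `phi` limiting the rates to `[0, 3 fmax]`. Steps with no history
#' (`t <= delta_tA`) use a zero interaction term.
#'
#' @param intrinsic `Nh x T` matrix of intrinsic rates
#' @param U `Nh x Nh` interaction matrix
#' @param delta_tA interaction delay (`>= 1`)
#' @param fmax rate scale of the limiter
#' @param limiter `"clamp"` or `"gauss_cdf"` (see [sim_config()])
#' @return `Nh x T` matrix of interacting rates
#' @export
assembly_dynamics <- function(intrinsic, U, delta_tA, fmax, limiter = "clamp") {
  intrinsic <- as.matrix(intrinsic)
  U <- as.matrix(U)
  assert_finite(U, "U")
  delta_tA <- as.integer(delta_tA)
  stopifnot(delta_tA >= 1L)
  T <- ncol(intrinsic)
  lambda <- matrix(0, nrow(intrinsic), T)
  for (t in seq_len(T)) {
    inter <- if (t > delta_tA) drop(U %*% lambda[, t - delta_tA]) else 0
    lambda[, t] <- rate_limiter(intrinsic[, t] + inter, fmax, limiter)
  }
  lambda
}

#' Poisson observation of assembly rates
#'
#' Neuron k of assembly i draws a per-neuron scale `c_k ~ Uniform(c1, c2)`
#' once, then an independent Poisson count with mean `c_k * lambda_i(t)` per
#' time-step, binarized as count >= 1 (visible units are binary). The first
#' `t_settle` columns are removed.
#'
#' @param rates `Nh x T_total` nonnegative rate matrix (burn-in included)
#' @param config a [sim_config()]
#' @param seed optional seed
#' @param scales optional fixed per-neuron scales (length `Nh * Nv_per_assembly`)
#' @return list with `raster` ([spike_raster()]), `membership` (assembly
#'   index per neuron) and `scales`
#' @export
poisson_observe <- function(rates, config, seed = NULL, scales = NULL) {
  rates <- as.matrix(rates)
  if (any(rates < 0)) stop("rates must be nonnegative", call. = FALSE)
  Nv <- config$Nh * config$Nv_per_assembly
  membership <- rep(seq_len(config$Nh), each = config$Nv_per_assembly)
  with_seed(seed, {
    if (is.null(scales)) scales <- stats::runif(Nv, config$c1, config$c2)
    lam <- rates[membership, , drop = FALSE] * scales
    counts <- matrix(stats::rpois(length(lam), lam), Nv, ncol(lam))
    keep <- if (config$t_settle > 0L) -seq_len(config$t_settle) else TRUE
    V <- (counts >= 1L) * 1
    list(raster = spike_raster(V[, keep, drop = FALSE]),
         membership = membership, scales = scales)
  })
}

#' Generate a full simulated dataset
#'
#' Runs [intrinsic_rate()], [assembly_dynamics()] and [poisson_observe()]
#' in sequence and returns the raster together with all ground truth needed
#' for alignment and evaluation.
#'
#' @param config a [sim_config()]
#' @param seed optional seed (two calls with the same seed are identical)
#' @return a `sim_output` list: `raster`, `rates` and `intrinsic_rates`
#'   (`Nh x T`, burn-in removed), `membership`, `scales`, `U_true`, `config`
#' @export
simulate_assemblies <- function(config = default_sim_config(), seed = NULL) {
  with_seed(seed, {
    intr <- intrinsic_rate(config)
    lambda <- assembly_dynamics(intr, config$U, config$delta_tA, config$fmax,
                                config$limiter)
    obs <- poisson_observe(lambda, config)
    keep <- if (config$t_settle > 0L) -seq_len(config$t_settle) else TRUE
    structure(list(
      raster = obs$raster,
      rates = lambda[, keep, drop = FALSE],
      intrinsic_rates = intr[, keep, drop = FALSE],
      membership = obs$membership,
      scales = obs$scales,
      U_true = config$U,
      config = config
    ), class = "sim_output")
  })
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "sim_output: %d assemblies x %d neurons each, T = %d (delta_tA = %d)\n",
    x$config$Nh, x$config$Nv_per_assembly, ncol(x$raster$values),
    x$config$delta_tA
  ))
  invisible(x)
}
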