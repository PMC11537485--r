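# Moments, prediction error with normalized bounds, significance tests,
# segmenting.

test_that("moments of degenerate and hand-computable rasters are exact", {
  ones <- matrix(1, 3, 10)
  m <- compute_moments(ones)
  expect_equal(m$mean_v, rep(1, 3))
  expect_true(all(m$pair_vv == 1))
  expect_true(all(m$shifted_vv == 1))

  # deterministic alternation 1,0,1,0,...: mean 0.5, lag-1 self-moment 0
  alt <- matrix(rep(c(1, 0), 10), 1, 20)
  ma <- compute_moments(alt)
  expect_equal(ma$mean_v, 0.5)
  expect_equal(ma$shifted_vv[1, 1], 0)
  expect_equal(ma$pair_vv[1, 1], 0.5)
})

test_that("independent Bernoulli units have product pair moments", {
  set.seed(1)
  p <- 0.3
  V <- matrix(rbinom(4 * 40000, 1, p), 4, 40000)
  m <- compute_moments(V)
  off <- m$pair_vv[upper.tri(m$pair_vv)]
  expect_equal(mean(off), p^2, tolerance = 0.05)
  expect_true(isSymmetric(m$pair_vv))
})

test_that("hidden moments come from mean-field traces", {
  q <- random_rtrbm(3, 2, seed = 2)
  V <- random_raster(3, 50, seed = 3)$values
  m <- compute_moments(V, params = q)
  r <- hidden_trace(V, q)
  expect_equal(m$mean_h, rowMeans(r))
  expect_true(all(m$shifted_hh >= 0 & m$shifted_hh <= 1))
})

test_that("naive estimator MSE has the closed form 2p(1-p)", {
  V <- matrix(c(rep(1, 10), rep(0, 10)), 2, 10, byrow = TRUE)
  expect_equal(naive_mse(V), mean(c(0, 0)))
  half <- matrix(rep(c(1, 0), 10), 1, 20)
  expect_equal(naive_mse(half), 0.5)
  # mixed p vector: match a Monte-Carlo run of the naive estimator
  set.seed(4)
  p <- c(0.1, 0.35, 0.6, 0.9)
  V <- matrix(rbinom(4 * 2000, 1, p), 4, 2000)
  sim_mse <- mean((V - matrix(rbinom(4 * 2000, 1, rowMeans(V)), 4, 2000))^2)
  expect_equal(naive_mse(V), sim_mse, tolerance = 0.05)
})

test_that("nMSE endpoints and midpoint follow the normalization", {
  rep_ <- nmse(c(0.05, 0.125, 0.2), mse_naive = 0.2, mse_var = 0.05)
  expect_equal(rep_$nmse_per_horizon, c(0, 0.5, 1))
  expect_error(nmse(0.1, mse_naive = 0.05, mse_var = 0.05), "degenerate")
})

test_that("Spearman comparison reproduces hand-computed rank correlations", {
  expect_equal(spearman_compare(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(spearman_compare(1:7, 7:1), -1)
  expect_equal(spearman_compare(1:7, (1:7)^3), 1)
  expect_error(spearman_compare(rep(1, 5), 1:5), "constant")
})

test_that("segment splitting follows the 1-based index rule and conserves columns", {
  r <- spike_raster(matrix(rbinom(300, 1, .5), 3, 100))
  sp <- split_segments(r)
  # defaults: segments of 10 columns; test segments 2, 6, 7
  test_cols <- sort(unlist(lapply(sp$segment_columns[c(2, 6, 7)],
                                  function(x) x[1]:x[2])))
  expect_identical(test_cols, c(11:20, 51:60, 61:70))
  got <- sum(vapply(c(sp$train, sp$test), function(s) ncol(s$values), integer(1)))
  expect_identical(got, 100L)
  expect_length(sp$train, 7L)
  expect_length(sp$test, 3L)

  sp2 <- split_segments(r, n_segments = 2, test_segments = 2)
  expect_identical(ncol(sp2$test[[1]]$values), 50L)
  expect_error(split_segments(r, test_segments = 1:10), "proper subset")
})

test_that("remainder columns go to the last segment", {
  r <- spike_raster(matrix(rbinom(103 * 2, 1, .5), 2, 103))
  sp <- split_segments(r)
  expect_identical(sp$segment_columns[[10]][2], 103L)
})

test_that("identical groups are not significant; disjoint groups reach minimal p", {
  x <- c(1.2, 1.5, 1.1, 1.4, 1.3, 1.6, 1.25, 1.45, 1.35, 1.55)
  res <- suppressWarnings(model_comparison_tests(x, x, scheme = "mannwhitney"))
  expect_gte(res$p_value, 0.5)
  lo <- 1:10; hi <- 11:20
  res2 <- model_comparison_tests(hi, lo, scheme = "mannwhitney",
                                 alternative = "greater")
  expect_equal(res2$p_value, 1 / choose(20, 10))
  expect_error(model_comparison_tests(1:2, 1:5, scheme = "mannwhitney"),
               ">= 3 samples")
})

test_that("per-horizon t-tests apply the Bonferroni factor", {
  set.seed(5)
  A <- matrix(rnorm(40), 10, 4)
  B <- matrix(rnorm(40, mean = 2), 10, 4)
  res <- model_comparison_tests(A, B, scheme = "ttest_bonferroni",
                                alternative = "less")
  expect_identical(nrow(res), 4L)
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 4))
  res_aov <- model_comparison_tests(A, B, scheme = "anova2")
  expect_lt(res_aov$p_value, 0.001)
})

test_that("bootstrap comparison separates a matched from a shuffled model", {
  set.seed(6)
  Nv <- 60
  data_m <- compute_moments(matrix(rbinom(Nv * 400, 1,
                                          rep(seq(0.05, 0.6, length.out = Nv), 400)),
                                   Nv, 400))
  good <- data_m
  bad <- data_m
  bad$mean_v <- sample(bad$mean_v)
  bad$pair_vv <- bad$pair_vv[sample(Nv), sample(Nv)]
  bad$shifted_vv <- bad$shifted_vv[sample(Nv), sample(Nv)]
  res <- bootstrap_model_comparison(data_m, good, bad, subset_size = 15,
                                    seed = 7)
  expect_true(all(res$decision == "A better"))
  same <- bootstrap_model_comparison(data_m, good, good, subset_size = 15,
                                     seed = 8)
  expect_true(all(same$decision == "indistinguishable"))
  expect_error(bootstrap_model_comparison(data_m, good, bad, subset_size = 61),
               "fewer neurons")
})

test_that("sampled model moments match exact marginals on a tiny static RBM", {
  p <- random_rbm(3, 2, scale = 0.6, seed = 9)
  exact <- rtrbm:::exact_rbm_moments(p)
  test <- random_raster(3, 200, seed = 10)
  mm <- sample_model_moments(p, test, gibbs_steps = 3, burn_in = 100,
                             n_start_points = 200, chain_len = 25, seed = 11)
  n_eff <- mm$n_samples
  se <- sqrt(exact$Ev * (1 - exact$Ev) / n_eff) * 3  # ignores autocorrelation
  expect_true(all(abs(mm$mean_v - exact$Ev) < pmax(4 * se, 0.02)))
  # zero-weight model: sampled means equal sigmoid(bv)
  p0 <- rbm_params(matrix(0, 2, 3), c(-1, 0, 0.5), numeric(2))
  mm0 <- sample_model_moments(p0, test, gibbs_steps = 1, burn_in = 5,
                              n_start_points = 300, chain_len = 20, seed = 12)
  expect_equal(mm0$mean_v, plogis(c(-1, 0, 0.5)), tolerance = 0.03)
})

test_that("prediction error is zero for a copying model and MSE = MAE when binary", {
  # saturated RTRBM that deterministically reproduces the current state:
  # huge diagonal W, U = 0 -> hidden copies visible, visible copies hidden
  Nv <- 4
  q <- rtrbm_params(W = diag(Nv) * 60, U = matrix(0, Nv, Nv),
                    bv = rep(-30, Nv), bh = rep(-30, Nv), binit = rep(-30, Nv))
  const <- spike_raster(matrix(rep(c(1, 0, 1, 0), 30), Nv, 30))
  pm <- prediction_mse(q, const, horizons = 1, n_starts = 5, n_chains = 3,
                       K = 2, seed = 13)
  expect_equal(unname(pm$mse_per_horizon["h1"]), 0)
  pm_mean <- prediction_mse(q, const, horizons = 1:2, n_starts = 4,
                            n_chains = 3, estimator = "mean", K = 2, seed = 14)
  expect_equal(unname(pm_mean$mse_per_horizon), c(0, 0))
  expect_error(prediction_mse(q, const, horizons = 40), "horizon|context")
})

test_that("a marginal-rate sampler attains the naive bound", {
  # zero-weight RBM whose visible bias reproduces the data marginals: its
  # sampled predictions must score the naive MSE 2p(1-p)
  set.seed(21)
  p <- c(0.1, 0.3, 0.5, 0.8)
  V <- matrix(rbinom(4 * 3000, 1, p), 4, 3000)
  phat <- rowMeans(V)
  naive_model <- rbm_params(matrix(0, 2, 4), log(phat / (1 - phat)), numeric(2))
  pm <- prediction_mse(naive_model, V, horizons = 1, n_starts = 300,
                       n_chains = 20, K = 3, estimator = "sample", seed = 22)
  expect_equal(unname(pm$mse_per_horizon["h1"]), naive_mse(V),
               tolerance = 0.02)
})

test_that("the variance bound matches the Bernoulli collision closed form", {
  # constant rates, no interactions: paired observations disagree with
  # probability 2q(1-q), q = 1 - exp(-c lambda)
  lam0 <- 0.7; cscale <- 1.1
  cfg <- sim_config(Nh = 2, Nv_per_assembly = 3, T = 500L, t_settle = 0L,
                    U = matrix(0, 2, 2), c1 = cscale - 1e-6, c2 = cscale + 1e-6)
  sim <- structure(list(
    rates = matrix(lam0, 2, 500), intrinsic_rates = matrix(lam0, 2, 500),
    membership = rep(1:2, each = 3), scales = rep(cscale, 6),
    U_true = cfg$U, config = cfg,
    raster = spike_raster(matrix(0, 6, 500))
  ), class = "sim_output")
  lb <- lower_bound_mse(sim, n_states = 60, n_instances = 40, seed = 15)
  q <- 1 - exp(-cscale * lam0)
  expect_equal(lb$mse_var, 2 * q * (1 - q), tolerance = 4 * lb$sem + 0.01)

  # zero rates everywhere: no stochasticity at all
  sim0 <- sim
  sim0$rates <- sim0$intrinsic_rates <- matrix(0, 2, 500)
  expect_equal(lower_bound_mse(sim0, n_states = 20, n_instances = 10,
                               seed = 16)$mse_var, 0)
})

test_that("the variance bound is below the naive bound on generated data", {
  for (seed in 1:5) {
    sim <- simulate_assemblies(default_sim_config(T = 400L), seed = 30 + seed)
    lb <- lower_bound_mse(sim, n_states = 80, n_instances = 30,
                          seed = 40 + seed)
    expect_lt(lb$mse_var, naive_mse(sim$raster))
  }
})
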