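# CD + BPTT gradients and RTRBM training.

test_that("analytic gradients match finite differences of the exact likelihood", {
  set.seed(1)
  for (rep in 1:5) {
    q <- random_rtrbm(3, 2, scale = 0.8)
    V <- matrix(rbinom(9, 1, 0.5), 3, 3)
    g <- bptt_gradients(V, q, method = "exact", mean_over_time = FALSE)
    for (blk in c("W", "U", "bv", "bh", "binit")) {
      num <- vapply(seq_along(q[[blk]]), function(i) {
        eps <- 1e-5
        qp <- q; qm <- q
        qp[[blk]][i] <- qp[[blk]][i] + eps
        qm[[blk]][i] <- qm[[blk]][i] - eps
        (exact_sequence_loglik(V, qp) - exact_sequence_loglik(V, qm)) / (2 * eps)
      }, numeric(1))
      expect_equal(as.numeric(g[[paste0("d", blk)]]), num, tolerance = 1e-5)
    }
  }
})

test_that("the stochastic CD estimator is consistent with the exact gradient", {
  q <- random_rtrbm(3, 2, scale = 0.6, seed = 2)
  V <- matrix(rbinom(12, 1, 0.5), 3, 4)
  exact <- bptt_gradients(V, q, method = "exact")
  set.seed(3)
  cd <- Reduce(function(a, b) Map(`+`, a, b),
               lapply(1:4000, function(i) bptt_gradients(V, q, K = 20)))
  cd <- lapply(cd, `/`, 4000)
  for (nm in names(exact)) {
    expect_lt(max(abs(as.numeric(cd[[nm]]) - as.numeric(exact[[nm]]))), 0.025)
  }
})

test_that("the compiled gradient kernel agrees with the reference in expectation", {
  q <- random_rtrbm(3, 2, scale = 0.6, seed = 4)
  V <- matrix(rbinom(12, 1, 0.5), 3, 4)
  exact <- bptt_gradients(V, q, method = "exact")
  set.seed(5)
  cpp <- Reduce(function(a, b) Map(`+`, a, b),
                lapply(1:3000, function(i) {
                  rtrbm:::.rtrbm_batch_gradient_cpp(V, q$W, q$U, q$bv, q$bh,
                                                    q$binit, 20L)
                }))
  cpp <- lapply(cpp, `/`, 3000)
  for (nm in names(exact)) {
    expect_lt(max(abs(as.numeric(cpp[[nm]]) - as.numeric(exact[[nm]]))), 0.025)
  }
})

test_that("single-step sequences yield zero temporal gradients", {
  q <- random_rtrbm(3, 2, seed = 6)
  V <- matrix(c(1, 0, 1), 3, 1)
  g <- bptt_gradients(V, q, method = "exact", mean_over_time = FALSE)
  expect_true(all(g$dU == 0))
  expect_true(all(g$dbh == 0))
  # dbinit reduces to the static CD bias gradient at t = 1
  cond <- conditional_rbm_at_t(q, t1 = TRUE)
  mom <- rtrbm:::exact_rbm_moments(cond)
  expect_equal(g$dbinit, drop(p_h_given_v(c(1, 0, 1), cond)) - mom$Eh)
})

test_that("model-matched structureless data gives a vanishing expected U gradient", {
  # data drawn i.i.d. from the static marginal of the model itself: every
  # per-step conditional is already matched, so the expected temporal
  # gradient must vanish
  q <- random_rtrbm(4, 3, scale = 0.3, seed = 7)
  q$U <- matrix(0, 3, 3)
  q$binit <- q$bh
  marg <- rtrbm:::exact_visible_marginal(rbm_params(q$W, q$bv, q$bh))
  set.seed(8)
  acc <- matrix(0, 3, 3)
  n <- 600
  for (i in 1:n) {
    cols <- sample.int(ncol(marg$states), 6, replace = TRUE, prob = marg$p)
    V <- marg$states[, cols]
    acc <- acc + bptt_gradients(V, q, method = "exact")$dU
  }
  expect_lt(max(abs(acc / n)), 0.02)
})

test_that("frozen transfer mode leaves W bit-identical", {
  sim <- simulate_assemblies(default_sim_config(T = 300L), seed = 9)
  W0 <- matrix(rnorm(10 * 200, sd = 0.2), 10, 200)
  tc <- train_config(learning_rate = 0.05, n_updates = 30,
                     batches_per_update = 2, w_learning_rate_factor = 0,
                     seed = 10)
  fit <- train_rtrbm(sim$raster, tc, init_W = W0)
  expect_identical(fit$params$W, W0)
  expect_false(all(fit$params$U == 0))   # the temporal block did train
})

test_that("exact sequence log-likelihood increases during training", {
  # data from a known tiny RTRBM with strong temporal structure
  truth <- rtrbm_params(W = matrix(c(4, -4, -4, 4, 4, -4), 2, 3),
                        U = matrix(c(3, -3, -3, 3), 2, 2),
                        bv = rep(-1, 3), bh = c(0, 0), binit = c(0, 0))
  gen <- sample_sequence(truth, T = 300, K = 5, n_chains = 1, seed = 11)
  V <- gen$v[, , 1]
  tc <- train_config(n_hidden = 2, learning_rate = 0.05, epochs = 30,
                     batch_length = 10, batches_per_update = 5, seed = 12)
  fit <- train_rtrbm(spike_raster(V), tc)
  init <- rtrbm:::with_seed(12L, rtrbm:::init_params(2, 3, temporal = TRUE))
  expect_gt(exact_sequence_loglik(V, fit$params),
            exact_sequence_loglik(V, init) + 1)
})

test_that("RTRBM training is bit-identical under a fixed seed", {
  r <- random_raster(6, 100, p = 0.3, seed = 13)
  tc <- train_config(n_hidden = 3, learning_rate = 0.05, n_updates = 20,
                     batches_per_update = 2, seed = 14)
  f1 <- train_rtrbm(r, tc)
  f2 <- train_rtrbm(r, tc)
  expect_identical(f1$params, f2$params)
})

test_that("reconstruction error is zero for a copier and 0.5 for a coin flip", {
  Nv <- 4
  copier <- rtrbm_params(W = diag(Nv) * 60, U = matrix(0, Nv, Nv),
                         bv = rep(-30, Nv), bh = rep(-30, Nv),
                         binit = rep(-30, Nv))
  V <- matrix(rbinom(Nv * 50, 1, 0.5), Nv, 50)
  expect_equal(reconstruction_mse(V, copier, K = 1, seed = 15,
                                  probabilities = FALSE), 0)
  coin <- rbm_params(matrix(0, 2, Nv), numeric(Nv), numeric(2))
  set.seed(16)
  balanced <- matrix(rbinom(Nv * 4000, 1, 0.5), Nv, 4000)
  expect_equal(reconstruction_mse(balanced, coin, K = 1, seed = 17,
                                  probabilities = FALSE), 0.5,
               tolerance = 0.02)
  # with probability output the coin-flip reconstruction error is 0.25
  expect_equal(reconstruction_mse(balanced, coin, K = 1, seed = 18), 0.25,
               tolerance = 0.01)
})

test_that("reconstruction error decreases over training on simulated data", {
  sim <- simulate_assemblies(default_sim_config(T = 600L), seed = 19)
  tc <- train_config(n_hidden = 10, learning_rate = 0.05, n_updates = 400,
                     batches_per_update = 5, seed = 20)
  fit <- train_rtrbm(sim$raster, tc)
  expect_lt(tail(fit$log$recon_mse, 1), fit$log$recon_mse[1])
})
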