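# Ground-truth generator: intrinsic rates, delayed interactions, Poisson
# observation, decimation.

test_that("reference configuration carries the standard generator values", {
  cfg <- default_sim_config()
  expect_identical(cfg$Nh, 10L)
  expect_identical(cfg$Nv_per_assembly, 20L)
  expect_equal(c(cfg$t1, cfg$t2), c(5, 10))
  expect_equal(c(cfg$sigma1, cfg$sigma2), c(0.1, 0.5))
  expect_equal(c(cfg$c1, cfg$c2), c(0.6, 1.4))
  expect_identical(cfg$t_settle, 25L)
  expect_equal(cfg$fmax, 0.8)
  expect_identical(cfg$delta_tA, 1L)
  expect_identical(default_sim_config(delta_tA = 4L)$delta_tA, 4L)
})

test_that("interaction matrix has one excitatory and one inhibitory link per side", {
  for (Nh in c(3L, 5L, 10L)) {
    U <- default_U(Nh)
    expect_true(all(diag(U) == 0))
    expect_true(all(rowSums(U > 0) == 1), info = paste("Nh", Nh))
    expect_true(all(rowSums(U < 0) == 1))
    expect_true(all(colSums(U > 0) == 1))
    expect_true(all(colSums(U < 0) == 1))
  }
  # excitatory part with Nh = 3 is the 1 -> 2 -> 3 -> 1 cycle
  U3 <- default_U(3)
  expect_true(U3[2, 1] > 0 && U3[3, 2] > 0 && U3[1, 3] > 0)
  expect_error(default_U(2), "Nh >= 3")
})

test_that("intrinsic rates stay in range and vanish at fmax = 0", {
  cfg <- default_sim_config(T = 600L)
  intr <- intrinsic_rate(cfg, seed = 1)
  expect_equal(dim(intr), c(10L, 625L))
  expect_true(all(intr >= 0))
  expect_true(all(intr <= cfg$fmax + cfg$fmax / 10 + 1e-12))
  cfg0 <- default_sim_config(T = 600L, fmax = 0)
  expect_true(all(intrinsic_rate(cfg0, seed = 1) == 0))
})

test_that("inter-peak intervals realized in the rates follow Uniform(t1, t2)", {
  # long single-assembly trace; detect the dominant-instance peaks as local
  # maxima above half the peak rate and check the gap distribution
  cfg <- sim_config(Nh = 1, Nv_per_assembly = 1, T = 60000L, t_settle = 0L,
                    U = matrix(0, 1, 1))
  x <- drop(intrinsic_rate(cfg, seed = 2))
  n <- length(x)
  is_peak <- x > 0.5 * cfg$fmax &
    x >= c(-Inf, x[-n]) & x >= c(x[-1], -Inf)
  gaps <- diff(which(is_peak))
  gaps <- gaps[gaps > 2]            # discard double-detections on flat tops
  expect_gt(length(gaps), 5000)
  # Uniform(5, 10) placed on the integer grid: mean 7.5, gaps within [4, 11]
  expect_equal(mean(gaps), 7.5, tolerance = 0.05)
  expect_true(all(gaps >= 4 & gaps <= 11))
  expect_equal(sd(gaps), sqrt(25 / 12), tolerance = 0.1)
})

test_that("interaction dynamics respect delay, clamping, and the U = 0 identity", {
  cfg <- default_sim_config(T = 200L)
  intr <- intrinsic_rate(cfg, seed = 4)
  lam0 <- assembly_dynamics(intr, matrix(0, 10, 10), cfg$delta_tA, cfg$fmax)
  expect_equal(lam0, intr)   # intrinsic never exceeds 1.1 fmax < 3 fmax

  # two-assembly chain: impulse in assembly 1 appears in assembly 2 at lag d
  for (d in c(1L, 3L, 5L)) {
    impulse <- matrix(0, 2, 40)
    impulse[1, 10] <- 0.8
    U <- matrix(c(0, 1, 0, 0), 2, 2)   # U[2,1] = 1: 1 drives 2
    lam <- assembly_dynamics(impulse, U, d, fmax = 0.8)
    expect_equal(which.max(lam[2, ]), 10L + d)
  }

  # strongly negative input floors at zero; strong positive clamps at 3 fmax
  drive <- matrix(0.8, 2, 30)
  Uneg <- matrix(c(0, -10, 0, 0), 2, 2)
  lamn <- assembly_dynamics(drive, Uneg, 1L, fmax = 0.8)
  expect_true(all(lamn[2, -1] == 0))
  Upos <- matrix(c(0, 10, 0, 0), 2, 2)
  lamp <- assembly_dynamics(drive, Upos, 1L, fmax = 0.8)
  expect_true(all(lamp[2, -1] == 3 * 0.8))
  expect_error(assembly_dynamics(drive, matrix(NA_real_, 2, 2), 1L, 0.8),
               "finite")
})

test_that("rates of generated datasets stay within the limiter range", {
  for (seed in 1:3) {
    sim <- simulate_assemblies(default_sim_config(T = 300L), seed = seed)
    expect_true(all(sim$rates >= 0))
    expect_true(all(sim$rates <= 3 * sim$config$fmax))
  }
})

test_that("Poisson observation matches the Bernoulli closed form", {
  cfg <- sim_config(Nh = 2, Nv_per_assembly = 5, T = 4000L, t_settle = 0L,
                    U = matrix(0, 2, 2))
  lam <- matrix(c(0.3, 1.2), 2, 4000)
  obs <- poisson_observe(lam, cfg, seed = 5)
  expect_true(all(obs$raster$values %in% c(0, 1)))
  expect_equal(dim(obs$raster$values), c(10L, 4000L))
  p_obs <- rowMeans(obs$raster$values)
  p_theory <- 1 - exp(-obs$scales * lam[obs$membership, 1])
  se <- sqrt(p_theory * (1 - p_theory) / 4000)
  expect_true(all(abs(p_obs - p_theory) < 3.5 * se))
  # zero rates give an all-zero raster
  obs0 <- poisson_observe(matrix(0, 2, 100), cfg, seed = 6)
  expect_true(all(obs0$raster$values == 0))
  expect_error(poisson_observe(matrix(-1, 2, 10), cfg), "nonnegative")
})

test_that("generation is deterministic per seed and seeds differ", {
  cfg <- default_sim_config(T = 200L)
  a <- simulate_assemblies(cfg, seed = 7)
  b <- simulate_assemblies(cfg, seed = 7)
  c <- simulate_assemblies(cfg, seed = 8)
  expect_identical(a$raster$values, b$raster$values)
  expect_identical(a$rates, b$rates)
  expect_false(identical(a$raster$values, c$raster$values))
})

test_that("decimation keeps every k-th column and scales dt", {
  r <- spike_raster(matrix(rep(c(1, 0), 50)[1:50], 5, 10), dt = 2)
  expect_equal(downsample_raster(r, 1)$values, r$values)
  d <- downsample_raster(r, 4)
  expect_equal(d$values, r$values[, c(1, 5, 9)])
  expect_equal(d$dt, 8)
  expect_error(downsample_raster(r, 10), "smaller")
})

test_that("excited targets lag their drivers by the interaction delay", {
  cfg <- default_sim_config(T = 800L, U = default_U(10, 0.5))
  wins <- vapply(1:10, function(seed) {
    sim <- simulate_assemblies(cfg, seed = 20 + seed)
    lam <- sim$rates
    T <- ncol(lam)
    lag_cor <- function(d) {
      mean(vapply(1:10, function(i) {
        j <- i %% 10 + 1   # the assembly excited by i
        cor(lam[i, 1:(T - d)], lam[j, (1 + d):T])
      }, numeric(1)))
    }
    lag_cor(cfg$delta_tA) > lag_cor(0)
  }, logical(1))
  expect_gte(sum(wins), 9)   # one-sided sign test at p < 0.05 over 10 seeds
})
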