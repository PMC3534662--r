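test_that("the relative-latency voltage map has the analytic limits", {
  k <- psp_kernel_params()
  expect_equal(vmax_of_dt(0, 0.6, 0.6, k), 1.2, tolerance = 1e-10)
  expect_equal(vmax_of_dt(500, 0.7, 0.9, k), 0.9, tolerance = 1e-6)
  expect_equal(vmax_of_dt(-500, 0.7, 0.9, k), 0.9, tolerance = 1e-6)
  # equal weights: even function of dt
  d <- c(1.5, 4, 11, 27)
  expect_equal(vmax_of_dt(d, 0.8, 0.8, k), vmax_of_dt(-d, 0.8, 0.8, k),
               tolerance = 1e-10)
  expect_error(vmax_of_dt(0, -1, 0.5, k), "positive")
})

test_that("the pair fast path agrees with the general event-driven voltage", {
  set.seed(7)
  k <- psp_kernel_params()
  for (i in 1:30) {
    w <- rnorm(2, 0.5, 0.5)
    if (w[1] + w[2] <= 0 || max(w) <= 0) next
    dt <- runif(1, -60, 60)
    t1 <- 50
    pat <- trial_pattern(1, list(`1` = t1, `2` = t1 + dt))
    m <- tempotron_model(w, kernel = k)
    expect_lt(abs(vmax_of_dt(dt, w[1], w[2], k) -
                    peak_voltage(pat, m, window_ms = 200)$v_max), 1e-10)
  }
})

test_that("boundary solving is symmetric, collapses at synchrony, and round-trips", {
  k <- psp_kernel_params()
  bd <- solve_dt_boundaries(0.6, 0.6, 1, k)
  expect_gt(bd$dt_plus, 0)
  expect_equal(bd$dt_minus, -bd$dt_plus, tolerance = 1e-6)
  # dense-grid bisection oracle for the symmetric root
  g <- seq(0, 60, by = 0.001)
  v <- vmax_of_dt(g, 0.6, 0.6, k)
  expect_equal(bd$dt_plus, g[which.min(abs(v - 1))], tolerance = 0.01)
  # theta = w1 + w2: boundaries collapse to synchrony
  bd2 <- solve_dt_boundaries(0.5, 0.5, 1 - 1e-9, k)
  expect_equal(bd2$dt_plus, 0, tolerance = 0.05)
  # theta below the larger efficacy: always fires, no boundary
  bd3 <- solve_dt_boundaries(1.4, 0.8, 1, k)
  expect_true(is.na(bd3$dt_plus) && is.na(bd3$dt_minus))
})

test_that("weights_for_boundaries inverts solve_dt_boundaries", {
  k <- psp_kernel_params()
  for (req in list(c(-5, 5), c(-3, 8), c(-30, 30), c(-40, 10), c(-1, 2))) {
    sol <- weights_for_boundaries(req[1], req[2], 1, k)
    bd <- solve_dt_boundaries(sol$w1, sol$w2, 1, k)
    expect_lt(abs(bd$dt_minus - req[1]), 1e-4)
    expect_lt(abs(bd$dt_plus - req[2]), 1e-4)
    expect_lt(sol$residual, 1e-8)
    if (sol$regime == "++") expect_true(sol$fires_inside)
    else expect_false(sol$fires_inside)
  }
  # symmetric requests give equal positive weights
  s <- weights_for_boundaries(-12, 12, 1, k)
  expect_equal(s$w1, s$w2, tolerance = 1e-6)
  expect_equal(s$regime, "++")
})

test_that("the fire set is a single interval (tripartite dissection)", {
  k <- psp_kernel_params()
  g <- seq(-80, 80, by = 0.05)
  # ++ weights with max(w) < theta < w1 + w2: fire inside one closed interval
  fire <- vmax_of_dt(g, 0.7, 0.65, k) >= 1
  runs <- rle(fire)
  expect_equal(sum(runs$values), 1)
  # mixed signs with excitatory weight > theta: silent on one interval
  sol <- weights_for_boundaries(-1, 2, 1, k)
  expect_true(sol$regime %in% c("+-", "-+"))
  silent <- vmax_of_dt(g, sol$w1, sol$w2, k) < 1
  expect_equal(sum(rle(silent)$values), 1)
})

test_that("the ++/mixed regime split approaches the kernel time-to-peak asymptotically", {
  k <- psp_kernel_params()
  # with one boundary far out (dt_minus = -40), the solution type switches
  # from mixed to purely excitatory as the other boundary passes the
  # kernel's time-to-peak (4.62 ms): the transition is bracketed by it
  tp <- k$t_peak
  expect_true(weights_for_boundaries(-40, 4, 1, k)$regime %in% c("+-", "-+"))
  expect_equal(weights_for_boundaries(-40, 6, 1, k)$regime, "++")
  expect_true(tp > 4 && tp < 6)
  # a symmetric wide request stays purely excitatory
  expect_equal(weights_for_boundaries(-50, 50, 1, k)$regime, "++")
})

test_that("threshold-noise error behaves at its limits and prefers separating kernels", {
  k <- psp_kernel_params()
  tight <- data.frame(mu = c(0, -40, 40), sd = c(1, 1, 1), label = c(1, 0, 0))
  expect_lt(threshold_noise_error(tight, 0.6, 0.6, 1, k, noise_frac = 1e-12),
            1e-6)
  expect_equal(threshold_noise_error(tight, 0.6, 0.6, 1, k, noise_frac = 1e5),
               0.5, tolerance = 1e-3)
  # a kernel with larger voltage separation yields a lower achievable error
  noise <- data.frame(mu = c(0, -40, 40), sd = c(6, 6, 6), label = c(1, 0, 0))
  short_k <- optimize_pair(noise, tau_grid = 8,
                           weight_grid = seq(0.1, 2, by = 0.05),
                           constraint = "++", nq = 41)
  long_k <- optimize_pair(noise, tau_grid = 100,
                          weight_grid = seq(0.1, 2, by = 0.05),
                          constraint = "++", nq = 41)
  expect_lt(short_k$error, long_k$error)
})

test_that("pair optimization reproduces the U-shaped error versus time constant", {
  noise <- data.frame(mu = c(0, -40, 40), sd = c(4, 4, 4), label = c(1, 0, 0))
  op <- optimize_pair(noise, tau_grid = c(1, 10, 100),
                      weight_grid = seq(-2, 2, length.out = 41), nq = 41)
  expect_lt(op$error[op$tau_m == 10], op$error[op$tau_m == 1])
  expect_lt(op$error[op$tau_m == 10], op$error[op$tau_m == 100])
  expect_lt(op$error[op$tau_m == 10], 0.05)
  # a mixed-sign solution also separates the three peaks, with the output
  # convention reversed (it fires for the separated class)
  tight <- data.frame(mu = c(0, -40, 40), sd = c(2, 2, 2), label = c(0, 1, 1))
  mixed <- optimize_pair(tight, tau_grid = 10,
                         weight_grid = seq(-2, 2, length.out = 81),
                         constraint = "mixed", nq = 41)
  expect_lt(mixed$error, 0.05)
})

test_that("the readout-time sweep rises from chance to the unrestricted optimum", {
  cfg <- population_config(n_cells = 2, failure_rate = rep(0, 4))
  pop <- sample_population(cfg, seed = 21)
  pop$phase_offset <- c(0, 180)
  ds <- restrict_spikes(simulate_dataset(pop, trials_per_condition = 12,
                                         contrasts = 47, seed = 22), k_max = 1)
  spec_l <- enumerate_realizations("luminance")[[1]]
  sw <- readout_time_sweep(ds, spec_l, t_max_grid = c(5, 90, 1000, 1e6),
                           weight_grid = seq(-2, 2, length.out = 21))
  # t_max below every latency: all trials silent -> chance on balanced classes
  expect_equal(sw$fraction_correct[sw$t_max == 5], 0.5)
  # t_max beyond every latency: equals the unrestricted optimum
  expect_equal(sw$fraction_correct[sw$t_max == 1000],
               sw$fraction_correct[sw$t_max == 1e6])
  expect_gt(sw$fraction_correct[sw$t_max == 1000],
            sw$fraction_correct[sw$t_max == 5])
  expect_error(readout_time_sweep(ds, spec_l, numeric(0)), "non-empty")
})

test_that("the boundary task needs more readout time than the luminance task", {
  cfg <- population_config(n_cells = 2, failure_rate = rep(0, 4))
  pop <- sample_population(cfg, seed = 21)
  pop$phase_offset <- c(0, 180)
  ds <- restrict_spikes(simulate_dataset(pop, trials_per_condition = 15,
                                         contrasts = 47, seed = 22), k_max = 1)
  grid <- seq(40, 140, by = 10)
  plateau_at <- function(task) {
    sw <- readout_time_sweep(ds, enumerate_realizations(task)[[1]],
                             t_max_grid = grid,
                             weight_grid = seq(-2, 2, length.out = 21))
    fc <- sw$fraction_correct
    grid[which(fc >= 0.95 * max(fc))[1]]
  }
  expect_lt(plateau_at("luminance"), plateau_at("boundary"))
})
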