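test_that("PSP kernel is causal, unit-peak, and peaks at the analytic time", {
  k <- psp_kernel_params(10, 2.5)
  expect_equal(psp_kernel(0, k), 0)
  expect_equal(psp_kernel(-5, k), 0)
  tstar <- 10 * 2.5 / (10 - 2.5) * log(10 / 2.5)
  expect_equal(k$t_peak, tstar, tolerance = 1e-12)
  expect_equal(psp_kernel(tstar, k), 1, tolerance = 1e-12)
  # dense-grid maximization confirms peak location and unit height
  g <- seq(0.0001, 100, by = 0.0001)
  kv <- psp_kernel(g, k)
  expect_equal(max(kv), 1, tolerance = 1e-8)
  expect_equal(g[which.max(kv)], 4.6210, tolerance = 1e-3)
  # monotone decay beyond the peak, vanishing tail
  late <- psp_kernel(seq(tstar, 200, by = 1), k)
  expect_true(all(diff(late) < 0))
  expect_lt(psp_kernel(500, k), 1e-10)
  expect_error(psp_kernel_params(2, 5), "tau_m > tau_s")
})

test_that("kernel peak is exactly 1 for arbitrary valid time constants", {
  set.seed(1)
  for (i in 1:20) {
    taus <- runif(1, 0.5, 20)
    taum <- taus * runif(1, 1.05, 10)
    k <- psp_kernel_params(taum, taus)
    expect_equal(psp_kernel(k$t_peak, k), 1, tolerance = 1e-10)
  }
})

test_that("depression factors follow the resource recursion and its limits", {
  expect_equal(depression_factors(50, 0.5, 300), 1)
  # U = 1, ISI = 5, tau_d = 500: second spike almost fully discounted
  R <- depression_factors(c(0, 5), 1, 500)
  expect_equal(R[2], 1 - exp(-0.01), tolerance = 1e-12)
  expect_lt(R[2], 0.02)
  # tau_d -> 0: full recovery, static synapse limit
  expect_equal(depression_factors(c(0, 5, 10), 0.9, 1e-9), rep(1, 3))
  # general recursion against direct evaluation
  tt <- c(3, 9, 20, 21)
  R2 <- depression_factors(tt, 0.4, 80)
  expect_equal(R2[1], 1)
  for (j in 1:3)
    expect_equal(R2[j + 1],
                 1 - (1 - 0.6 * R2[j]) * exp(-(tt[j + 1] - tt[j]) / 80))
  expect_error(depression_factors(c(5, 3), 0.5, 100), "sorted")
})

test_that("peak voltage matches kernel normalization and superposition", {
  m <- tempotron_model(c(0.8, 0.5))
  pv <- peak_voltage(trial_pattern(1, list(`1` = 20, `2` = numeric(0))), m)
  expect_equal(pv$v_max, 0.8, tolerance = 1e-10)
  expect_equal(pv$t_vmax, 20 + m$kernel$t_peak, tolerance = 1e-8)
  # synchronous spikes sum
  m2 <- tempotron_model(c(0.6, 0.6))
  expect_equal(peak_voltage(trial_pattern(1, list(`1` = 30, `2` = 30)), m2)$v_max,
               1.2, tolerance = 1e-10)
  # far-apart spikes: the larger efficacy wins
  m3 <- tempotron_model(c(0.7, 0.9))
  pv3 <- peak_voltage(trial_pattern(1, list(`1` = 10, `2` = 510)), m3,
                      window_ms = 600)
  expect_equal(pv3$v_max, 0.9, tolerance = 1e-6)
  # all-empty pattern
  pv0 <- peak_voltage(trial_pattern(1, list(`1` = numeric(0), `2` = numeric(0))), m)
  expect_equal(pv0$v_max, 0)
  expect_true(is.na(pv0$t_vmax))
})

test_that("event-driven peak voltage equals dense-grid maximization", {
  set.seed(99)
  for (i in 1:100) {
    pat <- random_pattern()
    m <- tempotron_model(rnorm(4, 0, 0.7))
    ev <- peak_voltage(pat, m)
    gr <- grid_peak_voltage(pat, m)
    expect_lt(abs(ev$v_max - gr$v_max), 1e-6)
  }
})

test_that("classification thresholds strictly and crossing precedes the peak", {
  m <- tempotron_model(c(0.6, 0.6))
  pat <- trial_pattern(1, list(`1` = 30, `2` = 30))
  cl <- classify(pat, m)
  expect_true(cl$fired)
  expect_lt(cl$spike_time, peak_voltage(pat, m)$t_vmax)
  # voltage at the reported crossing equals theta
  vtheta <- 1.2 * psp_kernel(cl$spike_time - 30, m$kernel)
  expect_equal(vtheta, 1, tolerance = 1e-9)
  m99 <- tempotron_model(c(0.495, 0.495))
  expect_false(classify(pat, m99)$fired)
  expect_false(classify(trial_pattern(1, list(`1` = numeric(0), `2` = numeric(0))), m)$fired)
})

test_that("classification is invariant to common scaling of weights and threshold", {
  set.seed(5)
  for (i in 1:20) {
    pat <- random_pattern()
    w <- rnorm(4, 0, 0.8)
    s <- runif(1, 0.1, 10)
    f1 <- classify(pat, tempotron_model(w, threshold = 1))$fired
    f2 <- classify(pat, tempotron_model(s * w, threshold = s))$fired
    expect_identical(f1, f2)
  }
})

test_that("time translation shifts the voltage peak without changing its height", {
  set.seed(6)
  for (i in 1:10) {
    pat <- random_pattern(max_spikes = 4, window = 100)
    if (sum(lengths(pat$trains)) == 0) next
    m <- tempotron_model(abs(rnorm(4, 0.3, 0.2)))
    shift <- 23.5
    pat2 <- pat
    pat2$trains <- lapply(pat$trains, function(x) x + shift)
    a <- peak_voltage(pat, m); b <- peak_voltage(pat2, m, window_ms = 200)
    expect_equal(b$v_max, a$v_max, tolerance = 1e-9)
    expect_equal(b$t_vmax, a$t_vmax + shift, tolerance = 1e-6)
  }
})

test_that("learn_step is error-driven with the documented sign and depression scaling", {
  m <- tempotron_model(c(0.6, 0.6))
  st <- learn_state(0.01, momentum = 0, n_weights = 2)
  # correct trial (fires on target): no change
  pat <- trial_pattern(1, list(`1` = 30, `2` = 30))
  out <- learn_step(pat, 1, m, st)
  expect_identical(out$model$weights, m$weights)
  # miss: single afferent spiking before t_vmax gets +lambda*K(t_vmax - t1)
  m2 <- tempotron_model(c(0.5, 0.3))
  pat2 <- trial_pattern(1, list(`1` = 20, `2` = numeric(0)))
  out2 <- learn_step(pat2, 1, m2, st)
  tvm <- peak_voltage(pat2, m2)$t_vmax
  expect_equal(out2$model$weights[1] - 0.5,
               0.01 * psp_kernel(tvm - 20, m2$kernel), tolerance = 1e-10)
  expect_equal(out2$model$weights[2], 0.3)
  # false alarm: same magnitude, negative sign
  out3 <- learn_step(trial_pattern(1, list(`1` = 20, `2` = numeric(0))), 0,
                     tempotron_model(c(1.5, 0)), st)
  expect_lt(out3$model$weights[1], 1.5)
  # depression U = 1: a second spike in the train contributes ~nothing
  mdep <- tempotron_model(c(0.5, 0.3), depression = list(U = 1, tau_d = 500))
  pat3 <- trial_pattern(1, list(`1` = c(20, 25), `2` = numeric(0)))
  out4 <- learn_step(pat3, 1, mdep, st)
  tvm3 <- peak_voltage(pat3, mdep)$t_vmax
  R <- depression_factors(c(20, 25), 1, 500)
  expect_equal(out4$model$weights[1] - 0.5,
               0.01 * sum(R * psp_kernel(tvm3 - c(20, 25), mdep$kernel)),
               tolerance = 1e-10)
  # with depression disabled the dynamic-synapse update reduces to the static rule
  moff <- tempotron_model(c(0.5, 0.3), depression = list(U = 0.6, tau_d = 1e-9))
  mstat <- tempotron_model(c(0.5, 0.3))
  a <- learn_step(pat3, 1, moff, st)$model$weights
  b <- learn_step(pat3, 1, mstat, st)$model$weights
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("training solves the synchrony task and respects trivial limits", {
  syn <- synchrony_dataset()
  # brute-force oracle: a feasible weight pair exists
  wg <- seq(0.1, 1.4, by = 0.05)
  feasible <- FALSE
  for (w in wg) {
    errs <- vapply(seq_along(syn$labels), function(i) {
      f <- classify(syn$dataset$trials[[i]], tempotron_model(c(w, w)))$fired
      f != (syn$labels[i] == 1)
    }, logical(1))
    if (!any(errs)) { feasible <- TRUE; break }
  }
  expect_true(feasible)
  # the learning rule finds a zero-error solution over a few seeded runs
  best <- min(vapply(1:6, function(s)
    train_tempotron(syn$dataset, syn$labels, step_size = 1e-2, cycles = 500,
                    seed = s)$best_error, numeric(1)))
  expect_equal(best, 0)
  # lambda = 0: weights stay at initialization, flat error curve
  fit0 <- train_tempotron(syn$dataset, syn$labels, step_size = 0, cycles = 50,
                          seed = 1)
  set.seed(1)
  expect_equal(fit0$final_model$weights, rnorm(2, 0, 0.05))
  expect_equal(length(unique(fit0$error_curve)), 1)
})

test_that("a single-cycle error spike moves the smoothed minimum by <= 1/window", {
  x <- rep(0.2, 200)
  base <- min(tempotron:::smooth_error_curve(x, 50))
  x[100] <- 1.0
  spiked <- min(tempotron:::smooth_error_curve(x, 50))
  expect_lte(spiked - base, 0.8 / 50 + 1e-12)
  expect_gte(spiked, base)
})

test_that("training is bit-reproducible under a fixed seed", {
  syn <- synchrony_dataset()
  a <- train_tempotron(syn$dataset, syn$labels, step_size = 5e-3, cycles = 80,
                       seed = 11)
  b <- train_tempotron(syn$dataset, syn$labels, step_size = 5e-3, cycles = 80,
                       seed = 11)
  expect_identical(a$model$weights, b$model$weights)
  expect_identical(a$error_curve, b$error_curve)
})
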