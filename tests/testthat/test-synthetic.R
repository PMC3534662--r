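test_that("population sampling is seeded, uniform in phase, independent across measures", {
  cfg <- population_config(n_cells = 200)
  p1 <- sample_population(cfg, seed = 3)
  p2 <- sample_population(cfg, seed = 3)
  expect_identical(p1$latency_baseline, p2$latency_baseline)
  expect_true(all(p1$latency_baseline > p1$latency_amplitude))
  expect_true(all(p1$latency_amplitude > 0))
  big <- sample_population(population_config(n_cells = 1000), seed = 8)
  # uniform phase offsets (goodness-of-fit at 5%)
  ks <- suppressWarnings(stats::ks.test(big$phase_offset, "punif", 0, 360))
  expect_gt(ks$p.value, 0.05)
  # latency and count parameters uncorrelated
  expect_lt(abs(cor(big$latency_baseline, big$count_baseline)), 0.1)
  expect_lt(abs(cor(big$latency_amplitude, big$count_amplitude)), 0.1)
})

test_that("noiseless trials sit exactly on the cosine curves, in antiphase", {
  cfg <- population_config(n_cells = 5, jitter_shared_sd = 1e-12,
                           jitter_private_sd = 1e-12, count_noise_sd = 1e-12,
                           failure_rate = rep(0, 4))
  pop <- sample_population(cfg, seed = 2)
  ds <- simulate_dataset(pop, trials_per_condition = 2, contrasts = 47, seed = 3)
  ft <- fit_population_tuning(ds, contrast = 47)
  lat <- ft[ft$measure == "latency", ]
  expect_equal(lat$baseline, pop$latency_baseline, tolerance = 1e-6)
  expect_equal(lat$amplitude, pop$latency_amplitude, tolerance = 1e-6)
  expect_equal(lat$phase_offset, pop$phase_offset, tolerance = 1e-4)
  expect_true(all(lat$r2_single > 1 - 1e-9))
  # latency and count tuning ~180 deg apart (counts are integer-rounded)
  cnt <- ft[ft$measure == "count", ]
  dphi <- (cnt$phase_offset - lat$phase_offset) %% 360
  expect_true(all(abs(dphi - 180) < 15))
})

test_that("shared jitter produces the predicted pairwise latency correlation", {
  cfg <- population_config(n_cells = 2, jitter_shared_sd = 2,
                           jitter_private_sd = 2, failure_rate = rep(0, 4))
  pop <- sample_population(cfg, seed = 3)
  ds <- simulate_dataset(pop, trials_per_condition = 150, contrasts = 47, seed = 4)
  lat <- function(i) vapply(ds$trials, function(t)
    if (length(t$trains[[i]])) t$trains[[i]][1] else NA_real_, numeric(1))
  st <- vapply(ds$trials, function(t) as.numeric(t$phase_index), numeric(1))
  lc <- latency_correlation(lat(1), lat(2), st)
  # rho = sh^2/(sh^2 + pr^2) = 0.5
  expect_equal(lc$mean_r, 0.5, tolerance = 0.1)
  # with shared jitter only, relative latencies are noise-free
  cfg0 <- population_config(n_cells = 2, jitter_shared_sd = 3,
                            jitter_private_sd = 1e-12, count_noise_sd = 1e-12,
                            failure_rate = rep(0, 4))
  pop0 <- sample_population(cfg0, seed = 5)
  ds0 <- simulate_dataset(pop0, trials_per_condition = 10, contrasts = 47, seed = 6)
  l1 <- vapply(ds0$trials, function(t) t$trains[[1]][1], numeric(1))
  l2 <- vapply(ds0$trials, function(t) t$trains[[2]][1], numeric(1))
  st0 <- vapply(ds0$trials, function(t) as.numeric(t$phase_index), numeric(1))
  for (p in unique(st0))
    expect_lt(stats::sd((l2 - l1)[st0 == p]), 1e-9)
})

test_that("contrast shifts the latency baseline additively, sparing amplitude and phase", {
  cfg <- population_config(n_cells = 4, jitter_shared_sd = 1e-12,
                           jitter_private_sd = 1e-12, count_noise_sd = 1e-12,
                           failure_rate = c(0, 0),
                           contrast_levels = c(23, 47),
                           contrast_shift = c(20, 0))
  pop <- sample_population(cfg, seed = 7)
  ds <- simulate_dataset(pop, trials_per_condition = 2, seed = 8)
  hi <- fit_population_tuning(ds, contrast = 47)
  lo <- fit_population_tuning(ds, contrast = 23)
  hi <- hi[hi$measure == "latency", ]; lo <- lo[lo$measure == "latency", ]
  expect_equal(lo$baseline - hi$baseline, rep(20, 4), tolerance = 1e-6)
  expect_equal(lo$amplitude, hi$amplitude, tolerance = 1e-6)
  expect_equal(lo$phase_offset, hi$phase_offset, tolerance = 1e-4)
})

test_that("failures appear at low contrast and bursts stay inside the window", {
  cfg <- population_config(n_cells = 6)
  pop <- sample_population(cfg, seed = 9)
  ds <- simulate_dataset(pop, trials_per_condition = 25, seed = 10)
  emptiness <- function(cl) {
    tr <- Filter(function(t) t$contrast == cl, ds$trials)
    mean(vapply(tr, function(t) mean(lengths(t$trains) == 0), numeric(1)))
  }
  expect_gt(emptiness(23), emptiness(47))
  for (t in ds$trials) for (tt in t$trains) {
    if (length(tt) > 1) expect_equal(unique(round(diff(tt), 9)), 8)
    if (length(tt) > 0) expect_lte(max(tt), 150)
  }
})

test_that("dark fraction has the point, averaging, and polarity limits", {
  # shrinking RF inside a dark bar -> 1; polarity inversion complements
  expect_equal(dark_fraction(c(0, 0), 1e-4, 180, 0), 1, tolerance = 1e-9)
  set.seed(11)
  for (i in 1:10) {
    ctr <- runif(2, -1, 1); phi <- runif(1, 0, 360); psi <- runif(1, -90, 90)
    D <- dark_fraction(ctr, 0.12, phi, psi)
    expect_equal(D + dark_fraction(ctr, 0.12, phi + 180, psi), 1,
                 tolerance = 1e-9)
    expect_equal(dark_fraction(ctr, 0.12, phi, psi + 180), D, tolerance = 1e-12)
  }
  # RF much wider than the period: half dark
  expect_equal(dark_fraction(c(0.3, -0.2), 10, 77, 31), 0.5, tolerance = 1e-6)
  # continuity in phase and orientation (within the training range)
  d0 <- dark_fraction(c(0.3, 0.2), 0.12, 40, 25)
  expect_lt(abs(dark_fraction(c(0.3, 0.2), 0.12, 40.01, 25) - d0), 1e-3)
  expect_lt(abs(dark_fraction(c(0.3, 0.2), 0.12, 40, 25.01) - d0), 1e-3)
})

test_that("latency falls monotonically with dark coverage between b+a and b-a", {
  expect_equal(eq_latency_from_dark(0, 80, 25), 105)
  expect_equal(eq_latency_from_dark(1, 80, 25), 55)
  expect_equal(eq_latency_from_dark(0.5, 80, 25), 80)
  d <- seq(0, 1, by = 0.01)
  expect_true(all(diff(eq_latency_from_dark(d, 80, 25)) < 0))
  # clipping at small positive latency
  expect_equal(eq_latency_from_dark(0, 1, 25), 26)
  expect_equal(eq_latency_from_dark(1, 1, 25), 0.5)
})

test_that("the hexagonal schematic separates the preferred grating and its inverse", {
  hx <- hex_schematic()
  expect_length(hx$patterns, 128)
  labs <- vapply(hx$patterns, function(p) p$class_label, integer(1))
  expect_equal(sum(labs == 0), 126)
  expect_equal(sum(labs == 1), 2)
  # polarity inversion is an involution mapping preferred <-> inverse
  hx2 <- hex_schematic(preferred = 1 - c(0, 0, 1, 1, 1, 0, 0))
  expect_equal(hx2$preferred_index, hx$inverse_index)
  expect_equal(hx2$inverse_index, hx$preferred_index)
  # exhaustive evaluation: preferred strictly highest, inverse second
  m <- tempotron_model(hx$weights)
  v <- vapply(hx$patterns, function(p) peak_voltage(p, m)$v_max, numeric(1))
  ord <- order(v, decreasing = TRUE)
  expect_equal(ord[1], hx$preferred_index)
  expect_equal(ord[2], hx$inverse_index)
  expect_gt(v[hx$inverse_index],
            max(v[-c(hx$preferred_index, hx$inverse_index)]))
  # a high threshold detects one pattern, a lower one both polarities
  v126 <- max(v[-c(hx$preferred_index, hx$inverse_index)])
  th_high <- (v[hx$preferred_index] + v[hx$inverse_index]) / 2
  th_low <- (v[hx$inverse_index] + v126) / 2
  expect_equal(sum(v >= th_high), 1)
  expect_equal(sum(v >= th_low), 2)
})
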