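#' Configuration of a synthetic fast-Off RGC population
#'
#' The synthetic generator emulates the statistical structure of the fast-Off
#' retinal ganglion cell population: cosine-tuned first-spike latencies and
#' spike counts versus grating phase, phase offsets covering the circle
#' uniformly, latency and count tuning in ~180 deg antiphase, additive
#' contrast-dependent latency shifts shared across the population,
#' trial-to-trial latency jitter with a shared (across cells) and a private
#' component, burst structure inside the 150 ms response window, and
#' occasional spike failures at low contrast.
#'
#' @param n_cells population size
#' @param latency_baseline_mean,latency_baseline_sd Gaussian of the latency
#'   baseline b, ms
#' @param latency_amplitude_mean,latency_amplitude_sd Gaussian of the latency
#'   modulation a, ms (draws truncated to b > a > 0)
#' @param count_baseline_mean,count_baseline_sd Gaussian of the count
#'   baseline, spikes
#' @param count_amplitude_mean,count_amplitude_sd Gaussian of the count
#'   modulation, spikes
#' @param contrast_levels percent Michelson contrasts available
#' @param contrast_shift additive latency shift per contrast level, ms
#'   (shared by all cells; 0 at the highest contrast)
#' @param failure_rate spike-failure probability per contrast level
#' @param jitter_shared_sd,jitter_private_sd latency jitter components, ms
#' @param count_noise_sd trial-to-trial count noise, spikes
#' @param burst_isi inter-spike interval inside a burst, ms
#' @param window_ms response window, ms
#' @return list of class \code{population_config}
#' @export
population_config <- function(n_cells = 8,
                              latency_baseline_mean = 80, latency_baseline_sd = 10,
                              latency_amplitude_mean = 25, latency_amplitude_sd = 5,
                              count_baseline_mean = 3.5, count_baseline_sd = 0.7,
                              count_amplitude_mean = 1.5, count_amplitude_sd = 0.4,
                              contrast_levels = c(23, 31, 39, 47),
                              contrast_shift = c(30, 18, 8, 0),
                              failure_rate = c(0.15, 0.1, 0.05, 0),
                              jitter_shared_sd = 2, jitter_private_sd = 2,
                              count_noise_sd = 1, burst_isi = 8,
                              window_ms = 150) {
  stopifnot(n_cells >= 1,
            length(contrast_shift) == length(contrast_levels),
            length(failure_rate) == length(contrast_levels),
            latency_baseline_sd > 0, latency_amplitude_sd > 0)
  structure(as.list(environment()), class = "population_config")
}

#' Sample a synthetic RGC population
#'
#' Phase offsets are uniform on [0, 360) deg; latency baseline/amplitude and
#' count baseline/amplitude are drawn independently from the configured
#' normals (truncated so b > a > 0 and counts stay non-negative). The count
#' tuning phase is the latency phase + 180 deg (strong stimuli: early spikes,
#' many spikes).
#'
#' @param config a [population_config()]
#' @param seed RNG seed
#' @return data frame of class \code{synthetic_population}: one row per cell
#' @export
sample_population <- function(config = population_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_cells
  draw_trunc <- function(n, mean, sd, lower, upper = Inf) {
    x <- rnorm(n, mean, sd)
    bad <- which(x <= lower | x >= upper)
    while (length(bad) > 0) {
      x[bad] <- rnorm(length(bad), mean, sd)
      bad <- which(x <= lower | x >= upper)
    }
    x
  }
  a <- draw_trunc(n, config$latency_amplitude_mean,
                  config$latency_amplitude_sd, 0)
  b <- numeric(n)
  for (i in seq_len(n))
    b[i] <- draw_trunc(1, config$latency_baseline_mean,
                       config$latency_baseline_sd, a[i])
  ca <- draw_trunc(n, config$count_amplitude_mean, config$count_amplitude_sd, 0)
  cb <- numeric(n)
  for (i in seq_len(n))
    cb[i] <- draw_trunc(1, config$count_baseline_mean,
                        config$count_baseline_sd, ca[i])
  pop <- data.frame(cell = seq_len(n),
                    latency_baseline = b, latency_amplitude = a,
                    phase_offset = runif(n, 0, 360),
                    count_baseline = cb, count_amplitude = ca)
  attr(pop, "config") <- config
  class(pop) <- c("synthetic_population", "data.frame")
  pop
}

#' Simulate one grating trial of a synthetic population
#'
#' Per cell, the first-spike latency is
#' b + shift(contrast) + a*cos(phi - phi0) + eta_shared + eta_private, with
#' the shared jitter drawn once per trial and common to all cells. The spike
#' count follows the antiphase cosine count tuning plus noise (rounded,
#' clipped at 0); later burst spikes follow at multiples of the burst ISI
#' inside the window. With the contrast's failure probability (or when the
#' drawn count is 0) the train is empty.
#'
#' @param population a [sample_population()] table
#' @param phase_index grating phase index 1--8
#' @param contrast one of the configured contrast levels
#' @param trial_id trial identifier
#' @param shared_jitter optional pre-drawn shared jitter, ms
#' @return a [trial_pattern()]
#' @export
simulate_trial <- function(population, phase_index, contrast, trial_id = 1L,
                           shared_jitter = NULL) {
  config <- attr(population, "config")
  stopifnot(phase_index %in% 1:8)
  ci <- match(contrast, config$contrast_levels)
  if (is.na(ci)) stop("contrast not in configured levels")
  phi <- (phase_index - 1) * 45
  if (is.null(shared_jitter))
    shared_jitter <- rnorm(1, 0, config$jitter_shared_sd)
  trains <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    p <- population[i, ]
    lat <- p$latency_baseline + config$contrast_shift[ci] +
      p$latency_amplitude * cos((phi - p$phase_offset) * pi / 180) +
      shared_jitter + rnorm(1, 0, config$jitter_private_sd)
    if (lat <= 0) lat <- 0.5
    cnt <- round(p$count_baseline +
                   p$count_amplitude * cos((phi - p$phase_offset - 180) * pi / 180) +
                   rnorm(1, 0, config$count_noise_sd))
    cnt <- max(0, cnt)
    fail <- runif(1) < config$failure_rate[ci]
    if (fail || cnt == 0 || lat > config$window_ms) {
      trains[[i]] <- numeric(0)
    } else {
      tt <- lat + (seq_len(cnt) - 1) * config$burst_isi
      trains[[i]] <- tt[tt <= config$window_ms]
    }
  }
  names(trains) <- as.character(population$cell)
  trial_pattern(trial_id, trains, phase_index = phase_index,
                contrast = contrast)
}

#' Simulate a full grating dataset
#'
#' @param population a [sample_population()] table
#' @param trials_per_condition trials per (phase, contrast) combination
#' @param contrasts subset of the configured contrast levels (default all)
#' @param phases phase indices to present (default 1:8)
#' @param seed RNG seed
#' @return a [spike_dataset()]
#' @export
simulate_dataset <- function(population, trials_per_condition = 15,
                             contrasts = NULL, phases = 1:8, seed = 1) {
  config <- attr(population, "config")
  if (is.null(contrasts)) contrasts <- config$contrast_levels
  set.seed(seed)
  trials <- list()
  tid <- 0L
  for (ct in contrasts) for (ph in phases) for (k in seq_len(trials_per_condition)) {
    tid <- tid + 1L
    trials[[tid]] <- simulate_trial(population, ph, ct, trial_id = tid)
  }
  # randomly interleave presentation order
  trials <- trials[sample.int(length(trials))]
  for (i in seq_along(trials)) trials[[i]]$trial_id <- i
  spike_dataset(trials, window_ms = config$window_ms,
                metadata = list(contrast_levels = contrasts))
}

#' Fraction of a Gaussian receptive field covered by dark grating bars
#'
#' The isotropic Gaussian receptive field is projected onto the grating's
#' modulation axis (a 1-D Gaussian with the same s.d.); D is the Gaussian
#' measure of the dark half-periods, summed over enough periods that the
#' omitted tails are below 1e-12. The grating has unit spatial period; a
#' point is dark where cos(2*pi*p - phi) < 0, p the coordinate along the
#' modulation axis. The orientation is canonicalized mod 180 deg, so
#' D is exactly invariant under psi -> psi + 180 deg.
#'
#' @param rf_center receptive-field center, c(x, y) in period units
#' @param sigma_rf receptive-field s.d., period units
#' @param phase_deg grating phase, degrees
#' @param orientation_deg grating orientation, degrees
#' @return dark fraction in [0, 1]
#' @export
dark_fraction <- function(rf_center, sigma_rf, phase_deg, orientation_deg) {
  stopifnot(sigma_rf > 0)
  psi <- (orientation_deg %% 180) * pi / 180
  p0 <- rf_center[1] * cos(psi) + rf_center[2] * sin(psi)
  phi <- phase_deg / 360
  # dark where cos(2*pi*(p - phi)) < 0: intervals (phi + 0.25 + k, phi + 0.75 + k)
  kmin <- floor(p0 - 8 * sigma_rf - phi - 0.75)
  kmax <- ceiling(p0 + 8 * sigma_rf - phi - 0.25)
  ks <- kmin:kmax
  lo <- phi + 0.25 + ks
  hi <- phi + 0.75 + ks
  d <- sum(stats::pnorm(hi, p0, sigma_rf) - stats::pnorm(lo, p0, sigma_rf))
  min(max(d, 0), 1)
}

#' Latency from dark coverage (orientation-model cells)
#'
#' latency = b + a*cos(pi*D) + noise: monotone decreasing in the dark
#' fraction D, so a fully darkened receptive field gives the fastest response
#' (b - a) and a fully brightened one the slowest (b + a), matching fast-Off
#' behavior. Non-positive results are clipped to 0.5 ms.
#'
#' @param D dark fraction in [0, 1] (vectorized)
#' @param baseline,amplitude cell tuning parameters, ms
#' @param noise_sd latency noise, ms (0 = deterministic)
#' @return latency, ms
#' @export
eq_latency_from_dark <- function(D, baseline, amplitude, noise_sd = 0) {
  stopifnot(all(D >= 0 & D <= 1))
  lat <- baseline + amplitude * cos(pi * D)
  if (noise_sd > 0) lat <- lat + rnorm(length(lat), 0, noise_sd)
  pmax(lat, 0.5)
}

#' Sample an orientation-model population
#'
#' 200 model ganglion cells by default: receptive-field centers uniform in a
#' circle (radius in grating periods), isotropic Gaussian profiles, latency
#' offset and modulation drawn from the same normals as the grating-indexed
#' population.
#'
#' @param n_cells population size
#' @param radius placement circle radius, period units
#' @param sigma_rf receptive-field s.d., period units
#' @param baseline_mean,baseline_sd latency offset Gaussian, ms
#' @param amplitude_mean,amplitude_sd latency modulation Gaussian, ms
#' @param seed RNG seed
#' @return data frame of class \code{orientation_population}
#' @export
sample_orientation_population <- function(n_cells = 200, radius = 1.5,
                                          sigma_rf = 0.12,
                                          baseline_mean = 80, baseline_sd = 10,
                                          amplitude_mean = 25, amplitude_sd = 5,
                                          seed = 1) {
  set.seed(seed)
  r <- radius * sqrt(runif(n_cells))
  th <- runif(n_cells, 0, 2 * pi)
  a <- rnorm(n_cells, amplitude_mean, amplitude_sd)
  while (any(a <= 0)) a[a <= 0] <- rnorm(sum(a <= 0), amplitude_mean, amplitude_sd)
  b <- rnorm(n_cells, baseline_mean, baseline_sd)
  while (any(b <= a)) b[b <= a] <- rnorm(sum(b <= a), baseline_mean, baseline_sd)
  pop <- data.frame(cell = seq_len(n_cells), x = r * cos(th), y = r * sin(th),
                    sigma_rf = sigma_rf, baseline = b, amplitude = a)
  class(pop) <- c("orientation_population", "data.frame")
  pop
}

#' Deterministic first-spike latencies for a grating stimulus
#'
#' @param population an [sample_orientation_population()]
#' @param phase_deg grating phase, degrees
#' @param orientation_deg grating orientation, degrees
#' @return one latency per cell, ms
#' @export
orientation_latencies <- function(population, phase_deg, orientation_deg) {
  D <- vapply(seq_len(nrow(population)), function(i)
    dark_fraction(c(population$x[i], population$y[i]), population$sigma_rf[i],
                  phase_deg, orientation_deg), numeric(1))
  eq_latency_from_dark(D, population$baseline, population$amplitude)
}

#' Hexagonal 7-cell schematic stimulus set
#'
#' Seven receptive fields on a hexagonal patch (center + 6 surround); a
#' stimulus is any binary dark/bright assignment, so there are 2^7 = 128
#' stimuli. Each cell fires one spike: early (t_early) if its field turns
#' dark, late (t_early + delta_t) if bright. The preferred grating is the
#' given binary pattern; its polarity inverse is the complement; the other
#' 126 patterns are tagged null. The default weight layout is signed and
#' symmetric: +1 on the preferred-dark cells, -1 on the preferred-bright
#' cells. With the default latency difference well above the PSP time to
#' peak, the preferred grating and its inverse produce the two highest peak
#' voltages over all 128 stimuli, the preferred one strictly highest.
#'
#' @param preferred binary 7-vector (1 = dark in the preferred grating);
#'   default is the horizontal middle-row grating c(0,0,1,1,1,0,0)
#' @param delta_t latency difference between bright and dark responses, ms
#' @param t_early latency of a darkened cell, ms
#' @return list(patterns = 128 [trial_pattern()]s with class_label 1 for the
#'   preferred grating and its inverse, weights = default layout,
#'   preferred_index, inverse_index)
#' @export
hex_schematic <- function(preferred = c(0, 0, 1, 1, 1, 0, 0), delta_t = 40,
                          t_early = 50) {
  stopifnot(length(preferred) == 7, all(preferred %in% c(0, 1)), delta_t > 0)
  n <- 7
  patterns <- vector("list", 2^n)
  codes <- matrix(0L, 2^n, n)
  for (s in 0:(2^n - 1)) {
    bits <- as.integer(bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L))
    codes[s + 1, ] <- bits
    times <- ifelse(bits == 1, t_early, t_early + delta_t)
    trains <- as.list(times)
    names(trains) <- as.character(seq_len(n))
    patterns[[s + 1]] <- trial_pattern(s + 1, trains)
  }
  pref_idx <- sum(preferred * 2^(0:(n - 1))) + 1
  inv_idx <- sum((1 - preferred) * 2^(0:(n - 1))) + 1
  for (s in seq_len(2^n))
    patterns[[s]]$class_label <- as.integer(s %in% c(pref_idx, inv_idx))
  weights <- ifelse(preferred == 1, 1, -1)
  list(patterns = patterns, codes = codes, weights = weights,
       preferred_index = pref_idx, inverse_index = inv_idx)
}
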