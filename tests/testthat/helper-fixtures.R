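# Dense-grid reference for the peak voltage: brute-force maximization of the
# PSP sum on a fine time grid (coarse scan, then local refinement around the
# coarse argmax). Independent of the event-driven code path.
grid_peak_voltage <- function(pattern, model, window_ms = 150, dt = 0.01) {
  eval_V <- function(g) {
    V <- numeric(length(g))
    for (i in seq_along(pattern$trains)) {
      tt <- pattern$trains[[i]]
      rr <- if (is.null(model$depression)) rep(1, length(tt)) else
        depression_factors(tt, model$depression$U, model$depression$tau_d)
      for (j in seq_along(tt))
        V <- V + model$weights[i] * rr[j] * psp_kernel(g - tt[j], model$kernel)
    }
    V
  }
  # spike times are kinks of V and legitimate maximum locations: include them
  g <- sort(c(seq(dt, window_ms + 5 * model$kernel$tau_m, by = dt),
              unlist(pattern$trains, use.names = FALSE)))
  V <- eval_V(g)
  # refine every near-maximal local peak (the global peak can be a whisker
  # above a competing one elsewhere)
  n <- length(V)
  locmax <- which(V >= c(-Inf, V[-n]) & V >= c(V[-1], -Inf) &
                    V > max(V) - 1e-3)
  best_v <- max(V); best_t <- g[which.max(V)]
  for (i in locmax) {
    gf <- seq(max(g[i] - 2 * dt, dt / 100), g[i] + 2 * dt, by = dt / 1000)
    Vf <- eval_V(gf)
    j <- which.max(Vf)
    if (Vf[j] > best_v) { best_v <- Vf[j]; best_t <- gf[j] }
  }
  list(v_max = max(best_v, 0), t_vmax = best_t)
}

# Random multi-afferent trial pattern.
random_pattern <- function(n_aff = 4, max_spikes = 5, window = 150) {
  trains <- lapply(seq_len(n_aff), function(i)
    sort(runif(sample.int(max_spikes + 1, 1) - 1, 0, window)))
  names(trains) <- as.character(seq_len(n_aff))
  trial_pattern(1, trains)
}

# Two-afferent synchrony-vs-asynchrony task: targets fire coincidently at a
# random onset, nulls 40 ms apart (both orders).
synchrony_dataset <- function(n_per_class = 12, gap = 40, seed = 7) {
  set.seed(seed)
  trials <- list(); labels <- integer(0)
  for (i in seq_len(2 * n_per_class)) {
    t0 <- runif(1, 30, 80)
    if (i <= n_per_class) {
      tr <- list(`1` = t0, `2` = t0); labels <- c(labels, 1L)
    } else {
      tr <- if (i %% 2 == 0) list(`1` = t0, `2` = t0 + gap) else
        list(`1` = t0 + gap, `2` = t0)
      labels <- c(labels, 0L)
    }
    trials[[i]] <- trial_pattern(i, tr)
  }
  list(dataset = spike_dataset(trials), labels = labels)
}

# Small single-contrast synthetic population dataset shared across tests.
demo_population <- function(n_cells = 8, seed = 42, ...) {
  sample_population(population_config(n_cells = n_cells, ...), seed = seed)
}
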