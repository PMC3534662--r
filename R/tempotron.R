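#' Postsynaptic-potential kernel
#'
#' The tempotron integrates each input spike as a stereotyped PSP
#' \deqn{K(t) = V_0 (e^{-t/\tau_m} - e^{-t/\tau_s}), \quad t > 0,}
#' with membrane time constant \eqn{\tau_m}, synaptic-current decay
#' \eqn{\tau_s < \tau_m}, and \eqn{V_0} fixed so the kernel peak equals 1
#' (PSP amplitudes are then the synaptic efficacies themselves).
#'
#' @param tau_m membrane time constant, ms
#' @param tau_s synaptic decay time constant, ms (default \code{tau_m/4})
#' @return object of class \code{psp_kernel} with fields \code{tau_m},
#'   \code{tau_s}, \code{v0}, \code{t_peak}
#' @export
psp_kernel_params <- function(tau_m = 10, tau_s = tau_m / 4) {
  if (!(tau_m > tau_s && tau_s > 0))
    stop("kernel requires tau_m > tau_s > 0")
  t_peak <- tau_m * tau_s / (tau_m - tau_s) * log(tau_m / tau_s)
  structure(list(tau_m = tau_m, tau_s = tau_s,
                 v0 = cpp_kernel_v0(tau_m, tau_s), t_peak = t_peak),
            class = "psp_kernel")
}

#' Evaluate the PSP kernel
#'
#' @param t times since the presynaptic spike, ms (K = 0 for t <= 0)
#' @param kernel a [psp_kernel_params()] object
#' @return dimensionless voltages, unit peak
#' @export
psp_kernel <- function(t, kernel = psp_kernel_params()) {
  cpp_kernel(as.numeric(t), kernel$tau_m, kernel$tau_s)
}

#' Tempotron readout model
#'
#' A current-based leaky integrate-and-fire neuron whose voltage is the
#' weighted sum of unit-peak PSPs from all afferent spikes,
#' \deqn{V(t) = \sum_i \omega_i \sum_j R_{ij} K(t - t_{ij}),}
#' and which classifies a trial as "target" by firing (peak voltage reaching
#' the threshold) or "null" by staying silent. \eqn{R_{ij} = 1} for static
#' synapses; with short-term depression enabled the factors follow the
#' resource-depletion dynamics of [depression_factors()].
#'
#' @param weights signed synaptic efficacies, one per afferent, in units of
#'   the firing threshold
#' @param threshold firing threshold (default 1)
#' @param kernel a [psp_kernel_params()]
#' @param depression NULL for static synapses, else
#'   \code{list(U = utilization fraction in (0,1], tau_d = recovery ms)}
#' @return object of class \code{tempotron}
#' @export
tempotron_model <- function(weights, threshold = 1,
                            kernel = psp_kernel_params(), depression = NULL) {
  stopifnot(threshold > 0, is.numeric(weights))
  if (!is.null(depression)) {
    stopifnot(depression$U > 0, depression$U <= 1, depression$tau_d > 0)
  }
  structure(list(weights = as.numeric(weights), threshold = threshold,
                 kernel = kernel, depression = depression),
            class = "tempotron")
}

#' @export
print.tempotron <- function(x, ...) {
  cat(sprintf("tempotron: %d afferents, theta = %g, tau_m = %g ms, tau_s = %g ms%s\n",
              length(x$weights), x$threshold, x$kernel$tau_m, x$kernel$tau_s,
              if (is.null(x$depression)) "" else
                sprintf(", depression (U = %g, tau_d = %g ms)",
                        x$depression$U, x$depression$tau_d)))
  invisible(x)
}

#' Short-term synaptic depression factors
#'
#' Tsodyks-style depression-only dynamics: each spike consumes a fraction
#' \code{U} of the synaptic resources, which recover exponentially with time
#' constant \code{tau_d}. With \eqn{R_1 = 1},
#' \deqn{R_{j+1} = 1 - (1 - (1-U) R_j)\, e^{-(t_{j+1}-t_j)/\tau_D}.}
#' The first spike of a train is always transmitted at full amplitude.
#'
#' @param times sorted spike times of one afferent, ms
#' @param U utilization fraction in (0, 1]
#' @param tau_d recovery time constant, ms
#' @return per-spike scale factors in [0, 1]
#' @export
depression_factors <- function(times, U, tau_d) {
  stopifnot(U > 0, U <= 1, tau_d > 0)
  n <- length(times)
  if (n == 0) return(numeric(0))
  if (is.unsorted(times, strictly = TRUE) && n > 1)
    stop("spike times must be sorted strictly increasing")
  R <- numeric(n)
  R[1] <- 1
  for (j in seq_len(n - 1)) {
    R[j + 1] <- 1 - (1 - (1 - U) * R[j]) * exp(-(times[j + 1] - times[j]) / tau_d)
  }
  R
}

# Assemble the (times, amplitudes) event list of one trial under a model.
pattern_events <- function(pattern, model) {
  trains <- pattern$trains
  stopifnot(length(trains) == length(model$weights))
  tt <- unlist(trains, use.names = FALSE)
  w <- rep(model$weights, lengths(trains))
  rr <- if (is.null(model$depression)) rep(1, length(tt)) else
    unlist(lapply(trains, function(x)
      depression_factors(x, model$depression$U, model$depression$tau_d)),
      use.names = FALSE)
  o <- order(tt)
  list(times = tt[o], amp = (w * rr)[o], rfac = rr[o])
}

#' Peak postsynaptic voltage of a trial
#'
#' Computes the global maximum of the voltage trace over
#' \code{(0, window + 5 tau_m]} exactly, by closed-form maximization of the
#' two-exponential voltage within each inter-spike interval (event-driven; no
#' time discretization).
#'
#' @param pattern a [trial_pattern()] with one train per model afferent
#' @param model a [tempotron_model()]
#' @param window_ms response window, ms
#' @return list with \code{v_max} (dimensionless) and \code{t_vmax} (ms; NA
#'   when the pattern has no spikes)
#' @export
peak_voltage <- function(pattern, model, window_ms = 150) {
  ev <- pattern_events(pattern, model)
  if (length(ev$times) == 0) return(list(v_max = 0, t_vmax = NA_real_))
  tend <- window_ms + 5 * model$kernel$tau_m
  r <- cpp_peak_voltage(ev$times, ev$amp, model$kernel$tau_m,
                        model$kernel$tau_s, tend)
  list(v_max = r[1], t_vmax = r[2])
}

#' Classify a trial pattern
#'
#' The tempotron fires iff the peak voltage reaches the threshold; the output
#' spike time is the earliest threshold crossing.
#'
#' @inheritParams peak_voltage
#' @return list with \code{fired} (logical) and \code{spike_time} (ms or NA)
#' @export
classify <- function(pattern, model, window_ms = 150) {
  ev <- pattern_events(pattern, model)
  tend <- window_ms + 5 * model$kernel$tau_m
  if (length(ev$times) == 0) return(list(fired = FALSE, spike_time = NA_real_))
  r <- cpp_peak_voltage(ev$times, ev$amp, model$kernel$tau_m,
                        model$kernel$tau_s, tend)
  if (r[1] >= model$threshold) {
    ct <- cpp_first_crossing(ev$times, ev$amp, model$kernel$tau_m,
                             model$kernel$tau_s, tend, model$threshold)
    list(fired = TRUE, spike_time = ct)
  } else list(fired = FALSE, spike_time = NA_real_)
}

#' Learning-rule state
#'
#' @param step_size lambda, maximal synaptic update per input spike
#' @param momentum mu in [0, 1)
#' @param velocity per-weight running update (defaults to zeros)
#' @param n_weights weight count used when velocity is not given
#' @return object of class \code{learn_state}
#' @export
learn_state <- function(step_size, momentum = 0.9, velocity = NULL,
                        n_weights = NULL) {
  stopifnot(momentum >= 0, momentum < 1)
  if (is.null(velocity)) velocity <- numeric(n_weights)
  structure(list(step_size = step_size, momentum = momentum,
                 velocity = velocity), class = "learn_state")
}

#' One error-driven tempotron learning step
#'
#' No change on a correct trial. On a miss (silent target) each efficacy
#' grows by \eqn{\lambda \sum_{t_{ij} < t_{max}} R_{ij} K(t_{max} - t_{ij})};
#' on a false alarm (firing null) the same amount is subtracted. A momentum
#' term accumulates the updates:
#' velocity <- mu * velocity + dw; weights <- weights + velocity.
#'
#' @param pattern a [trial_pattern()]
#' @param label 1 = target, 0 = null
#' @param model a [tempotron_model()]
#' @param state a [learn_state()]
#' @param window_ms response window, ms
#' @return list(model, state), updated
#' @export
learn_step <- function(pattern, label, model, state, window_ms = 150) {
  pv <- peak_voltage(pattern, model, window_ms)
  fired <- pv$v_max >= model$threshold
  if ((label == 1) == fired) return(list(model = model, state = state))
  if (!is.finite(pv$t_vmax)) return(list(model = model, state = state))
  ev <- pattern_events(pattern, model)
  kv <- psp_kernel(pv$t_vmax - ev$times, model$kernel)
  aff <- rep(seq_along(model$weights), lengths(pattern$trains))
  aff <- aff[order(unlist(pattern$trains, use.names = FALSE))]
  dw <- numeric(length(model$weights))
  contrib <- ev$rfac * kv
  for (j in seq_along(contrib)) dw[aff[j]] <- dw[aff[j]] + contrib[j]
  sign <- if (label == 1) 1 else -1
  state$velocity <- state$momentum * state$velocity +
    sign * state$step_size * dw
  model$weights <- model$weights + state$velocity
  list(model = model, state = state)
}

# Centered moving average with partial windows at the edges; window w spans
# indices [i - floor((w-1)/2), i + ceiling((w-1)/2)] clipped to the range.
smooth_error_curve <- function(x, window = 50) {
  n <- length(x)
  lo <- pmax(1, seq_len(n) - floor((window - 1) / 2))
  hi <- pmin(n, seq_len(n) + ceiling((window - 1) / 2))
  cs <- c(0, cumsum(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Train a tempotron on a labeled dataset
#'
#' Cycles over all trials in a fixed seeded random order for \code{cycles}
#' cycles, applying the error-driven rule with momentum. The per-cycle
#' misclassification fraction is smoothed by a centered moving average
#' (default 50 cycles) and the returned model is the weight snapshot at the
#' smoothed minimum (earliest cycle on ties).
#'
#' @param dataset a [spike_dataset()]
#' @param labels per-trial binary labels (1 target / 0 null)
#' @param step_size lambda
#' @param momentum mu
#' @param cycles learning cycles
#' @param smooth_window smoothing window, cycles
#' @param init_sd Gaussian s.d. of initial weights
#' @param seed RNG seed for initialization and trial order
#' @param kernel a [psp_kernel_params()]
#' @param depression NULL or list(U, tau_d)
#' @param threshold firing threshold
#' @param margin training margin (targets must exceed theta*(1+margin), nulls
#'   stay below theta*(1-margin) to count as correct during training)
#' @return list with \code{model} (best snapshot), \code{error_curve},
#'   \code{smoothed}, \code{best_cycle}, \code{best_error}, \code{final_model}
#' @export
train_tempotron <- function(dataset, labels, step_size = 1e-3, momentum = 0.9,
                            cycles = 2000, smooth_window = 50, init_sd = 0.05,
                            seed = 1, kernel = psp_kernel_params(),
                            depression = NULL, threshold = 1, margin = 0) {
  stopifnot(length(labels) == length(dataset$trials))
  if (cycles < 1) stop("cycles must be >= 1")
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1)
    stop("need at least one target and one null trial")
  fl <- flatten_dataset(dataset, depression)
  nw <- length(dataset$afferents)
  set.seed(seed)
  w0 <- rnorm(nw, 0, init_sd)
  ord <- sample.int(length(dataset$trials)) - 1L
  tend <- dataset$window_ms + 5 * kernel$tau_m
  fit <- cpp_train(fl$tim, fl$aff, fl$rfac, fl$ptr, as.integer(labels), ord,
                   w0, threshold, kernel$tau_m, kernel$tau_s, tend,
                   step_size, -1, momentum, as.integer(cycles),
                   rep(margin, length(labels)), TRUE, 0L)
  sm <- smooth_error_curve(fit$error_curve, smooth_window)
  best <- which.min(sm)
  list(model = tempotron_model(fit$snapshots[best, ], threshold, kernel, depression),
       error_curve = fit$error_curve, smoothed = sm, best_cycle = best,
       best_error = sm[best],
       final_model = tempotron_model(fit$weights, threshold, kernel, depression))
}

#' Margin-free classification error of a model on a dataset
#'
#' @param dataset a [spike_dataset()]
#' @param labels binary labels
#' @param model a [tempotron_model()]
#' @return fraction of misclassified trials
#' @export
evaluate_tempotron <- function(dataset, labels, model) {
  fl <- flatten_dataset(dataset, model$depression)
  tend <- dataset$window_ms + 5 * model$kernel$tau_m
  ev <- cpp_eval_batch(fl$tim, fl$aff, fl$rfac, fl$ptr, model$weights,
                       model$threshold, model$kernel$tau_m,
                       model$kernel$tau_s, tend)
  fired <- ev[, 1] >= model$threshold
  mean(fired != (labels == 1))
}
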