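#' Per-afferent spike counts
#'
#' @param pattern a [trial_pattern()]
#' @param window count spikes with time <= window, ms
#' @return integer vector, one count per afferent
#' @export
spike_counts <- function(pattern, window = 150) {
  stopifnot(window > 0)
  vapply(pattern$trains, function(tt) sum(tt <= window), integer(1))
}

count_matrix <- function(dataset, window) {
  t(vapply(dataset$trials, spike_counts, integer(length(dataset$afferents)),
           window = window))
}

#' Train a spike-count perceptron
#'
#' The classic perceptron benchmark: each afferent contributes its spike
#' count inside a fixed window (150 ms default; 80 ms is the optimized
#' boundary-task preset) and the decision thresholds the weighted count sum
#' plus a trained bias. Training follows the same protocol as the tempotron:
#' seeded random trial order, 2000 cycles, centered 50-cycle smoothing of the
#' per-cycle error, snapshot at the smoothed minimum.
#'
#' @param dataset a [spike_dataset()]
#' @param labels binary labels (1 target / 0 null)
#' @param step_size learning rate
#' @param cycles,smooth_window,init_sd,seed training protocol controls
#' @param count_window counting window, ms
#' @return list with \code{model} (class \code{perceptron}),
#'   \code{error_curve}, \code{smoothed}, \code{best_cycle}, \code{best_error}
#' @export
perceptron_fit <- function(dataset, labels, step_size = 0.01, cycles = 2000,
                           smooth_window = 50, init_sd = 0.05, seed = 1,
                           count_window = 150) {
  stopifnot(length(labels) == length(dataset$trials))
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1)
    stop("need at least one target and one null trial")
  X <- count_matrix(dataset, count_window)
  y <- ifelse(labels == 1, 1, -1)
  set.seed(seed)
  w <- rnorm(ncol(X), 0, init_sd)
  b <- rnorm(1, 0, init_sd)
  ord <- sample.int(nrow(X))
  nerrs <- numeric(cycles)
  snaps <- matrix(0, cycles, ncol(X) + 1)
  for (cyc in seq_len(cycles)) {
    nerr <- 0
    for (i in ord) {
      pred <- if (sum(w * X[i, ]) + b >= 0) 1 else -1
      if (pred != y[i]) {
        nerr <- nerr + 1
        w <- w + step_size * y[i] * X[i, ]
        b <- b + step_size * y[i]
      }
    }
    nerrs[cyc] <- nerr / nrow(X)
    snaps[cyc, ] <- c(w, b)
  }
  sm <- smooth_error_curve(nerrs, smooth_window)
  best <- which.min(sm)
  model <- structure(list(weights = snaps[best, seq_len(ncol(X))],
                          bias = snaps[best, ncol(X) + 1],
                          count_window = count_window),
                     class = "perceptron")
  list(model = model, error_curve = nerrs, smoothed = sm,
       best_cycle = best, best_error = sm[best])
}

#' @export
predict.perceptron <- function(object, dataset, ...) {
  X <- count_matrix(dataset, object$count_window)
  as.integer(X %*% object$weights + object$bias >= 0)
}

# Ranked (time, afferent) pairs of a trial's earliest spikes.
first_spike_table <- function(pattern) {
  ft <- vapply(pattern$trains, function(tt)
    if (length(tt) > 0) tt[1] else NA_real_, numeric(1))
  ft
}

#' Temporal winner-take-all decision
#'
#' k = 1: the class label of the earliest-firing afferent wins. k = 3:
#' majority label among the afferents owning the three earliest spikes in the
#' population (an afferent may own several of them through a burst). Exact
#' latency ties resolve to the lowest afferent index; a spikeless trial votes
#' for the null class.
#'
#' @param pattern a [trial_pattern()]
#' @param model a \code{twta} model: list(labels = per-afferent 0/1, k)
#' @return 0/1 decision
#' @export
twta_decide <- function(pattern, model) {
  tt <- unlist(pattern$trains, use.names = FALSE)
  aff <- rep(seq_along(pattern$trains), lengths(pattern$trains))
  if (length(tt) == 0) return(0L)
  o <- order(tt, aff)
  k <- min(model$k, length(tt))
  votes <- model$labels[aff[o[seq_len(k)]]]
  as.integer(mean(votes) > 0.5 ||
               (mean(votes) == 0.5 && votes[1] == 1))
}

#' Fit a temporal winner-take-all decoder by exhaustive labeling search
#'
#' Enumerates all 2^N afferent labelings and returns the one minimizing the
#' training error (first in lexicographic order on ties).
#'
#' @param dataset a [spike_dataset()]
#' @param labels binary trial labels
#' @param k number of earliest spikes considered (1 or 3)
#' @return list(model = list(labels, k), error)
#' @export
twta_fit <- function(dataset, labels, k = 1) {
  n <- length(dataset$afferents)
  if (n > 25) stop("exhaustive labeling search limited to <= 25 afferents; ",
                   "reduce the population")
  # precompute the owners of the k earliest spikes per trial
  owners <- lapply(dataset$trials, function(tr) {
    tt <- unlist(tr$trains, use.names = FALSE)
    aff <- rep(seq_along(tr$trains), lengths(tr$trains))
    if (length(tt) == 0) return(integer(0))
    o <- order(tt, aff)
    aff[o[seq_len(min(k, length(tt)))]]
  })
  best <- NULL; best_err <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    dec <- vapply(owners, function(ow) {
      if (length(ow) == 0) return(0L)
      v <- lab[ow]
      as.integer(mean(v) > 0.5 || (mean(v) == 0.5 && v[1] == 1))
    }, integer(1))
    err <- mean(dec != labels)
    if (err < best_err) { best_err <- err; best <- lab }
  }
  list(model = structure(list(labels = best, k = k), class = "twta"),
       error = best_err)
}

#' Rank-order decoder potential and decision
#'
#' Each afferent contributes at most one spike; ranks r_i = 0, 1, ... are
#' assigned by ascending first-spike latency (ties broken by afferent index,
#' silent afferents contribute nothing). The potential is
#' \eqn{\sum_i \omega_i m^{r_i}} with desensitization factor m in (0, 1]; the
#' decoder fires when the potential reaches its threshold.
#'
#' @param pattern a [trial_pattern()] (restrict to first spikes upstream)
#' @param model a \code{rank_order} model: list(weights, attenuation,
#'   threshold)
#' @return list(potential, decision)
#' @export
rank_decode <- function(pattern, model) {
  ft <- first_spike_table(pattern)
  fired <- which(!is.na(ft))
  if (length(fired) == 0) return(list(potential = 0, decision = 0L))
  r <- rank(ft[fired], ties.method = "first") - 1
  pot <- sum(model$weights[fired] * model$attenuation^r)
  list(potential = pot, decision = as.integer(pot >= model$threshold))
}

rank_potentials <- function(dataset, weights, m) {
  vapply(dataset$trials, function(tr) {
    ft <- first_spike_table(tr)
    fired <- which(!is.na(ft))
    if (length(fired) == 0) return(0)
    r <- rank(ft[fired], ties.method = "first") - 1
    sum(weights[fired] * m^r)
  }, numeric(1))
}

#' Fit a rank-order decoder
#'
#' For each attenuation value m, each synaptic weight is set to the
#' afferent's average attenuation factor over the target patterns
#' (\eqn{\omega_i = \langle m^{r_i} \rangle_{target}}), and the firing
#' threshold is then optimized over quantiles of the training potentials;
#' returns the (m, threshold) pair minimizing training error.
#'
#' @param dataset a [spike_dataset()]
#' @param labels binary trial labels
#' @param m_grid attenuation grid
#' @param n_threshold number of threshold quantiles tried
#' @return list(model, error)
#' @export
rank_fit <- function(dataset, labels,
                     m_grid = c(seq(0.5, 0.95, by = 0.05), 0.99),
                     n_threshold = 100) {
  stopifnot(length(m_grid) > 0)
  best <- NULL; best_err <- Inf
  for (m in m_grid) {
    # target-average weight rule
    wsum <- numeric(length(dataset$afferents))
    wn <- numeric(length(dataset$afferents))
    for (i in which(labels == 1)) {
      ft <- first_spike_table(dataset$trials[[i]])
      fired <- which(!is.na(ft))
      if (length(fired) == 0) next
      r <- rank(ft[fired], ties.method = "first") - 1
      wsum[fired] <- wsum[fired] + m^r
      wn[fired] <- wn[fired] + 1
    }
    w <- ifelse(wn > 0, wsum / pmax(wn, 1), 0)
    pot <- rank_potentials(dataset, w, m)
    ths <- unique(quantile(pot, probs = seq(0, 1, length.out = n_threshold),
                           names = FALSE))
    for (th in ths) {
      err <- mean(as.integer(pot >= th) != labels)
      if (err < best_err) {
        best_err <- err
        best <- structure(list(weights = w, attenuation = m, threshold = th),
                          class = "rank_order")
      }
    }
  }
  list(model = best, error = best_err)
}
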