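#' Fit a cosine tuning curve to single-trial responses
#'
#' Fits f(phi) = b + a*cos(phi - phi0) by least squares on single trials. The
#' fit is solved exactly through the linearization
#' b + alpha*cos(phi) + beta*sin(phi) (the same model class, convex), with
#' a = sqrt(alpha^2 + beta^2) and phi0 = atan2(beta, alpha). For latency
#' tuning, drop spikeless trials before calling. r2 values follow the plain
#' 1 - SS_res/SS_tot definition and are not clipped at zero.
#'
#' @param phase_deg per-trial stimulus phase, degrees
#' @param value per-trial response (latency in ms or spike count)
#' @param kind "latency" or "count" (annotation only)
#' @return object of class \code{cosine_fit}: baseline, amplitude,
#'   phase_offset (degrees in [0, 360)), r2_single, r2_mean, degenerate flag
#' @export
fit_cosine <- function(phase_deg, value, kind = c("latency", "count")) {
  kind <- match.arg(kind)
  ok <- is.finite(phase_deg) & is.finite(value)
  phase_deg <- phase_deg[ok]; value <- value[ok]
  if (length(unique(phase_deg)) < 3)
    stop("need responses at >= 3 distinct phases")
  rad <- phase_deg * pi / 180
  degenerate <- FALSE
  if (stats::var(value) == 0) {
    b <- value[1]; a <- 0; phi0 <- 0
    degenerate <- TRUE
  } else {
    co <- stats::coef(stats::lm(value ~ cos(rad) + sin(rad)))
    b <- co[1]
    a <- sqrt(co[2]^2 + co[3]^2)
    phi0 <- atan2(co[3], co[2]) * 180 / pi
  }
  phi0 <- phi0 %% 360
  pred <- b + a * cos(rad - phi0 * pi / 180)
  ss_res <- sum((value - pred)^2)
  ss_tot <- sum((value - mean(value))^2)
  r2s <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res == 0) 1 else -Inf
  fit <- structure(list(baseline = unname(b), amplitude = unname(a),
                        phase_offset = unname(phi0), kind = kind,
                        r2_single = r2s, r2_mean = NA_real_,
                        degenerate = degenerate),
                   class = "cosine_fit")
  fit$r2_mean <- r2_of_means(fit, phase_deg, value)
  fit
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf("cosine fit (%s): b = %.3f, a = %.3f, phi0 = %.1f deg, r2(single) = %.3f, r2(mean) = %.3f\n",
              x$kind, x$baseline, x$amplitude, x$phase_offset,
              x$r2_single, x$r2_mean))
  invisible(x)
}

#' Coefficient of determination for per-phase mean responses
#'
#' Uses the parameters fitted on single trials to predict the response at
#' each phase and evaluates 1 - sum_i (mean_i - pred_i)^2 /
#' sum_i (mean_i - grand mean)^2 over the per-phase means: the fraction of
#' variance of the mean tuning curve explained by the single-trial fit.
#'
#' @param fit a [fit_cosine()] result
#' @param phase_deg,value the responses the fit was computed from
#' @return a fraction (can be negative; not clipped)
#' @export
r2_of_means <- function(fit, phase_deg, value) {
  ok <- is.finite(phase_deg) & is.finite(value)
  phase_deg <- phase_deg[ok]; value <- value[ok]
  phases <- sort(unique(phase_deg))
  if (length(phases) < 2) stop("need >= 2 distinct phases")
  mn <- vapply(phases, function(p) mean(value[phase_deg == p]), numeric(1))
  pred <- fit$baseline +
    fit$amplitude * cos((phases - fit$phase_offset) * pi / 180)
  ss_tot <- sum((mn - mean(mn))^2)
  if (ss_tot == 0) return(if (sum((mn - pred)^2) == 0) 1 else -Inf)
  1 - sum((mn - pred)^2) / ss_tot
}

#' Per-stimulus latency correlation of a simultaneously recorded cell pair
#'
#' Pearson correlation of first-spike latencies within each stimulus
#' condition; trials where either cell failed to spike are dropped, and
#' conditions with < 3 complete pairs or zero variance in either cell are
#' skipped.
#'
#' @param lat_a,lat_b per-trial latencies of the two cells (NA = failure)
#' @param stimulus per-trial stimulus condition id
#' @return list(per_stimulus = named r vector, mean_r)
#' @export
latency_correlation <- function(lat_a, lat_b, stimulus) {
  stopifnot(length(lat_a) == length(lat_b),
            length(lat_a) == length(stimulus))
  out <- c()
  for (s in sort(unique(stimulus))) {
    idx <- stimulus == s & is.finite(lat_a) & is.finite(lat_b)
    if (sum(idx) < 3) next
    if (stats::sd(lat_a[idx]) == 0 || stats::sd(lat_b[idx]) == 0) next
    out[as.character(s)] <- stats::cor(lat_a[idx], lat_b[idx])
  }
  list(per_stimulus = out,
       mean_r = if (length(out) > 0) mean(out) else NA_real_)
}

#' Rotate one cell's trials within each stimulus condition
#'
#' The trial-shift control: within each stimulus, cell B's trial order is
#' rotated by \code{by} so that the pairing with cell A crosses trials,
#' destroying shared trial-to-trial jitter while preserving both marginals.
#' Conditions with a single trial are left unshifted.
#'
#' @param lat_b per-trial latencies of cell B
#' @param stimulus per-trial stimulus condition id
#' @param by rotation amount, trials
#' @return shifted latency vector, same length
#' @export
shift_trials <- function(lat_b, stimulus, by = 1) {
  out <- lat_b
  for (s in unique(stimulus)) {
    idx <- which(stimulus == s)
    n <- length(idx)
    if (n < 2) next
    out[idx] <- lat_b[idx][((seq_len(n) - 1 + by) %% n) + 1]
  }
  out
}

#' Tuning-curve fits for every cell of a dataset
#'
#' Convenience wrapper: fits latency and count cosine tuning per afferent at
#' one contrast level. Latency fits use only trials where the cell spiked.
#'
#' @param dataset a [spike_dataset()]
#' @param contrast restrict to this contrast (NULL = all trials)
#' @param phase_step degrees per phase index (45 for the 8-grating set)
#' @return data frame: one row per cell x measure with the fit parameters
#' @export
fit_population_tuning <- function(dataset, contrast = NULL, phase_step = 45) {
  trials <- dataset$trials
  if (!is.null(contrast))
    trials <- Filter(function(t) isTRUE(t$contrast == contrast), trials)
  phases <- vapply(trials, function(t)
    (as.numeric(t$phase_index) - 1) * phase_step, numeric(1))
  rows <- list()
  for (ci in seq_along(dataset$afferents)) {
    lat <- vapply(trials, function(t) {
      tt <- t$trains[[ci]]
      if (length(tt) > 0) tt[1] else NA_real_
    }, numeric(1))
    cnt <- vapply(trials, function(t) length(t$trains[[ci]]), numeric(1))
    for (meas in c("latency", "count")) {
      v <- if (meas == "latency") lat else cnt
      f <- fit_cosine(phases, v, kind = meas)
      rows[[length(rows) + 1]] <- data.frame(
        cell = dataset$afferents[ci], measure = meas,
        baseline = f$baseline, amplitude = f$amplitude,
        phase_offset = f$phase_offset, r2_single = f$r2_single,
        r2_mean = f$r2_mean)
    }
  }
  do.call(rbind, rows)
}
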