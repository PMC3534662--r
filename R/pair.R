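#' Peak voltage as a function of relative latency (two afferents)
#'
#' For two afferents firing one spike each at relative latency
#' dt = t2 - t1, returns the peak of w1*K(t) + w2*K(t - dt). At dt = 0 the
#' peak is w1 + w2; as |dt| grows it approaches the larger efficacy. The
#' mapping is non-monotonic in general, which is what lets a single readout
#' neuron dissect the latency axis into three regions.
#'
#' @param dt relative latency t2 - t1, ms (vectorized)
#' @param w1,w2 synaptic efficacies; at least one excitatory, sum positive
#' @param kernel a [psp_kernel_params()]
#' @return peak voltages, same length as dt
#' @export
vmax_of_dt <- function(dt, w1, w2, kernel = psp_kernel_params()) {
  if (!(w1 + w2 > 0 && max(w1, w2) > 0))
    stop("requires at least one excitatory weight and a positive sum")
  cpp_vmax_pair(as.numeric(dt), w1, w2, kernel$tau_m, kernel$tau_s)
}

#' Decision boundaries on relative latency for fixed weights
#'
#' Solves vmax_of_dt(dt) = theta for the two boundary latencies, one per
#' firing order (dt_minus < 0 < dt_plus for purely excitatory weights with
#' max(w) < theta < w1 + w2). Roots are bracketed on a scan grid and refined
#' to 1e-6 ms. When the threshold is outside the attainable voltage range on
#' a side, that boundary is NA.
#'
#' @param w1,w2 efficacies
#' @param theta firing threshold
#' @param kernel a [psp_kernel_params()]
#' @param dt_max scan range, ms
#' @return list(dt_minus, dt_plus)
#' @export
solve_dt_boundaries <- function(w1, w2, theta, kernel = psp_kernel_params(),
                                dt_max = 60 * kernel$tau_m) {
  f <- function(d) vmax_of_dt(d, w1, w2, kernel) - theta
  one_side <- function(sgn) {
    grid <- sgn * seq(0, dt_max, length.out = 2001)
    fv <- f(grid)
    ch <- which(fv[-1] * fv[-length(fv)] < 0)
    if (length(ch) == 0) {
      z <- which(fv == 0)
      return(if (length(z) > 0) grid[z[1]] else NA_real_)
    }
    i <- ch[1]
    r <- stats::uniroot(f, lower = min(grid[i], grid[i + 1]),
                        upper = max(grid[i], grid[i + 1]), tol = 1e-9)
    r$root
  }
  list(dt_minus = one_side(-1), dt_plus = one_side(1))
}

#' Weights realizing prescribed decision boundaries
#'
#' Solves the two-equation system vmax(dt_minus) = vmax(dt_plus) = theta for
#' the synaptic weights (w1, w2) by damped Newton iteration with numerical
#' Jacobian, starting from the symmetric purely excitatory solution and, if
#' that fails, from mixed-sign starts. The returned solution is classified as
#' regime "++" (both weights positive; the neuron fires inside
#' [dt_minus, dt_plus]) or "+-" / "-+" (mixed signs; fires outside).
#'
#' @param dt_minus,dt_plus requested boundaries, dt_minus < dt_plus, ms
#' @param theta firing threshold
#' @param kernel a [psp_kernel_params()]
#' @param tol residual tolerance on the boundary equations
#' @return list(dt_minus, dt_plus, w1, w2, regime, fires_inside, residual)
#' @export
weights_for_boundaries <- function(dt_minus, dt_plus, theta = 1,
                                   kernel = psp_kernel_params(), tol = 1e-8) {
  if (!(dt_minus < dt_plus)) stop("need dt_minus < dt_plus")
  resid <- function(w) {
    if (w[1] + w[2] <= 0 || max(w) <= 0) return(c(1e6, 1e6))
    cpp_vmax_pair(c(dt_minus, dt_plus), w[1], w[2],
                  kernel$tau_m, kernel$tau_s) - theta
  }
  newton <- function(w) {
    for (it in 1:200) {
      r <- resid(w)
      if (max(abs(r)) < tol) return(list(w = w, ok = TRUE))
      h <- 1e-6 * pmax(abs(w), 1)
      J <- matrix(0, 2, 2)
      for (k in 1:2) {
        wp <- w; wp[k] <- wp[k] + h[k]
        J[, k] <- (resid(wp) - r) / h[k]
      }
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(list(w = w, ok = FALSE))
      lam <- 1
      repeat {
        wn <- w - lam * step
        if (sum(abs(resid(wn))) < sum(abs(r)) || lam < 1e-4) break
        lam <- lam / 2
      }
      w <- wn
    }
    list(w = w, ok = max(abs(resid(w))) < tol)
  }
  # a valid solution makes both boundaries transversal threshold crossings:
  # the fire side flips between the inside midpoint and the outside flanks
  span <- max(dt_plus - dt_minus, 4 * kernel$tau_m)
  probes <- c((dt_minus + dt_plus) / 2, dt_minus - span, dt_plus + span)
  valid <- function(w) {
    v <- cpp_vmax_pair(probes, w[1], w[2], kernel$tau_m, kernel$tau_s) - theta
    all(abs(v) > 1e-3 * theta) &&
      sign(v[1]) == -sign(v[2]) && sign(v[1]) == -sign(v[3])
  }
  # coarse scan for a Newton start, then multi-start refinement
  gr <- seq(-3, 3, length.out = 61) * theta
  cand <- expand.grid(w1 = gr, w2 = gr)
  cand <- cand[cand$w1 + cand$w2 > 0.05 * theta & pmax(cand$w1, cand$w2) > 0, ]
  r1 <- vapply(seq_len(nrow(cand)), function(i)
    sum(abs(resid(c(cand$w1[i], cand$w2[i])))), numeric(1))
  ord <- order(r1)
  sol <- NULL
  for (i in ord[seq_len(min(60, length(ord)))]) {
    n <- newton(c(cand$w1[i], cand$w2[i]))
    if (n$ok && valid(n$w)) { sol <- n$w; break }
  }
  if (is.null(sol))
    stop("no weight pair realizes these boundaries for this kernel; ",
         "a shorter or longer PSP time course (tau_m) may be required")
  mid <- vmax_of_dt((dt_minus + dt_plus) / 2, sol[1], sol[2], kernel)
  regime <- if (sol[1] > 0 && sol[2] > 0) "++" else
    if (sol[1] > 0) "+-" else "-+"
  list(dt_minus = dt_minus, dt_plus = dt_plus, w1 = sol[1], w2 = sol[2],
       regime = regime, fires_inside = mid >= theta,
       residual = max(abs(resid(sol))))
}

#' Expected pair-readout error under Gaussian threshold noise
#'
#' The relative latency of each stimulus is modeled as a Gaussian; the
#' neuron's threshold fluctuates with zero-mean Gaussian noise whose s.d. is
#' a fraction of the mean weight magnitude. The expected error integrates the
#' Gaussian-threshold tail probability of a wrong decision over each
#' stimulus's latency distribution (trapezoid quadrature over +-5 s.d.).
#'
#' @param noise data frame with columns \code{mu}, \code{sd}, \code{label}
#'   (1 target / 0 null), one row per stimulus
#' @param w1,w2 efficacies
#' @param theta threshold
#' @param kernel a [psp_kernel_params()]
#' @param noise_frac threshold-noise s.d. as a fraction of mean |w|
#' @param nq quadrature nodes
#' @return expected error fraction
#' @export
threshold_noise_error <- function(noise, w1, w2, theta = 1,
                                  kernel = psp_kernel_params(),
                                  noise_frac = 0.05, nq = 201) {
  z <- seq(-5, 5, length.out = nq)
  pw <- exp(-z^2 / 2); pw <- pw / sum(pw)
  nsd <- noise_frac * mean(abs(c(w1, w2)))
  per <- vapply(seq_len(nrow(noise)), function(s) {
    d <- noise$mu[s] + noise$sd[s] * z
    v <- vmax_of_dt(d, w1, w2, kernel)
    pfire <- if (nsd > 0) stats::pnorm((v - theta) / nsd) else
      as.numeric(v >= theta)
    if (!all(is.finite(pfire))) stop("non-finite integrand")
    sum(pw * (if (noise$label[s] == 1) 1 - pfire else pfire))
  }, numeric(1))
  mean(per)
}

#' Exhaustive pair-weight optimization per PSP time constant
#'
#' For each membrane time constant in \code{tau_grid} (with tau_s = tau_m/4),
#' searches the weight grid exhaustively under a sign constraint ("++": both
#' excitatory; "mixed": one excitatory, one inhibitory) and records the
#' minimal expected error under Gaussian latency input and threshold noise.
#'
#' @param noise data frame (mu, sd, label) as in [threshold_noise_error()]
#' @param theta threshold
#' @param tau_grid membrane time constants, ms
#' @param weight_grid candidate weights (pruned by the constraint)
#' @param constraint "++" or "mixed"
#' @param noise_frac threshold-noise fraction
#' @param nq quadrature nodes
#' @return data frame: tau_m, w1, w2, error (one row per tau)
#' @export
optimize_pair <- function(noise, theta = 1, tau_grid = 10^seq(0, 2, length.out = 13),
                          weight_grid = seq(-3, 3, length.out = 201),
                          constraint = c("++", "mixed"), noise_frac = 0.05,
                          nq = 61) {
  constraint <- match.arg(constraint)
  stopifnot(length(tau_grid) > 0, length(weight_grid) > 0)
  pos <- weight_grid[weight_grid > 0]
  neg <- weight_grid[weight_grid < 0]
  rows <- lapply(tau_grid, function(tm) {
    grids <- if (constraint == "++") list(list(pos, pos)) else
      list(list(pos, neg), list(neg, pos))
    best <- c(err = Inf, w1 = NA, w2 = NA)
    for (g in grids) {
      em <- cpp_pair_grid_error(g[[1]], g[[2]], noise$mu, noise$sd,
                                as.integer(noise$label), theta, tm, tm / 4,
                                noise_frac, as.integer(nq))
      i <- which(em == min(em, na.rm = TRUE), arr.ind = TRUE)[1, ]
      if (em[i[1], i[2]] < best["err"])
        best <- c(err = em[i[1], i[2]], w1 = g[[1]][i[1]], w2 = g[[2]][i[2]])
    }
    data.frame(tau_m = tm, w1 = best["w1"], w2 = best["w2"],
               error = best["err"], row.names = NULL)
  })
  do.call(rbind, rows)
}

# Empirical pair classification error from first-spike latencies. Trials
# where an afferent is silent contribute only the surviving spikes (a fully
# silent trial is classified null).
pair_error_empirical <- function(l1, l2, labels, w1, w2, theta, kernel) {
  both <- is.finite(l1) & is.finite(l2)
  v <- numeric(length(l1))
  if (any(both))
    v[both] <- cpp_vmax_pair(l2[both] - l1[both], w1, w2,
                             kernel$tau_m, kernel$tau_s)
  only1 <- is.finite(l1) & !is.finite(l2)
  only2 <- !is.finite(l1) & is.finite(l2)
  v[only1] <- max(w1, 0)
  v[only2] <- max(w2, 0)
  mean((v >= theta) != (labels == 1))
}

#' Readout-time sweep for a two-afferent readout
#'
#' For each maximal allowed latency t_max, first spikes later than t_max are
#' discarded and the weight pair is re-optimized by exhaustive grid search;
#' reports the best fraction of correct classifications, per contrast level.
#'
#' @param dataset a two-afferent [spike_dataset()] (first-spike-restricted)
#' @param spec task realization from [enumerate_realizations()]
#' @param t_max_grid maximal allowed latencies, ms
#' @param theta threshold
#' @param kernel a [psp_kernel_params()]
#' @param weight_grid candidate weights
#' @return data frame: t_max, contrast, fraction_correct
#' @export
readout_time_sweep <- function(dataset, spec, t_max_grid, theta = 1,
                               kernel = psp_kernel_params(),
                               weight_grid = seq(-2, 2, length.out = 41)) {
  if (length(t_max_grid) == 0) stop("t_max_grid must be non-empty")
  if (length(dataset$afferents) != 2) stop("dataset must have 2 afferents")
  lab <- label_trials(dataset, spec)
  ds <- lab$dataset; labels <- lab$labels
  l1 <- vapply(ds$trials, function(t)
    if (length(t$trains[[1]]) > 0) t$trains[[1]][1] else NA_real_, numeric(1))
  l2 <- vapply(ds$trials, function(t)
    if (length(t$trains[[2]]) > 0) t$trains[[2]][1] else NA_real_, numeric(1))
  contr <- vapply(ds$trials, function(t) as.numeric(t$contrast), numeric(1))
  if (all(is.na(contr))) contr <- rep(0, length(l1))
  wpairs <- expand.grid(w1 = weight_grid, w2 = weight_grid)
  wpairs <- wpairs[wpairs$w1 + wpairs$w2 > 0 & pmax(wpairs$w1, wpairs$w2) > 0, ]
  rows <- list()
  for (tmax in t_max_grid) {
    a <- ifelse(!is.na(l1) & l1 <= tmax, l1, NA_real_)
    b <- ifelse(!is.na(l2) & l2 <= tmax, l2, NA_real_)
    for (cl in sort(unique(contr))) {
      sel <- contr == cl
      errs <- vapply(seq_len(nrow(wpairs)), function(i)
        pair_error_empirical(a[sel], b[sel], labels[sel],
                             wpairs$w1[i], wpairs$w2[i], theta, kernel),
        numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        t_max = tmax, contrast = cl, fraction_correct = 1 - min(errs))
    }
  }
  do.call(rbind, rows)
}
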