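# Vectorized dark fraction for all cells of an orientation population at one
# (phase, orientation) stimulus; same convention as dark_fraction().
dark_fraction_cells <- function(population, phase_deg, orientation_deg) {
  psi <- (orientation_deg %% 180) * pi / 180
  p0 <- population$x * cos(psi) + population$y * sin(psi)
  sigma <- population$sigma_rf
  phi <- phase_deg / 360
  kmin <- floor(min(p0 - 8 * sigma) - phi - 0.75)
  kmax <- ceiling(max(p0 + 8 * sigma) - phi - 0.25)
  ks <- kmin:kmax
  lo <- outer(rep(1, length(p0)), phi + 0.25 + ks)
  hi <- lo + 0.5
  d <- rowSums(stats::pnorm((hi - p0) / sigma) - stats::pnorm((lo - p0) / sigma))
  pmin(pmax(d, 0), 1)
}

#' Phase x orientation stimulus grid
#'
#' The training grid for the phase-invariant orientation task: phases linear
#' in [-180, 180] deg, orientations linear in [-90, 90] deg. A stimulus is a
#' target iff its orientation lies within the target half-width of 0 deg.
#' Within the exclusion half-width of the target-region boundary the training
#' margin is switched off (margin_active = FALSE) so the margin never fights
#' the hard class boundary.
#'
#' @param n_phases,n_orientations grid resolution (201 x 101 full scale;
#'   41 x 21 is the reduced desk-scale preset)
#' @param target_halfwidth degrees (15 narrow / 30 wide)
#' @param margin training margin, fraction of threshold
#' @param exclusion_halfwidth degrees (3 narrow / 6 wide)
#' @return data frame of class \code{orientation_grid}: phase, orientation,
#'   label, margin_active
#' @export
build_grid <- function(n_phases = 201, n_orientations = 101,
                       target_halfwidth = 15, margin = 0.1,
                       exclusion_halfwidth = 3) {
  g <- expand.grid(phase = seq(-180, 180, length.out = n_phases),
                   orientation = seq(-90, 90, length.out = n_orientations))
  g$label <- as.integer(abs(g$orientation) <= target_halfwidth)
  g$margin_active <- abs(abs(g$orientation) - target_halfwidth) >
    exclusion_halfwidth
  attr(g, "margin") <- margin
  attr(g, "target_halfwidth") <- target_halfwidth
  class(g) <- c("orientation_grid", "data.frame")
  g
}

# Flatten the deterministic single-spike patterns of a population over a grid
# into the arrays the compiled trainer consumes.
orientation_pattern_arrays <- function(population, grid) {
  n <- nrow(grid)
  nc <- nrow(population)
  tim <- numeric(n * nc)
  aff <- integer(n * nc)
  for (i in seq_len(n)) {
    D <- dark_fraction_cells(population, grid$phase[i], grid$orientation[i])
    lat <- pmax(population$baseline + population$amplitude * cos(pi * D), 0.5)
    o <- order(lat)
    idx <- ((i - 1) * nc + 1):(i * nc)
    tim[idx] <- lat[o]
    aff[idx] <- o - 1L
  }
  list(tim = tim, aff = aff, rfac = rep(1, n * nc),
       ptr = as.integer(seq(0, n * nc, by = nc)))
}

#' Learning schedule for the orientation experiment
#'
#' Step size decays as lambda_n = lambda0 / (1 + n / decay_scale) with n the
#' number of presented patterns; momentum 0.99; small Gaussian weight
#' initialization.
#'
#' @param lambda0 initial step size
#' @param decay_scale presentations at which the step size halves
#' @param momentum momentum parameter
#' @param cycles learning cycles over the grid
#' @param init_sd initial-weight s.d.
#' @return list of class \code{schedule_spec}
#' @export
schedule_spec <- function(lambda0 = 5e-4, decay_scale = 2e5, momentum = 0.99,
                          cycles = 10000, init_sd = 0.001) {
  stopifnot(lambda0 >= 0, decay_scale > 0, momentum >= 0, momentum < 1)
  structure(list(lambda0 = lambda0, decay_scale = decay_scale,
                 momentum = momentum, cycles = cycles, init_sd = init_sd),
            class = "schedule_spec")
}

#' Train a tempotron for phase-invariant orientation tuning
#'
#' Margin-aware training over the full stimulus grid: targets must exceed
#' theta*(1+margin) and nulls stay below theta*(1-margin) except in the
#' exclusion zones, with the decaying step-size schedule and momentum, in a
#' random but fixed presentation order. Convergence (zero margin-free
#' classification error over the whole grid) is checked every
#' \code{check_every} cycles; training stops early once converged.
#'
#' @param population an [sample_orientation_population()]
#' @param grid a [build_grid()]
#' @param schedule a [schedule_spec()]
#' @param kernel a [psp_kernel_params()]
#' @param theta firing threshold
#' @param seed RNG seed (weight init and presentation order)
#' @param check_every convergence-check period, cycles
#' @return list(model, converged, cycles_run, error_curve,
#'   grid_error_history, arrays)
#' @export
train_orientation <- function(population, grid, schedule = schedule_spec(),
                              kernel = psp_kernel_params(), theta = 1,
                              seed = 1, check_every = 50) {
  arr <- orientation_pattern_arrays(population, grid)
  n <- nrow(grid)
  margins <- ifelse(grid$margin_active, attr(grid, "margin"), 0)
  set.seed(seed)
  w0 <- rnorm(nrow(population), 0, schedule$init_sd)
  ord <- sample.int(n) - 1L
  tend <- max(arr$tim) + 5 * kernel$tau_m
  fit <- cpp_train(arr$tim, arr$aff, arr$rfac, arr$ptr,
                   as.integer(grid$label), ord, w0, theta,
                   kernel$tau_m, kernel$tau_s, tend,
                   schedule$lambda0, schedule$decay_scale, schedule$momentum,
                   as.integer(schedule$cycles), margins, FALSE,
                   as.integer(check_every))
  list(model = tempotron_model(fit$weights, theta, kernel),
       converged = fit$converged, cycles_run = fit$cycles_run,
       error_curve = fit$error_curve[seq_len(fit$cycles_run)],
       grid_error_history = fit$grid_error_history, arrays = arr)
}

# Evaluate peak voltage and first crossing of a trained model over stimuli.
orientation_eval <- function(model, population, phases, orientations) {
  g <- expand.grid(phase = phases, orientation = orientations)
  nc <- nrow(population)
  arr <- orientation_pattern_arrays(population, g)
  tend <- max(arr$tim) + 5 * model$kernel$tau_m
  ev <- cpp_eval_batch(arr$tim, arr$aff, arr$rfac, arr$ptr, model$weights,
                       model$threshold, model$kernel$tau_m,
                       model$kernel$tau_s, tend)
  g$v_max <- ev[, 1]
  g$t_cross <- ev[, 3]
  g
}

#' Orientation tuning curves of the peak voltage
#'
#' Noiseless evaluation of the peak voltage across orientations at a few
#' probe phases; a converged phase-invariant model crosses threshold only
#' inside the target orientation band, at every probe phase.
#'
#' @param model a trained [tempotron_model()]
#' @param population the model's input population
#' @param orientations orientations to probe, degrees
#' @param probe_phases phases to probe, degrees
#' @return data frame: phase, orientation, v_max
#' @export
tuning_curves <- function(model, population,
                          orientations = seq(-90, 90, by = 2),
                          probe_phases = c(-90, 0, 90, 180)) {
  ev <- orientation_eval(model, population, probe_phases, orientations)
  ev[, c("phase", "orientation", "v_max")]
}

#' Output spike-latency map over the stimulus grid
#'
#' First-crossing times where the model fires, expressed relative to the
#' shortest output latency over the grid (map minimum is 0); NA where silent.
#'
#' @param model a trained [tempotron_model()]
#' @param population the model's input population
#' @param grid a [build_grid()]
#' @return data frame: phase, orientation, latency (NA = silent)
#' @export
latency_map <- function(model, population, grid) {
  ev <- orientation_eval(model, population, unique(grid$phase),
                         unique(grid$orientation))
  ev$latency <- ev$t_cross - min(ev$t_cross, na.rm = TRUE)
  ev[, c("phase", "orientation", "latency")]
}
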