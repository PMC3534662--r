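#' Enumerate the realizations of a grating classification task
#'
#' With eight grating phases (index i at spatial phase (i-1)*45 deg), the
#' luminance task discriminates an adjacent phase pair \{i, i+1\} from its
#' polarity-inverted pair \{i+4, i+5\} (8 realizations, role swaps included);
#' the boundary task discriminates a polarity pair \{i, i+4\} from the
#' quarter-period-shifted pair \{i+2, i+6\} (4 realizations). All phase
#' arithmetic is cyclic mod 8.
#'
#' @param task_type "luminance" or "boundary"
#' @return list of task specs: list(task_type, target_phases, null_phases)
#' @export
enumerate_realizations <- function(task_type = c("luminance", "boundary")) {
  task_type <- match.arg(task_type)
  wrap8 <- function(i) ((i - 1) %% 8) + 1
  out <- list()
  if (task_type == "luminance") {
    for (i in 1:8) {
      out[[i]] <- list(task_type = task_type,
                       target_phases = wrap8(c(i, i + 1)),
                       null_phases = wrap8(c(i + 4, i + 5)))
    }
  } else {
    combos <- list(c(1, 3), c(2, 4), c(3, 1), c(4, 2))
    for (k in seq_along(combos)) {
      i <- combos[[k]][1]; j <- combos[[k]][2]
      out[[k]] <- list(task_type = task_type,
                       target_phases = wrap8(c(i, i + 4)),
                       null_phases = wrap8(c(j, j + 4)))
    }
  }
  out
}

#' Label the trials of a dataset under one task realization
#'
#' @param dataset a [spike_dataset()]
#' @param spec one element of [enumerate_realizations()]
#' @return list(dataset = trials restricted to the spec's phases,
#'   labels = 1 for target phases, 0 for null phases)
#' @export
label_trials <- function(dataset, spec) {
  phases <- vapply(dataset$trials, function(t) as.numeric(t$phase_index),
                   numeric(1))
  missing <- setdiff(c(spec$target_phases, spec$null_phases), phases)
  if (length(missing) > 0)
    warning("phases absent from dataset: ", paste(missing, collapse = ", "))
  keep <- phases %in% c(spec$target_phases, spec$null_phases)
  sub <- dataset
  sub$trials <- dataset$trials[keep]
  labels <- as.integer(phases[keep] %in% spec$target_phases)
  list(dataset = sub, labels = labels)
}

#' Run the full training/evaluation protocol for one task realization
#'
#' Learning decoders (tempotron, tempotron+depression, perceptron) are
#' trained \code{runs} times per (lambda, init_sd) grid point with distinct
#' seeds; the reported performance is the minimal smoothed training error
#' over everything. Search decoders (twta1, twta3, rank) report their
#' exhaustive-search optimum.
#'
#' @param dataset a [spike_dataset()]
#' @param spec a task realization from [enumerate_realizations()]
#' @param decoder_kind one of "tempotron", "tempotron+depression",
#'   "perceptron", "twta1", "twta3", "rank"
#' @param lambda_grid step-size grid for learning decoders
#' @param init_sd_grid initial-weight s.d. grid
#' @param runs learning runs per grid point
#' @param cycles,smooth_window,momentum training protocol controls
#' @param depression list(U, tau_d) for the depressing variant
#' @param count_window perceptron counting window, ms
#' @param seed base seed; each (grid point, run) gets a distinct derived seed
#' @return list(best_error, best_correct, best_model, best_config, records)
#' @export
run_protocol <- function(dataset, spec, decoder_kind,
                         lambda_grid = 10^seq(-4, -1, by = 1),
                         init_sd_grid = c(0.01, 0.05, 0.1),
                         runs = 3, cycles = 2000, smooth_window = 50,
                         momentum = 0.9,
                         depression = list(U = 1, tau_d = 500),
                         count_window = 150, seed = 1) {
  lab <- label_trials(dataset, spec)
  ds <- lab$dataset; labels <- lab$labels
  kinds <- c("tempotron", "tempotron+depression", "perceptron",
             "twta1", "twta3", "rank")
  if (!decoder_kind %in% kinds)
    stop("unknown decoder kind: ", decoder_kind)
  if (decoder_kind %in% c("twta1", "twta3")) {
    k <- if (decoder_kind == "twta1") 1 else 3
    fit <- twta_fit(ds, labels, k = k)
    return(list(best_error = fit$error, best_correct = 1 - fit$error,
                best_model = fit$model, best_config = list(k = k),
                records = NULL))
  }
  if (decoder_kind == "rank") {
    ds1 <- restrict_spikes(ds, k_max = 1)
    fit <- rank_fit(ds1, labels)
    return(list(best_error = fit$error, best_correct = 1 - fit$error,
                best_model = fit$model,
                best_config = list(m = fit$model$attenuation), records = NULL))
  }
  if (length(lambda_grid) == 0 || length(init_sd_grid) == 0)
    stop("parameter grids must be non-empty")
  dep <- if (decoder_kind == "tempotron+depression") depression else NULL
  best <- list(best_error = Inf)
  records <- list()
  sidx <- 0
  for (lam in lambda_grid) for (sd0 in init_sd_grid) for (r in seq_len(runs)) {
    sidx <- sidx + 1
    s <- (seed * 10007L + sidx) %% .Machine$integer.max
    fit <- if (decoder_kind == "perceptron")
      perceptron_fit(ds, labels, step_size = lam, cycles = cycles,
                     smooth_window = smooth_window, init_sd = sd0, seed = s,
                     count_window = count_window)
    else
      train_tempotron(ds, labels, step_size = lam, momentum = momentum,
                      cycles = cycles, smooth_window = smooth_window,
                      init_sd = sd0, seed = s, depression = dep)
    records[[sidx]] <- list(lambda = lam, init_sd = sd0, run = r,
                            error = fit$best_error)
    if (fit$best_error < best$best_error) {
      best <- list(best_error = fit$best_error,
                   best_correct = 1 - fit$best_error,
                   best_model = fit$model,
                   best_config = list(lambda = lam, init_sd = sd0, seed = s),
                   records = NULL)
    }
  }
  best$records <- records
  best
}

#' Average protocol performance over all realizations of a task
#'
#' @inheritParams run_protocol
#' @param task_type "luminance" or "boundary"
#' @return list(mean_correct, per_realization)
#' @export
run_task_average <- function(dataset, task_type, decoder_kind, ...) {
  specs <- enumerate_realizations(task_type)
  per <- vapply(seq_along(specs), function(i)
    run_protocol(dataset, specs[[i]], decoder_kind, ...)$best_correct,
    numeric(1))
  list(mean_correct = mean(per), per_realization = per)
}

# Stratified 75/25 split; resamples (reseeds) until both classes appear in
# both subsets.
stratified_split <- function(labels, train_frac = 0.75, seed = 1) {
  for (attempt in seq_len(100)) {
    set.seed(seed + attempt - 1)
    tr <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      ntr <- round(train_frac * length(idx))
      ntr <- min(max(ntr, 1), length(idx) - 1)
      tr[sample(idx, ntr)] <- TRUE
    }
    if (length(unique(labels[tr])) == 2 && length(unique(labels[!tr])) == 2)
      return(tr)
  }
  stop("could not produce a stratified split with both classes present")
}

#' Cross-validated tempotron performance with a training margin
#'
#' Stratified 75/25 split; training counts a target as an error unless
#' v_max >= theta*(1+margin) and a null unless v_max <= theta*(1-margin).
#' The margin is chosen by training performance; the test error is measured
#' margin-free.
#'
#' @param dataset a [spike_dataset()]
#' @param spec task realization
#' @param margin_grid margins tried
#' @param step_size,init_sd,cycles,smooth_window,momentum training controls
#' @param seed RNG seed (split and training)
#' @return list(train_error, test_error, margin, model, split)
#' @export
crossvalidate <- function(dataset, spec,
                          margin_grid = c(0, 0.025, 0.05, 0.1, 0.15, 0.2),
                          step_size = 1e-3, init_sd = 0.05, cycles = 2000,
                          smooth_window = 50, momentum = 0.9, seed = 1) {
  lab <- label_trials(dataset, spec)
  ds <- lab$dataset; labels <- lab$labels
  if (length(labels) < 8) stop("need at least 8 labeled trials")
  tr <- stratified_split(labels, 0.75, seed)
  train_ds <- ds; train_ds$trials <- ds$trials[tr]
  test_ds <- ds; test_ds$trials <- ds$trials[!tr]
  best <- list(train_error = Inf)
  for (m in margin_grid) {
    fit <- train_tempotron(train_ds, labels[tr], step_size = step_size,
                           momentum = momentum, cycles = cycles,
                           smooth_window = smooth_window, init_sd = init_sd,
                           seed = seed, margin = m)
    if (fit$best_error < best$train_error) {
      best <- list(train_error = fit$best_error, margin = m,
                   model = fit$model)
    }
  }
  best$test_error <- evaluate_tempotron(test_ds, labels[!tr], best$model)
  best$split <- tr
  best
}

#' Train on selected contrasts, evaluate per contrast
#'
#' Trains a single tempotron on trials from all contrasts or from the two
#' extreme contrasts only, freezes its weights, and measures the
#' classification error separately within each contrast level (the
#' contrast-generalization design).
#'
#' @param dataset multi-contrast [spike_dataset()]
#' @param spec task realization
#' @param train_contrasts "all" or "extremes"
#' @param ... passed to [train_tempotron()]
#' @return list(per_contrast = named error vector, model, trained_on)
#' @export
contrast_generalization <- function(dataset, spec,
                                    train_contrasts = c("all", "extremes"),
                                    ...) {
  train_contrasts <- match.arg(train_contrasts)
  lab <- label_trials(dataset, spec)
  ds <- lab$dataset; labels <- lab$labels
  contr <- vapply(ds$trials, function(t) as.numeric(t$contrast), numeric(1))
  levels <- sort(unique(contr))
  if (length(levels) < 2 && train_contrasts == "extremes")
    stop("need >= 2 contrast levels")
  sel <- if (train_contrasts == "all") rep(TRUE, length(contr)) else
    contr %in% range(levels)
  train_ds <- ds; train_ds$trials <- ds$trials[sel]
  fit <- train_tempotron(train_ds, labels[sel], ...)
  per <- vapply(levels, function(cl) {
    sub <- ds; sub$trials <- ds$trials[contr == cl]
    evaluate_tempotron(sub, labels[contr == cl], fit$model)
  }, numeric(1))
  names(per) <- levels
  list(per_contrast = per, model = fit$model, trained_on = levels[
    if (train_contrasts == "all") seq_along(levels) else c(1, length(levels))])
}

#' Resample afferent subsets from a pooled dataset
#'
#' Draws \code{n_samples} virtual populations of \code{n_cells} afferents
#' (sampled without replacement within each draw) from the pool, mimicking
#' the validation of readout performance across cell subsets.
#'
#' @param pool a [spike_dataset()]
#' @param n_cells afferents per sample
#' @param n_samples number of virtual populations
#' @param seed RNG seed
#' @return list of spike_datasets (each records its cell subset in metadata)
#' @export
resample_populations <- function(pool, n_cells, n_samples, seed = 1) {
  naff <- length(pool$afferents)
  if (n_cells > naff) stop("n_cells exceeds pool size")
  set.seed(seed)
  lapply(seq_len(n_samples), function(i) {
    pick <- sort(sample.int(naff, n_cells))
    sub <- pool
    sub$trials <- lapply(pool$trials, function(tr) {
      tr$trains <- tr$trains[pick]
      tr
    })
    sub$afferents <- pool$afferents[pick]
    sub$metadata$cells <- pick
    sub
  })
}
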