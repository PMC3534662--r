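#' Spike-pattern data model and tabular I/O
#'
#' A \code{spike_dataset} holds the population spike responses to a set of
#' grating trials: one spike train per afferent (retinal ganglion cell) per
#' trial, with spike times in milliseconds relative to stimulus onset, plus
#' the stimulus metadata (grating phase index 1--8, Michelson contrast in
#' percent). All trials of a dataset share the same afferent set, and all
#' spike times lie inside the response window (150 ms by default).
#'
#' @param trials list of trial patterns as built by [trial_pattern()]
#' @param window_ms response-window duration in ms
#' @param metadata optional list of free-form dataset annotations
#' @return an object of class \code{spike_dataset}
#' @export
spike_dataset <- function(trials, window_ms = 150, metadata = list()) {
  stopifnot(is.list(trials), window_ms > 0)
  if (length(trials) > 0) {
    affs <- names(trials[[1]]$trains)
    for (tr in trials) {
      if (!identical(names(tr$trains), affs))
        stop("all trials must share the same afferent set")
      for (tt in tr$trains) {
        if (length(tt) > 0) {
          if (is.unsorted(tt, strictly = TRUE))
            stop("spike times must be strictly increasing")
          if (any(tt < 0) || any(tt > window_ms))
            stop("spike times must lie in [0, window_ms]")
        }
      }
    }
  } else affs <- character(0)
  structure(list(trials = trials, afferents = affs,
                 window_ms = window_ms, metadata = metadata),
            class = "spike_dataset")
}

#' Build one trial pattern
#'
#' @param trial_id integer trial identifier
#' @param trains named list (afferent id -> numeric vector of spike times,
#'   ms); an empty vector marks a spike failure
#' @param phase_index grating phase index (1--8) or continuous degrees
#' @param contrast percent Michelson contrast
#' @param class_label optional binary label (1 target, 0 null, NA unassigned)
#' @return a list of class \code{trial_pattern}
#' @export
trial_pattern <- function(trial_id, trains, phase_index = NA, contrast = NA,
                          class_label = NA) {
  trains <- lapply(trains, function(x) as.numeric(sort(x)))
  structure(list(trial_id = as.integer(trial_id), trains = trains,
                 phase_index = phase_index, contrast = contrast,
                 class_label = class_label),
            class = "trial_pattern")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("spike_dataset: %d trials, %d afferents, window %g ms\n",
              length(x$trials), length(x$afferents), x$window_ms))
  invisible(x)
}

#' @export
print.trial_pattern <- function(x, ...) {
  cat(sprintf("trial %d (phase %s, contrast %s): %d spikes on %d afferents\n",
              x$trial_id, format(x$phase_index), format(x$contrast),
              sum(lengths(x$trains)), length(x$trains)))
  invisible(x)
}

#' Read a spike table and its stimulus table
#'
#' Spike files are plain CSV with columns \code{trial_id, afferent_id,
#' time_ms}; the stimulus table has \code{trial_id, phase_index, contrast}.
#' Afferents are indexed 1..max(afferent_id); a trial with no row for an
#' afferent gets an empty train (spike failure).
#'
#' @param path spike CSV path
#' @param stimulus_path stimulus CSV path
#' @param window_ms response window, ms
#' @return a [spike_dataset()]
#' @export
read_spike_table <- function(path, stimulus_path, window_ms = 150) {
  sp <- utils::read.csv(path)
  st <- utils::read.csv(stimulus_path)
  need <- c("trial_id", "afferent_id", "time_ms")
  if (!all(need %in% names(sp)))
    stop("spike file must have columns trial_id, afferent_id, time_ms")
  if (!all(c("trial_id", "phase_index", "contrast") %in% names(st)))
    stop("stimulus file must have columns trial_id, phase_index, contrast")
  if (nrow(sp) > 0) {
    bad <- setdiff(unique(sp$trial_id), st$trial_id)
    if (length(bad) > 0)
      stop("spike file references trial_id(s) absent from stimulus table: ",
           paste(bad, collapse = ", "))
    if (any(sp$time_ms < 0) || any(sp$time_ms > window_ms))
      stop("spike times must lie in [0, window_ms]")
  }
  n_aff <- if (nrow(sp) > 0) max(sp$afferent_id) else 0L
  aff_ids <- as.character(seq_len(n_aff))
  trials <- lapply(seq_len(nrow(st)), function(i) {
    tid <- st$trial_id[i]
    rows <- sp[sp$trial_id == tid, , drop = FALSE]
    trains <- lapply(aff_ids, function(a) {
      sort(rows$time_ms[rows$afferent_id == as.integer(a)])
    })
    names(trains) <- aff_ids
    trial_pattern(tid, trains, phase_index = st$phase_index[i],
                  contrast = st$contrast[i])
  })
  spike_dataset(trials, window_ms = window_ms,
                metadata = list(contrast_levels = sort(unique(st$contrast))))
}

#' Write a dataset as spike + stimulus CSV tables
#'
#' Times are written with 4 decimal places so a write/read round trip is
#' exact to 1e-3 ms and repeated writes are byte-identical.
#'
#' @param dataset a [spike_dataset()]
#' @param path spike CSV path
#' @param stimulus_path stimulus CSV path (omit to skip)
#' @return invisibly, \code{dataset}
#' @export
write_spike_table <- function(dataset, path, stimulus_path = NULL) {
  rows <- list()
  for (tr in dataset$trials) {
    for (a in names(tr$trains)) {
      tt <- tr$trains[[a]]
      if (length(tt) > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = tr$trial_id, afferent_id = as.integer(a),
          time_ms = sprintf("%.4f", tt))
    }
  }
  sp <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(trial_id = integer(0), afferent_id = integer(0),
               time_ms = character(0))
  utils::write.csv(sp, path, row.names = FALSE, quote = FALSE)
  if (!is.null(stimulus_path)) {
    st <- data.frame(
      trial_id = vapply(dataset$trials, function(t) t$trial_id, integer(1)),
      phase_index = vapply(dataset$trials, function(t) as.numeric(t$phase_index), numeric(1)),
      contrast = vapply(dataset$trials, function(t) as.numeric(t$contrast), numeric(1)))
    utils::write.csv(st, stimulus_path, row.names = FALSE, quote = FALSE)
  }
  invisible(dataset)
}

#' Restrict spikes per afferent
#'
#' Truncates each train to its first \code{k_max} spikes, then removes spikes
#' later than \code{t_max}. Used to study readout from first spikes only and
#' readout-time-limited decoding.
#'
#' @param dataset a [spike_dataset()]
#' @param k_max keep at most this many spikes per afferent (NULL = all)
#' @param t_max keep only spikes at or before this time, ms (NULL = all)
#' @return a new restricted [spike_dataset()]
#' @export
restrict_spikes <- function(dataset, k_max = NULL, t_max = NULL) {
  if (!is.null(k_max) && k_max < 1) stop("k_max must be >= 1")
  if (!is.null(t_max) && t_max <= 0) stop("t_max must be > 0")
  trials <- lapply(dataset$trials, function(tr) {
    tr$trains <- lapply(tr$trains, function(tt) {
      if (!is.null(k_max) && length(tt) > k_max) tt <- tt[seq_len(k_max)]
      if (!is.null(t_max)) tt <- tt[tt <= t_max]
      tt
    })
    tr
  })
  out <- dataset
  out$trials <- trials
  out
}

# Flatten a dataset into the arrays the compiled core consumes: spike times
# concatenated per trial (sorted within trial), 0-based afferent index per
# spike, per-spike depression factor, and 0-based trial offsets.
flatten_dataset <- function(dataset, depression = NULL) {
  affs <- dataset$afferents
  ntr <- length(dataset$trials)
  tim <- list(); aff <- list(); rfac <- list()
  ptr <- integer(ntr + 1)
  for (i in seq_len(ntr)) {
    tr <- dataset$trials[[i]]
    tt <- unlist(tr$trains, use.names = FALSE)
    ai <- rep(seq_along(affs) - 1L, lengths(tr$trains))
    rr <- if (is.null(depression)) rep(1, length(tt)) else
      unlist(lapply(tr$trains, function(x)
        depression_factors(x, depression$U, depression$tau_d)),
        use.names = FALSE)
    o <- order(tt)
    tim[[i]] <- tt[o]; aff[[i]] <- ai[o]; rfac[[i]] <- rr[o]
    ptr[i + 1] <- ptr[i] + length(tt)
  }
  list(tim = as.numeric(unlist(tim)), aff = as.integer(unlist(aff)),
       rfac = as.numeric(unlist(rfac)), ptr = ptr,
       phase = vapply(dataset$trials, function(t) as.numeric(t$phase_index), numeric(1)),
       contrast = vapply(dataset$trials, function(t) as.numeric(t$contrast), numeric(1)))
}
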