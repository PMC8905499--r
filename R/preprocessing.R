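#' Baseline-correct an epoch dataset
#'
#' Subtracts, for every trial and channel, the mean potential over the
#' pre-stimulus window from the whole epoch, so that each trial's
#' pre-stimulus mean becomes exactly zero.
#'
#' @param dataset an `epoch_dataset`.
#' @param window baseline window in ms (default c(-100, 0)).
#' @return a new `epoch_dataset`.
#' @export
baseline_correct <- function(dataset, window = c(-100, 0)) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  idx <- window_indices(dataset$times, window, dataset$rate)
  trials <- dataset$trials
  base <- apply(trials[, , idx, drop = FALSE], c(1, 2), mean)
  out <- trials - array(base, dim = dim(trials))  # base recycles over samples
  dataset$trials <- out
  dataset
}

#' Average repetitions into one evoked response per stimulus
#'
#' The arithmetic mean of all trials of each stimulus, ordered by the
#' design's stimulus order when a design is given (otherwise by first
#' appearance). Averaging over n repetitions reduces trial noise variance
#' by a factor n, which is why classification operates on evoked responses
#' rather than single trials.
#'
#' @param dataset an `epoch_dataset`.
#' @param design optional `stimulus_design` fixing the output order; every
#'   design stimulus must have at least one trial.
#' @return an `evoked_set`: list with `subject_id`, `evoked`
#'   (n_stimuli x n_channels x n_samples), `stimulus_ids`, `times`, `rate`.
#' @export
average_repetitions <- function(dataset, design = NULL) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  ids <- if (is.null(design)) unique(dataset$stimulus_ids) else design$stimuli$id
  missing_ids <- setdiff(ids, dataset$stimulus_ids)
  if (length(missing_ids))
    stop("no trials for stimuli: ", paste(missing_ids, collapse = ", "))
  d <- dim(dataset$trials)
  evoked <- array(0, dim = c(length(ids), d[2], d[3]))
  for (i in seq_along(ids)) {
    rows <- which(dataset$stimulus_ids == ids[i])
    block <- dataset$trials[rows, , , drop = FALSE]
    evoked[i, , ] <- apply(block, c(2, 3), mean)
  }
  structure(list(subject_id = dataset$subject_id, evoked = evoked,
                 stimulus_ids = ids, times = dataset$times,
                 rate = dataset$rate),
            class = "evoked_set")
}

#' Standardize channels across all evoked responses
#'
#' Per channel, subtracts the grand mean and divides by the grand standard
#' deviation computed by pooling every stimulus and every sample of that
#' channel (population sd, divide-by-N). After standardization each
#' channel's pooled values have mean 0 and sd 1; the transform is
#' invariant to prior channel-wise affine maps.
#'
#' @param evoked an `evoked_set`.
#' @return a new `evoked_set`.
#' @export
standardize_channels <- function(evoked) {
  stopifnot(inherits(evoked, "evoked_set"))
  arr <- evoked$evoked
  n_ch <- dim(arr)[2]
  for (c_i in seq_len(n_ch)) {
    x <- arr[, c_i, ]
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (s == 0)
      stop("channel ", c_i, " has zero variance; cannot standardize")
    arr[, c_i, ] <- (x - m) / s
  }
  evoked$evoked <- arr
  evoked
}

#' Run the canonical preprocessing pipeline
#'
#' Baseline correction, then per-stimulus repetition averaging, then
#' channel standardization — the object entering classification and
#' decoding. Standardization is idempotent: standardizing twice changes
#' nothing beyond numerical tolerance.
#'
#' @param dataset an `epoch_dataset`.
#' @param design optional `stimulus_design` (fixes evoked order).
#' @param baseline_window baseline window in ms.
#' @return an `evoked_set`.
#' @export
preprocess_subject <- function(dataset, design = NULL,
                               baseline_window = c(-100, 0)) {
  standardize_channels(
    average_repetitions(baseline_correct(dataset, baseline_window), design))
}

#' @export
print.evoked_set <- function(x, ...) {
  d <- dim(x$evoked)
  cat("Evoked set ", x$subject_id, ": ", d[1], " stimuli x ", d[2],
      " channels x ", d[3], " samples\n", sep = "")
  invisible(x)
}
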