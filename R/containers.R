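#' Trial-epoch container
#'
#' Channels x time x trials EEG array with montage and sampling
#' metadata. Time zero is the auditory cue onset.
#'
#' @param data numeric array channels x time x trials (microvolts).
#' @param sample_rate Hz.
#' @param channel_names one 10-20 label per channel.
#' @param epoch_window length-2 ms window relative to the cue covered by
#'   the time axis.
#' @param trial_mask optional logical per trial; `FALSE` marks trials
#'   excluded a priori (e.g. failed movements recorded by the
#'   therapist). Defaults to all `TRUE`.
#' @return object of class `trial_epochs`.
#' @export
trial_epochs <- function(data, sample_rate, channel_names,
                         epoch_window, trial_mask = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != length(channel_names))
    stop("channel count does not match channel names")
  nt_expected <- round(diff(epoch_window) / 1000 * sample_rate) + 1
  if (abs(dim(data)[2] - nt_expected) > 1)
    stop("time axis length inconsistent with epoch_window and sample_rate")
  if (is.null(trial_mask)) trial_mask <- rep(TRUE, dim(data)[3])
  structure(list(data = data, sample_rate = sample_rate,
                 channel_names = channel_names,
                 epoch_window = epoch_window,
                 trial_mask = trial_mask),
            class = "trial_epochs")
}

#' @export
print.trial_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_epochs> %d channels x %d samples x %d trials @ %g Hz, window [%g, %g] ms\n",
              d[1], d[2], d[3], x$sample_rate, x$epoch_window[1], x$epoch_window[2]))
  invisible(x)
}

#' Time axis of a trial-epoch container (ms)
#' @param epochs a [trial_epochs()].
#' @export
epoch_times <- function(epochs) {
  seq(epochs$epoch_window[1], by = 1000 / epochs$sample_rate,
      length.out = dim(epochs$data)[2])
}

#' Source-spectrogram container
#'
#' Baseline-corrected induced power (percent change from baseline) over
#' sources x frequencies x peristimulus time.
#'
#' @param power numeric array sources x frequencies x time.
#' @param frequencies Hz.
#' @param times ms, relative to the cue.
#' @param source_labels one label per source.
#' @param n_trials_used trials entering the average (for provenance).
#' @return object of class `source_spectrogram`.
#' @export
source_spectrogram <- function(power, frequencies, times, source_labels,
                               n_trials_used = NA_integer_) {
  stopifnot(length(dim(power)) == 3,
            dim(power)[1] == length(source_labels),
            dim(power)[2] == length(frequencies),
            dim(power)[3] == length(times))
  if (!all(is.finite(power))) stop("spectrogram power must be finite")
  dimnames(power) <- list(source_labels, frequencies, times)
  structure(list(power = power, frequencies = frequencies, times = times,
                 source_labels = source_labels,
                 n_trials_used = n_trials_used),
            class = "source_spectrogram")
}

#' @export
print.source_spectrogram <- function(x, ...) {
  cat(sprintf("<source_spectrogram> %d sources x %d frequencies (%g-%g Hz) x %d times (%g to %g ms)\n",
              length(x$source_labels), length(x$frequencies),
              min(x$frequencies), max(x$frequencies), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Read/write trial epochs
#'
#' Epochs serialize to a single-file RDS container holding the data
#' array, sampling metadata and trial mask.
#'
#' @param epochs a [trial_epochs()].
#' @param path file path.
#' @return `read_trial_epochs` returns a [trial_epochs()].
#' @export
write_trial_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "trial_epochs"))
  saveRDS(unclass(epochs), path)
  invisible(path)
}

#' @rdname write_trial_epochs
#' @export
read_trial_epochs <- function(path) {
  x <- readRDS(path)
  trial_epochs(x$data, x$sample_rate, x$channel_names, x$epoch_window,
               x$trial_mask)
}
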