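#' Zero-phase band-pass filter of trial epochs
#'
#' 4th-order Butterworth applied forward-backward (zero phase) per
#' channel and trial.
#'
#' @param raw a [trial_epochs()].
#' @param low,high band edges, Hz; defaults 4-48.
#' @return filtered [trial_epochs()] with unchanged shape.
#' @export
bandpass_epochs <- function(raw, low = 4, high = 48) {
  nyq <- raw$sample_rate / 2
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (high >= nyq) stop("high edge must be below the Nyquist frequency (",
                        nyq, " Hz)")
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  d <- raw$data
  for (tr in seq_len(dim(d)[3]))
    for (ch in seq_len(dim(d)[1]))
      d[ch, , tr] <- signal::filtfilt(bf, d[ch, , tr])
  out <- raw
  out$data <- d
  out
}

#' Reject high-amplitude artifact trials
#'
#' Drops any trial whose absolute amplitude exceeds the threshold
#' (strict `>`) on any channel at any sample; survivor order is
#' preserved.
#'
#' @param epochs a [trial_epochs()].
#' @param threshold_uV amplitude threshold, microvolts (default 500).
#' @return list `epochs` (survivors), `rejected_indices`.
#' @export
reject_artifacts <- function(epochs, threshold_uV = 500) {
  if (threshold_uV <= 0) stop("threshold must be positive")
  peak <- apply(abs(epochs$data), 3, max)
  bad <- which(peak > threshold_uV)
  if (length(bad) == dim(epochs$data)[3])
    stop("all trials rejected at ", threshold_uV,
         " uV; downstream stages need at least one trial")
  out <- epochs
  if (length(bad)) {
    out$data <- epochs$data[, , -bad, drop = FALSE]
    out$trial_mask <- epochs$trial_mask[-bad]
  }
  list(epochs = out, rejected_indices = bad)
}

#' Mirror the montage across the mid-sagittal line
#'
#' For right-hemisphere lesions each lateral channel's data are swapped
#' with its mirror (C3 with C4 and so on) so that the ipsilesional
#' hemisphere is always mapped to the left; midline channels are
#' untouched and `lesion_side = "left"` is the identity.
#'
#' @param epochs a [trial_epochs()].
#' @param lesion_side `"left"` or `"right"`.
#' @param montage montage with mirror pairs ([default_montage()]).
#' @return a [trial_epochs()].
#' @export
flip_hemispheres <- function(epochs, lesion_side = c("left", "right"),
                             montage = default_montage()) {
  lesion_side <- match.arg(lesion_side)
  if (lesion_side == "left") return(epochs)
  ch <- epochs$channel_names
  lateral <- grepl("[0-9]$", ch) & !grepl("z$", ch)
  perm <- seq_along(ch)
  for (i in which(lateral)) {
    j <- match(ch[i], montage$pairs$left)
    mirror <- if (!is.na(j)) montage$pairs$right[j] else {
      j <- match(ch[i], montage$pairs$right)
      if (is.na(j)) stop("montage error: no mirror defined for lateral channel ",
                         ch[i])
      montage$pairs$left[j]
    }
    k <- match(mirror, ch)
    if (is.na(k)) stop("montage error: mirror channel ", mirror,
                       " of ", ch[i], " is not in the recording")
    perm[i] <- k
  }
  out <- epochs
  out$data <- epochs$data[perm, , , drop = FALSE]
  out
}

#' Project channel epochs to sources
#'
#' Applies the Moore-Penrose pseudoinverse of the lead field per time
#' sample and trial (minimum-norm source estimate).
#'
#' @param epochs a [trial_epochs()].
#' @param lead_field channels x sources gain matrix with rows matching
#'   the epochs' channels.
#' @return object of class `source_series`: `data` (sources x time x
#'   trials), `sample_rate`, `epoch_window`, `source_labels`.
#' @export
project_to_sources <- function(epochs, lead_field) {
  if (nrow(lead_field) != dim(epochs$data)[1])
    stop("lead field channel dimension does not match epochs")
  if (qr(lead_field)$rank < ncol(lead_field))
    warning("lead field is rank deficient; minimum-norm solution returned")
  pinv <- MASS::ginv(lead_field)
  d <- epochs$data
  ns <- ncol(lead_field)
  out <- array(0, c(ns, dim(d)[2], dim(d)[3]))
  for (tr in seq_len(dim(d)[3])) out[, , tr] <- pinv %*% d[, , tr]
  structure(list(data = out, sample_rate = epochs$sample_rate,
                 epoch_window = epochs$epoch_window,
                 source_labels = colnames(lead_field)),
            class = "source_series")
}

#' Complex Morlet wavelet kernel
#'
#' Gaussian-windowed complex exponential with `n_cycles` cycles
#' (sigma_t = n_cycles / (2 pi f)), truncated at 4 sigma and scaled so
#' a unit-amplitude sinusoid at `f` yields magnitude ~1.
#'
#' @param f center frequency, Hz.
#' @param sample_rate Hz.
#' @param n_cycles wavelet number.
#' @return complex vector (odd length, centered).
#' @export
morlet_kernel <- function(f, sample_rate, n_cycles = 7) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * sample_rate)
  t <- (-half:half) / sample_rate
  env <- exp(-t^2 / (2 * sigma_t^2))
  k <- env * exp(1i * 2 * pi * f * t)
  k * (2 / sum(env))
}

#' Per-trial Morlet time-frequency power
#'
#' Magnitude of the complex Morlet convolution at each frequency
#' (wavelet number 7 by default), per source and trial.
#'
#' @param series a `source_series` from [project_to_sources()], or any
#'   list with `data` (units x time x trials) and `sample_rate`.
#' @param frequencies Hz (all below Nyquist).
#' @param wavelet_number cycles per wavelet, >= 1.
#' @return object of class `trial_power`: `power` (sources x
#'   frequencies x time x trials), `frequencies`, `times` (ms),
#'   `sample_rate`.
#' @export
morlet_power <- function(series, frequencies, wavelet_number = 7) {
  if (wavelet_number < 1) stop("wavelet_number must be >= 1")
  if (any(frequencies >= series$sample_rate / 2))
    stop("frequencies must be below the Nyquist frequency")
  d <- series$data
  nsrc <- dim(d)[1]; nt <- dim(d)[2]; ntr <- dim(d)[3]
  nf <- length(frequencies)
  power <- array(0, c(nsrc, nf, nt, ntr))
  for (fi in seq_len(nf)) {
    k <- morlet_kernel(frequencies[fi], series$sample_rate, wavelet_number)
    for (tr in seq_len(ntr)) for (s in seq_len(nsrc)) {
      power[s, fi, , tr] <- Mod(conv_same(d[s, , tr], k))
    }
  }
  times <- seq(series$epoch_window[1], by = 1000 / series$sample_rate,
               length.out = nt)
  structure(list(power = power, frequencies = frequencies, times = times,
                 sample_rate = series$sample_rate),
            class = "trial_power")
}

# centered ("same") convolution via FFT; kernel length must be odd
conv_same <- function(x, k) {
  nk <- length(k)
  n <- length(x) + nk - 1
  nfft <- stats::nextn(n, 2)
  full <- stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                       stats::fft(c(k, rep(0, nfft - nk))), inverse = TRUE) / nfft
  half <- (nk - 1) / 2
  full[(half + 1):(half + length(x))]
}

#' Trial-average and baseline-correct induced power
#'
#' Averages power over trials, then per source and frequency corrects
#' by the mean over the baseline window (-850 to -800 ms by default):
#' percent change `100 (x - b) / b` (default) or subtraction `x - b`.
#' The result is cropped to the analysis window (-500 to 800 ms).
#'
#' @param trial_power a `trial_power` from [morlet_power()].
#' @param baseline_window ms pair, inside the epoch and before the crop
#'   start.
#' @param crop_window ms pair.
#' @param mode `"percent"` or `"subtract"`.
#' @param source_labels labels for the output spectrogram.
#' @return a [source_spectrogram()].
#' @export
average_and_baseline <- function(trial_power,
                                 baseline_window = c(-850, -800),
                                 crop_window = c(-500, 800),
                                 mode = c("percent", "subtract"),
                                 source_labels = NULL) {
  mode <- match.arg(mode)
  times <- trial_power$times
  if (baseline_window[1] < min(times) || baseline_window[2] > max(times))
    stop("baseline window outside the epoch")
  if (baseline_window[2] > crop_window[1])
    stop("baseline window must end before the crop start")
  avg <- apply(trial_power$power, c(1, 2, 3), mean)
  bidx <- which(times >= baseline_window[1] & times <= baseline_window[2])
  cidx <- which(times >= crop_window[1] & times <= crop_window[2])
  b <- apply(avg[, , bidx, drop = FALSE], c(1, 2), mean)
  out <- avg[, , cidx, drop = FALSE]
  if (mode == "percent") {
    if (any(b <= .Machine$double.eps * 100))
      stop("zero baseline power in at least one source/frequency bin; cannot form percent change")
    out <- 100 * sweep(sweep(out, c(1, 2), b, "-"), c(1, 2), b, "/")
  } else {
    out <- sweep(out, c(1, 2), b, "-")
  }
  if (is.null(source_labels))
    source_labels <- paste0("src", seq_len(dim(out)[1]))
  source_spectrogram(out, trial_power$frequencies, times[cidx],
                     source_labels, n_trials_used = dim(trial_power$power)[4])
}

#' Full preprocessing chain for one subject
#'
#' Band-pass, artifact rejection, mid-sagittal flipping, source
#' projection, Morlet transform and baseline-corrected trial average,
#' with the study defaults at every step.
#'
#' @param epochs raw [trial_epochs()].
#' @param lead_field channels x sources gain matrix.
#' @param lesion_side passed to [flip_hemispheres()].
#' @param frequencies analysis grid, Hz.
#' @param band 2-vector filter band, Hz.
#' @param threshold_uV artifact threshold.
#' @param wavelet_number Morlet cycles.
#' @param baseline_window,crop_window ms pairs.
#' @param mode baseline mode.
#' @return a [source_spectrogram()].
#' @export
preprocess_epochs <- function(epochs, lead_field, lesion_side = "left",
                              frequencies = 4:48, band = c(4, 48),
                              threshold_uV = 500, wavelet_number = 7,
                              baseline_window = c(-850, -800),
                              crop_window = c(-500, 800),
                              mode = "percent") {
  if (!all(epochs$trial_mask)) {
    keep <- which(epochs$trial_mask)
    epochs$data <- epochs$data[, , keep, drop = FALSE]
    epochs$trial_mask <- epochs$trial_mask[keep]
  }
  epochs <- bandpass_epochs(epochs, band[1], band[2])
  epochs <- reject_artifacts(epochs, threshold_uV)$epochs
  epochs <- flip_hemispheres(epochs, lesion_side)
  series <- project_to_sources(epochs, lead_field)
  tp <- morlet_power(series, frequencies, wavelet_number)
  average_and_baseline(tp, baseline_window, crop_window, mode,
                       source_labels = colnames(lead_field))
}
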