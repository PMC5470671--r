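#' Reduce a spectrogram to frequency modes
#'
#' SVD of the sources-stacked frequency x time matrix; the projector
#' maps the frequency grid to the top `n_modes` left singular vectors
#' and back. The energy retained is the cumulative squared singular
#' value fraction.
#'
#' @param spec a [source_spectrogram()].
#' @param n_modes number of modes, `1 <= n_modes <= n_frequencies`.
#' @return list `coefficients` (sources x modes x time),
#'   `projector` (frequencies x modes), `singular_values`,
#'   `energy_retained`, `reconstruction_error` (energy of discarded
#'   singular values).
#' @export
reduce_to_modes <- function(spec, n_modes) {
  nf <- length(spec$frequencies)
  if (n_modes < 1) stop("n_modes must be >= 1")
  if (n_modes > nf) stop("n_modes cannot exceed the number of frequencies")
  ns <- length(spec$source_labels)
  nt <- length(spec$times)
  # frequencies x (sources * time)
  X <- matrix(aperm(spec$power, c(2, 1, 3)), nrow = nf)
  sv <- svd(X)
  P <- sv$u[, seq_len(n_modes), drop = FALSE]
  coef <- t(P) %*% X
  coefficients <- aperm(array(coef, c(n_modes, ns, nt)), c(2, 1, 3))
  energy <- sv$d^2
  list(coefficients = coefficients, projector = P,
       singular_values = sv$d,
       energy_retained = sum(energy[seq_len(n_modes)]) / max(sum(energy), .Machine$double.eps),
       reconstruction_error = sum(energy[-seq_len(n_modes)]))
}

#' Project a spectrogram onto the four-band grid
#'
#' Averages frequency bins into bands and relabels the grid with the
#' band-center frequencies. This fixed "band basis" is the default
#' reduced space on which coupling models are fitted.
#'
#' @param spec a [source_spectrogram()].
#' @param bands a [band_scheme()].
#' @return a [source_spectrogram()] with one bin per band.
#' @export
project_to_bands <- function(spec, bands = band_scheme()) {
  P <- band_projector(spec$frequencies, bands)
  ns <- length(spec$source_labels)
  nt <- length(spec$times)
  out <- array(0, c(ns, nrow(P), nt))
  for (s in seq_len(ns)) out[s, , ] <- P %*% spec$power[s, , ]
  source_spectrogram(out, band_centers(bands), spec$times,
                     spec$source_labels, spec$n_trials_used)
}
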