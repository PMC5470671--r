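#' Integrate the induced-power forward model
#'
#' Solves the linear state equation `dg/dt = exp(logtau) (A g + C u(t))`
#' where `g` stacks induced power (percent change from baseline) over
#' sources x frequencies, `A` is assembled from the coupling parameters
#' and `u(t)` is a Gaussian cue bump. Integration is fixed-step RK4;
#' the state starts at baseline (`g = 0`) at the first requested time.
#'
#' @param model a [model_spec()].
#' @param params a conforming [coupling_params()].
#' @param frequencies frequency grid, Hz (default: the band centers, the
#'   "band-space" grid models are fitted on).
#' @param times observation times, ms relative to the cue.
#' @param input_onset cue time, seconds (0 = cue).
#' @param input_sigma width of the Gaussian cue bump, seconds.
#' @param dt integration step, seconds.
#' @param stability_bound error if the largest real eigenvalue part of
#'   the state matrix exceeds this (diverging trajectory).
#' @param check if `TRUE`, verify `params` conform to `model`.
#' @return a [source_spectrogram()].
#' @export
simulate_induced_power <- function(model, params,
                                   frequencies = band_centers(params$bands),
                                   times = seq(-500, 800, by = 50),
                                   input_onset = 0, input_sigma = 0.05,
                                   dt = 0.005, stability_bound = 1e-8,
                                   check = TRUE) {
  if (check) check_conform(params, model)
  fs <- full_state_matrix(params, model, frequencies)
  marg <- stability_margin(fs$A)
  if (marg > stability_bound)
    stop(sprintf(
      "unstable state matrix: largest eigenvalue real part %.4g exceeds bound %.4g; trajectories diverge",
      marg, stability_bound))
  t0 <- min(times) / 1000
  t1 <- max(times) / 1000
  nsteps <- max(1L, as.integer(ceiling((t1 - t0) / dt - 1e-9)))
  g <- rk4_forward_cpp(fs$A, fs$C, params$logtau, t0, dt, nsteps,
                       input_onset, input_sigma, numeric(nrow(fs$A)))
  grid_ms <- (t0 + dt * (0:nsteps)) * 1000
  # interpolate each state row onto the requested observation times
  gt <- apply(g, 1, function(row)
    approx(grid_ms, row, xout = times, rule = 2)$y)
  gt <- matrix(gt, nrow = length(times)) # times x states
  ns <- length(model$sources)
  nf <- length(frequencies)
  power <- aperm(array(t(gt), c(nf, ns, length(times))), c(2, 1, 3))
  source_spectrogram(power, frequencies, times, model$sources)
}

#' @rdname simulate_induced_power
#' @details `integrate_forward()` is the model-side name for the same
#'   computation (a single shared implementation).
#' @export
integrate_forward <- simulate_induced_power
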