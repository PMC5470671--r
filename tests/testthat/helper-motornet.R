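# Shared fixture builders; everything is generated in code at test time.

# small, fast simulation settings (reduced sampling/trials; semantics
# unchanged from the defaults)
tiny_config <- function(...) {
  args <- utils::modifyList(list(sample_rate = 200, n_trials = 4L,
                                 noise_sd = 0.5, seed = 7L), list(...))
  do.call(simulation_config, args)
}

# epochs containing a single known sinusoid on every channel
sine_epochs <- function(freq = 20, fs = 200, n_channels = 4, n_trials = 2,
                        amplitude = 1, window = c(-1500, 2000)) {
  times <- seq(window[1], window[2], by = 1000 / fs) / 1000
  x <- amplitude * sin(2 * pi * freq * times)
  data <- array(rep(x, each = n_channels), c(n_channels, length(times), 1))
  data <- array(data, c(n_channels, length(times), n_trials))
  trial_epochs(data, fs, default_montage()$channels[seq_len(n_channels)],
               window)
}

# amplitude spectrum via FFT, for filter checks
fft_amp <- function(x, fs, freq) {
  n <- length(x)
  sp <- abs(stats::fft(x))[seq_len(floor(n / 2))] * 2 / n
  fgrid <- (seq_len(floor(n / 2)) - 1) * fs / n
  sp[which.min(abs(fgrid - freq))]
}

# matched generator/prior settings used by the simulation studies
study_priors <- function() {
  default_priors(sd_linear = 0.4, sd_cross = 0.3, sd_intrinsic = 0.3,
                 sd_input = 150)
}

# one noisy band-space dataset from a given architecture
make_dataset <- function(model, seed, noise_frac = 0.1,
                         times = seq(-500, 800, by = 25), sd_cross = 0.3) {
  set.seed(seed)
  truth <- random_coupling(model, sd_cross = sd_cross)
  spec <- simulate_induced_power(model, truth, times = times)
  ns <- noise_frac * sqrt(mean(spec$power^2))
  spec$power <- spec$power +
    array(rnorm(length(spec$power), 0, ns), dim(spec$power))
  list(truth = truth, spec = spec)
}
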