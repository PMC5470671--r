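#' Simulation configuration
#'
#' Defaults mirror the acquisition conditions of the movement-task EEG
#' study the pipeline is built for: 32-channel 10-20 montage, 2000 Hz
#' sampling, 80 trials, a -1500 to 2000 ms peristimulus window and a
#' 4-48 Hz analysis band. Tests and demos pass reduced values; the
#' semantics do not change.
#'
#' @param n_sources number of cortical sources (5).
#' @param frequencies strictly increasing frequency grid within 4-48 Hz.
#' @param sample_rate Hz.
#' @param n_trials trials per subject.
#' @param n_channels EEG channels (must exceed `n_sources`).
#' @param noise_sd sensor noise standard deviation, microvolts.
#' @param amplitude baseline source oscillation amplitude, microvolts.
#' @param seed integer; fully determines all simulated outputs.
#' @param group_effect additive shift applied to the three designated
#'   SMA/cM1 beta couplings for the favorable class (see
#'   [generate_cohort()]).
#' @param subject_sd between-subject jitter (sd) on nonzero couplings.
#' @param epoch_window ms pair relative to the cue.
#' @param bands the [band_scheme()] structuring the coupling.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_sources = 5L, frequencies = 4:48,
                              sample_rate = 2000, n_trials = 80L,
                              n_channels = 32L, noise_sd = 1,
                              amplitude = 5, seed = 1L,
                              group_effect = 0.5, subject_sd = 0.15,
                              epoch_window = c(-1500, 2000),
                              bands = band_scheme()) {
  if (any(diff(frequencies) <= 0)) stop("frequencies must be strictly increasing")
  if (min(frequencies) < 4 || max(frequencies) > 48)
    stop("frequencies must lie within [4, 48] Hz")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_channels <= n_sources) stop("need more channels than sources")
  structure(list(n_sources = as.integer(n_sources), frequencies = frequencies,
                 sample_rate = sample_rate, n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels), noise_sd = noise_sd,
                 amplitude = amplitude, seed = as.integer(seed),
                 group_effect = group_effect, subject_sd = subject_sd,
                 epoch_window = epoch_window, bands = bands),
            class = "simulation_config")
}

# Idealized 10-20 electrode positions (mm): symmetric spherical layout,
# azimuth measured from the nasion axis (positive right), inclination
# from the vertex. Used only to give the synthetic lead field a
# spatially coherent, mirror-symmetric topography; not a head model.
electrode_positions <- function(channels = default_montage()$channels) {
  ang <- list(
    Fp1 = c(-18, 90), Fp2 = c(18, 90), F7 = c(-54, 90), F8 = c(54, 90),
    F3 = c(-39, 62), F4 = c(39, 62), Fz = c(0, 46),
    FC5 = c(-69, 72), FC6 = c(69, 72), FC1 = c(-45, 32), FC2 = c(45, 32),
    T7 = c(-90, 90), T8 = c(90, 90), C3 = c(-90, 46), C4 = c(90, 46),
    Cz = c(0, 0),
    CP5 = c(-111, 72), CP6 = c(111, 72), CP1 = c(-135, 32), CP2 = c(135, 32),
    TP9 = c(-95, 105), TP10 = c(95, 105),
    P7 = c(-126, 90), P8 = c(126, 90), P3 = c(-141, 62), P4 = c(141, 62),
    Pz = c(180, 46), PO9 = c(-144, 100), PO10 = c(144, 100),
    O1 = c(-162, 90), O2 = c(162, 90), Oz = c(180, 90)
  )
  missing <- setdiff(channels, names(ang))
  if (length(missing)) stop("no idealized position for: ",
                            paste(missing, collapse = ", "))
  radius <- 92
  center <- c(0, -18, 18)
  t(vapply(channels, function(ch) {
    az <- ang[[ch]][1] * pi / 180
    incl <- ang[[ch]][2] * pi / 180
    center + radius * c(sin(incl) * sin(az), sin(incl) * cos(az), cos(incl))
  }, numeric(3)))
}

#' Synthetic lead field
#'
#' Channels x sources gain matrix built from the distance between
#' idealized scalp electrode positions and the MNI source coordinates
#' (Gaussian falloff), optionally perturbed by seeded Gaussian jitter,
#' with columns scaled to unit norm. Mirror-symmetric sources map to
#' mirror-symmetric topographies, which [flip_hemispheres()] relies on.
#'
#' @param n_channels number of channels (first `n_channels` of the
#'   montage); must exceed the number of sources.
#' @param source_coords sources x 3 matrix of MNI mm coordinates
#'   (default: the five motor sources).
#' @param montage a [default_montage()].
#' @param spread Gaussian falloff scale, mm.
#' @param jitter_sd sd of multiplicative log-normal jitter (0 = purely
#'   geometric, the default).
#' @param seed seed for the jitter draw.
#' @return channels x sources matrix with unit-norm, full-rank columns.
#' @export
make_lead_field <- function(n_channels = 32L,
                            source_coords = default_source_coords(),
                            montage = default_montage(), spread = 45,
                            jitter_sd = 0, seed = 1L) {
  ns <- nrow(source_coords)
  if (n_channels <= ns)
    stop("rank error: need more channels (", n_channels,
         ") than sources (", ns, ")")
  pos <- electrode_positions(montage$channels[seq_len(n_channels)])
  L <- matrix(0, n_channels, ns,
              dimnames = list(rownames(pos), rownames(source_coords)))
  for (s in seq_len(ns)) {
    d2 <- rowSums((pos - matrix(source_coords[s, ], n_channels, 3,
                                byrow = TRUE))^2)
    L[, s] <- exp(-d2 / (2 * spread^2))
  }
  if (jitter_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    L <- L * exp(matrix(rnorm(length(L), 0, jitter_sd), nrow(L)))
  }
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  if (qr(L)$rank < ns) stop("rank error: lead field is column rank deficient")
  L
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Simulate cue-locked EEG trials for one subject
#'
#' Each source emits a sum of sinusoids at the band-center frequencies
#' whose amplitude envelopes follow the induced-power forward model
#' (amplitude = sqrt of absolute power, with baseline power 1);
#' channel data are `lead_field %*% sources` plus Gaussian sensor
#' noise. Trials differ only by oscillation phase and noise.
#'
#' @param model a [model_spec()].
#' @param params conforming [coupling_params()]; the subject's coupling.
#' @param lead_field channels x sources gain matrix.
#' @param config a [simulation_config()].
#' @param seed seed (default `config$seed`).
#' @return a [trial_epochs()].
#' @export
simulate_eeg_trials <- function(model, params, lead_field, config,
                                seed = config$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fs <- config$sample_rate
  win <- config$epoch_window
  times_ms <- seq(win[1], win[2], by = 1000 / fs)
  carriers <- band_centers(config$bands)
  env_grid <- seq(win[1], win[2], by = 10)
  spec <- simulate_induced_power(model, params, frequencies = carriers,
                                 times = env_grid)
  ns <- length(model$sources)
  nb <- length(carriers)
  nt <- length(times_ms)
  # amplitude envelope per source x band on the sample grid
  amp <- array(0, c(ns, nb, nt))
  for (s in seq_len(ns)) for (b in seq_len(nb)) {
    g <- approx(env_grid, spec$power[s, b, ], xout = times_ms, rule = 2)$y
    amp[s, b, ] <- config$amplitude * sqrt(pmax(0, 1 + g / 100))
  }
  tsec <- times_ms / 1000
  data <- array(0, c(nrow(lead_field), nt, config$n_trials))
  for (tr in seq_len(config$n_trials)) {
    src <- matrix(0, ns, nt)
    for (s in seq_len(ns)) for (b in seq_len(nb)) {
      phase <- runif(1, 0, 2 * pi)
      src[s, ] <- src[s, ] + amp[s, b, ] * sin(2 * pi * carriers[b] * tsec + phase)
    }
    noise <- if (config$noise_sd > 0)
      matrix(rnorm(nrow(lead_field) * nt, 0, config$noise_sd),
             nrow(lead_field)) else 0
    data[, , tr] <- lead_field %*% src + noise
  }
  trial_epochs(data, fs, rownames(lead_field), win)
}

#' Generate a synthetic patient cohort with known ground truth
#'
#' Draws a template coupling for each class from a base architecture,
#' applies the favorable-class shift on the three designated beta
#' connections (SMA->cPM more inhibitory by `group_effect`; SMA->cM1
#' and cM1->SMA more excitatory by `group_effect`), jitters nonzero
#' couplings per subject, and writes a clinical table whose pre/post
#' scores are consistent with each subject's label under the
#' 10%-of-maximum improvement rule.
#'
#' @param n_favorable,n_poor class sizes (>= 1).
#' @param config a [simulation_config()].
#' @param model architecture generating the data (default DCM1).
#' @return list with `clinical` (data frame in the Table-1 schema),
#'   `ground_truth` (list: `model`, `coupling` per subject, `labels`,
#'   `lead_field`).
#' @export
generate_cohort <- function(n_favorable, n_poor,
                            config = simulation_config(),
                            model = build_model_space()$DCM1) {
  if (n_favorable < 1 || n_poor < 1) stop("class counts must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  base <- random_coupling(model, config$bands)
  # fixed signed baselines on the three designated beta couplings so the
  # favorable-class shift has a consistent excitatory/inhibitory reading:
  # SMA suppresses cPM (more so when favorable), SMA inhibits cM1 (less
  # so when favorable), cM1 facilitates SMA (more so when favorable)
  base$A[["SMA->cPM"]]["beta", "beta"] <- -0.4
  base$A[["SMA->cM1"]]["beta", "beta"] <- -0.8
  base$A[["cM1->SMA"]]["beta", "beta"] <- 0.4
  n <- n_favorable + n_poor
  labels <- c(rep("F", n_favorable), rep("P", n_poor))
  beta_row <- "beta"
  shift <- function(p, ge) {
    p$A[["SMA->cPM"]][beta_row, beta_row] <-
      p$A[["SMA->cPM"]][beta_row, beta_row] - ge
    p$A[["SMA->cM1"]][beta_row, beta_row] <-
      p$A[["SMA->cM1"]][beta_row, beta_row] + ge
    p$A[["cM1->SMA"]][beta_row, beta_row] <-
      p$A[["cM1->SMA"]][beta_row, beta_row] + ge
    p
  }
  jitter <- function(p) {
    jit <- function(M) {
      nz <- M != 0
      M[nz] <- M[nz] + rnorm(sum(nz), 0, config$subject_sd)
      M
    }
    for (i in seq_along(p$A)) p$A[[i]] <- jit(p$A[[i]])
    for (i in seq_along(p$intrinsic)) p$intrinsic[[i]] <- jit(p$intrinsic[[i]])
    p$C <- jit(p$C)
    p
  }
  coupling <- vector("list", n)
  for (i in seq_len(n)) {
    p0 <- if (labels[i] == "F") shift(base, config$group_effect) else base
    for (try in 1:50) {
      p <- jitter(p0)
      if (stability_margin(full_state_matrix(p, model)$A) < -0.02) break
      if (try == 50) stop("could not stabilize subject coupling")
    }
    coupling[[i]] <- p
  }
  clinical <- synth_clinical_rows(labels)
  lead_field <- make_lead_field(config$n_channels)
  list(clinical = clinical,
       ground_truth = list(model = model, coupling = coupling,
                           labels = labels, lead_field = lead_field))
}

# Clinical rows consistent with the outcome rule: favorable subjects
# exceed at least one 10%-of-maximum improvement threshold (FMA 6.6,
# WMFT 7.5, TEMPA 16.2), poor subjects stay strictly below all three.
synth_clinical_rows <- function(labels, rule = outcome_rule()) {
  n <- length(labels)
  draw_delta <- function(fav) {
    if (fav) {
      which_scale <- sample(c("fma", "wmft", "tempa"), 1,
                            prob = c(0.6, 0.25, 0.15))
      d <- c(fma = abs(rnorm(1, 3, 2)), wmft = abs(rnorm(1, 3, 2)),
             tempa = abs(rnorm(1, 5, 4)))
      d[which_scale] <- rule[[which_scale]] + abs(rnorm(1, 4, 3))
      d
    } else {
      c(fma = min(rule$fma - 0.6, rnorm(1, 1.5, 2)),
        wmft = min(rule$wmft - 0.6, rnorm(1, 2, 2)),
        tempa = min(rule$tempa - 0.6, rnorm(1, 2, 4)))
    }
  }
  rows <- lapply(seq_len(n), function(i) {
    d <- pmin(round(draw_delta(labels[i] == "F"), 1), 30)
    # choose pre scores so the score ceilings (FMA 66, TEMPA 0) cannot
    # clip an improvement back below its threshold
    fma_pre <- round(runif(1, 8, min(55, 66 - d["fma"] - 0.5)))
    tempa_pre <- -round(runif(1, max(25, d["tempa"] + 1), 95))
    wmft_pre <- round(runif(1, 12, 55))
    data.frame(
      dataset = "training", id = i,
      gender = sample(c("M", "F"), 1, prob = c(0.7, 0.3)),
      age = round(rnorm(1, 56, 13)),
      time_poststroke = max(1, round(exp(rnorm(1, log(6), 0.6)))),
      hand_dominance = sample(c("R", "L"), 1, prob = c(0.92, 0.08)),
      stroke_type = sample(c("I", "H"), 1),
      affected_hemisphere = sample(c("L", "R"), 1),
      mri_report = "synthetic", lesion_site = sample(c("subcortical", "cortical"), 1, prob = c(0.65, 0.35)),
      brunnstrom_proximal = sample(2:5, 1), brunnstrom_distal = sample(2:5, 1),
      fma_pre = fma_pre, fma_post = fma_pre + d[["fma"]],
      tempa_pre = tempa_pre, tempa_post = min(0, tempa_pre + d[["tempa"]]),
      wmft_pre = wmft_pre, wmft_post = wmft_pre + d[["wmft"]],
      true_condition = labels[i], prediction = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
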