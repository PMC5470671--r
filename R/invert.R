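#' Default shrinkage priors for model inversion
#'
#' Zero-mean Gaussian shrinkage on coupling entries (variance 1/16 on
#' cross-frequency terms, looser on within-band terms), intrinsic decay
#' centered at -2 per second, diffuse input weights and a tight
#' log-normal prior on the global rate scale.
#'
#' @param sd_linear sd of within-band extrinsic couplings.
#' @param sd_cross sd of cross-frequency couplings.
#' @param intrinsic_mean,sd_intrinsic prior on intrinsic decay.
#' @param sd_input sd of input weights.
#' @param sd_logtau sd of the log rate scale.
#' @return named list of prior settings.
#' @export
default_priors <- function(sd_linear = 0.5, sd_cross = 0.25,
                           intrinsic_mean = -2, sd_intrinsic = 1,
                           sd_input = 200, sd_logtau = 0.1) {
  list(sd_linear = sd_linear, sd_cross = sd_cross,
       intrinsic_mean = intrinsic_mean, sd_intrinsic = sd_intrinsic,
       sd_input = sd_input, sd_logtau = sd_logtau)
}

# Free-parameter bookkeeping: one row per parameter with its position
# in the full band-space state matrix (0-based for the integrator),
# its kind and its Gaussian prior.
param_table <- function(model, bands = band_scheme(),
                        priors = default_priors()) {
  nb <- length(bands)
  bn <- names(bands)
  src <- model$sources
  srow <- function(s, b) (match(s, src) - 1) * nb + b # 1-based state index
  rows <- list()
  add <- function(name, kind, component, bt, bs, row, col, pm, psd) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, kind = kind, component = component,
      bt = bt, bs = bs, row = row, col = col, pm = pm, psd = psd,
      stringsAsFactors = FALSE)
  }
  ids <- edge_ids(model$edges)
  for (i in seq_len(nrow(model$edges))) {
    e <- model$edges[i, ]
    for (bt in seq_len(nb)) for (bs in seq_len(nb)) {
      if (bt != bs && !e$nonlinear) next
      add(sprintf("%s.%s<-%s", ids[i], bn[bt], bn[bs]), "A", ids[i],
          bt, bs, srow(e$to, bt), srow(e$from, bs),
          0, if (bt == bs) priors$sd_linear else priors$sd_cross)
    }
  }
  for (s in src) {
    for (bt in seq_len(nb)) for (bs in seq_len(nb)) {
      if (bt != bs && !model$intrinsic_nonlinear) next
      add(sprintf("intrinsic.%s.%s<-%s", s, bn[bt], bn[bs]), "intrinsic", s,
          bt, bs, srow(s, bt), srow(s, bs),
          if (bt == bs) priors$intrinsic_mean else 0,
          if (bt == bs) priors$sd_intrinsic else priors$sd_cross)
    }
  }
  for (s in model$input_targets) for (b in seq_len(nb))
    add(sprintf("input.%s.%s", s, bn[b]), "C", s, b, NA,
        srow(s, b), NA, 0, priors$sd_input)
  add("logtau", "logtau", "global", NA, NA, NA, NA, 0, priors$sd_logtau)
  do.call(rbind, rows)
}

# Rebuild a coupling_params object from a parameter vector.
theta_to_params <- function(theta, pt, model, bands = band_scheme()) {
  p <- coupling_params(model, bands)
  for (s in model$sources) p$intrinsic[[s]][] <- 0
  for (j in seq_len(nrow(pt))) {
    k <- pt$kind[j]
    if (k == "A") {
      p$A[[pt$component[j]]][pt$bt[j], pt$bs[j]] <- theta[j]
    } else if (k == "intrinsic") {
      p$intrinsic[[pt$component[j]]][pt$bt[j], pt$bs[j]] <- theta[j]
    } else if (k == "C") {
      p$C[pt$component[j], pt$bt[j]] <- theta[j]
    } else p$logtau <- theta[j]
  }
  p
}

# Flatten coupling_params into the parameter vector defined by pt.
params_to_theta <- function(params, pt) {
  vapply(seq_len(nrow(pt)), function(j) {
    k <- pt$kind[j]
    if (k == "A") params$A[[pt$component[j]]][pt$bt[j], pt$bs[j]]
    else if (k == "intrinsic") params$intrinsic[[pt$component[j]]][pt$bt[j], pt$bs[j]]
    else if (k == "C") params$C[pt$component[j], pt$bt[j]]
    else params$logtau
  }, numeric(1))
}

# state matrix and input vector from theta (band-space grid)
theta_to_system <- function(theta, pt, n) {
  A <- matrix(0, n, n)
  Cv <- numeric(n)
  isA <- pt$kind %in% c("A", "intrinsic")
  for (j in which(isA)) A[pt$row[j], pt$col[j]] <- A[pt$row[j], pt$col[j]] + theta[j]
  for (j in which(pt$kind == "C")) Cv[pt$row[j]] <- theta[j]
  logtau <- theta[pt$kind == "logtau"]
  list(A = A, C = Cv, logtau = if (length(logtau)) logtau else 0)
}

#' Invert a coupling model by variational Laplace
#'
#' Gauss-Newton ascent with Levenberg-style damping on the free energy
#' `F = accuracy - complexity` under Gaussian priors and likelihood.
#' The observation model is the forward integration of the state
#' equation on the band-space grid (one frequency bin per band); data
#' with a finer frequency grid should be reduced first with
#' [project_to_bands()]. Observation noise is a single variance per
#' source, profile-updated within the scheme. Accepted iterations never
#' decrease F; convergence is declared when the relative change in F
#' stays below `tol` for 3 successive iterations.
#'
#' @param model a [model_spec()].
#' @param data a [source_spectrogram()] with one bin per band and
#'   uniformly spaced times.
#' @param priors a [default_priors()] list.
#' @param bands a [band_scheme()].
#' @param options list: `max_iter` (64), `tol` (absolute change in F,
#'   nats; 0.05), `dt` integration step in seconds (0.01),
#'   `input_onset` (0 s), `input_sigma` (0.05 s).
#' @return object of class `dcm_fit`: posterior mean `params`
#'   ([coupling_params()]) and `theta`, posterior covariance `Sigma`,
#'   `free_energy` (nats), its `accuracy` term, `predicted`
#'   spectrogram, per-source noise variances `sigma2`, the
#'   `param_table`, `converged`, `iterations`.
#' @export
invert_dcm <- function(model, data, priors = default_priors(),
                       bands = band_scheme(), options = list()) {
  opt <- modifyList(list(max_iter = 64L, tol = 0.05, dt = 0.01,
                         input_onset = 0, input_sigma = 0.05), options)
  nb <- length(bands)
  if (length(data$frequencies) != nb)
    stop("data must have one frequency bin per band; see project_to_bands()")
  if (!all(is.finite(data$power))) stop("data must be finite")
  src <- model$sources
  ns <- length(src)
  n <- ns * nb
  pt <- param_table(model, bands, priors)
  p <- nrow(pt)

  times_s <- data$times / 1000
  spacing <- diff(times_s)
  if (max(abs(spacing - spacing[1])) > 1e-9)
    stop("data times must be uniformly spaced")
  sub <- max(1L, round(spacing[1] / opt$dt))
  dt <- spacing[1] / sub
  nobs <- length(times_s)
  obs_step <- as.integer((seq_len(nobs) - 1) * sub)
  nsteps <- obs_step[nobs]
  t0 <- times_s[1]

  # y ordered as (band within source within time)
  y <- as.numeric(matrix(aperm(data$power, c(2, 1, 3)), nrow = n))
  src_of_row <- rep(rep(src, each = nb), nobs)
  ndat_per_src <- nb * nobs

  mu0 <- pt$pm
  P0inv <- diag(1 / pt$psd^2, p)
  ld_prior <- sum(2 * log(pt$psd))

  integrate_theta <- function(theta, sens = TRUE) {
    sys <- theta_to_system(theta, pt, n)
    if (sens) {
      isA <- pt$kind %in% c("A", "intrinsic")
      ptype <- ifelse(isA, 0L, ifelse(pt$kind == "C", 1L, 2L))
      prow <- ifelse(is.na(pt$row), 0L, pt$row - 1L)
      pcol <- ifelse(is.na(pt$col), 0L, pt$col - 1L)
      rk4_sensitivities_cpp(sys$A, sys$C, sys$logtau, t0, dt, nsteps,
                            opt$input_onset, opt$input_sigma,
                            as.integer(prow), as.integer(pcol),
                            as.integer(ptype), obs_step)
    } else {
      g <- rk4_forward_cpp(sys$A, sys$C, sys$logtau, t0, dt, nsteps,
                           opt$input_onset, opt$input_sigma, numeric(n))
      list(g = g[, obs_step + 1, drop = FALSE])
    }
  }

  sse_by_source <- function(e) {
    vapply(src, function(s) sum(e[src_of_row == s]^2), numeric(1))
  }

  free_energy <- function(e, sigma2, theta, H = NULL) {
    sse <- sse_by_source(e)
    acc <- -0.5 * sum(sse / sigma2 + ndat_per_src * log(2 * pi * sigma2))
    d <- theta - mu0
    cmpl <- 0.5 * sum(d^2 / pt$psd^2) + 0.5 * ld_prior
    if (!is.null(H)) {
      ldH <- determinant(H, logarithm = TRUE)$modulus
      cmpl <- cmpl + 0.5 * as.numeric(ldH)
    }
    acc - cmpl
  }

  theta <- mu0
  fit0 <- integrate_theta(theta)
  e <- y - as.numeric(fit0$g)
  sigma2 <- pmax(sse_by_source(e) / ndat_per_src, 1e-8)
  J <- fit0$S
  w <- 1 / sigma2[match(src_of_row, src)]
  H <- crossprod(J * sqrt(w)) + P0inv
  Fcur <- free_energy(e, sigma2, theta, H)
  lambda <- 1e-4
  n_small <- 0L
  converged <- FALSE
  iter <- 0L
  warn_flag <- NULL

  while (iter < opt$max_iter) {
    iter <- iter + 1L
    grad <- crossprod(J, w * e) - P0inv %*% (theta - mu0)
    if (!all(is.finite(grad))) {
      warn_flag <- "numerical error: non-finite gradient"
      break
    }
    accepted <- FALSE
    for (attempt in 1:8) {
      Hd <- H + lambda * diag(diag(H), p)
      step <- tryCatch(solve(Hd, grad), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- theta + as.numeric(step)
      ok <- tryCatch({
        fitc <- integrate_theta(cand)
        all(is.finite(fitc$g)) && all(is.finite(fitc$S))
      }, error = function(e) FALSE)
      if (ok) {
        ec <- y - as.numeric(fitc$g)
        s2c <- pmax(sse_by_source(ec) / ndat_per_src, 1e-8)
        wc <- 1 / s2c[match(src_of_row, src)]
        Hc <- crossprod(fitc$S * sqrt(wc)) + P0inv
        Fc <- free_energy(ec, s2c, cand, Hc)
        if (is.finite(Fc) && Fc > Fcur - 1e-12) {
          n_small <- if (abs(Fc - Fcur) < opt$tol) n_small + 1L else 0L
          theta <- cand; e <- ec; sigma2 <- s2c; w <- wc
          J <- fitc$S; H <- Hc; Fcur <- Fc
          lambda <- max(lambda / 4, 1e-8)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) { n_small <- n_small + 1L }
    if (n_small >= 3L) { converged <- TRUE; break }
  }
  if (!converged && is.null(warn_flag))
    warn_flag <- "maximum iterations reached without convergence"
  if (!is.null(warn_flag)) warning(warn_flag)

  sse_fin <- sse_by_source(e)
  accuracy <- -0.5 * sum(sse_fin / sigma2 +
                           ndat_per_src * log(2 * pi * sigma2))
  Sigma <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  pred <- integrate_theta(theta, sens = FALSE)$g
  pred_arr <- aperm(array(pred, c(nb, ns, nobs)), c(2, 1, 3))
  predicted <- source_spectrogram(pred_arr, data$frequencies, data$times,
                                  src, data$n_trials_used)
  structure(list(
    params = theta_to_params(theta, pt, model, bands),
    theta = setNames(theta, pt$name), Sigma = Sigma,
    free_energy = Fcur, accuracy = accuracy, predicted = predicted,
    sigma2 = setNames(sigma2, src),
    param_table = pt, converged = converged, iterations = iter,
    model = model$name, bands = bands),
    class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> model %s: F = %.2f nats, %d parameters, %d iterations%s\n",
              x$model, x$free_energy, length(x$theta), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
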