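#' Fixed-effects Bayesian model selection
#'
#' Treats every subject as sharing one model: log group evidences are
#' the column sums of the free-energy matrix and posterior model
#' probabilities are their softmax (computed via log-sum-exp).
#'
#' @param F subjects x models matrix of free energies (nats); at least
#'   2 columns, finite.
#' @return named numeric vector of posterior model probabilities.
#' @export
ffx_compare <- function(F) {
  F <- as.matrix(F)
  if (ncol(F) < 2) stop("need at least 2 models")
  if (!all(is.finite(F))) stop("free energies must be finite")
  s <- colSums(F)
  z <- s - max(s)
  p <- exp(z) / sum(exp(z))
  setNames(p, colnames(F))
}

#' Random-effects Bayesian model selection
#'
#' Variational estimation of a Dirichlet posterior over model
#' frequencies in the population (uniform prior `alpha0 = 1` per
#' model), iterated to convergence, followed by Monte-Carlo estimation
#' of each model's exceedance probability — the probability that its
#' population frequency is the largest.
#'
#' @param F subjects x models free-energy matrix (nats).
#' @param seed seed for the Dirichlet sampler.
#' @param alpha0 prior concentration per model.
#' @param n_samples Monte-Carlo draws (>= 1e5).
#' @param max_iter,tol convergence controls for the variational loop.
#' @return object of class `bms_result`: `dirichlet_alpha`,
#'   `expected_prob`, `exceedance_prob`, `ffx_posterior`,
#'   `best_per_subject` (argmax model per subject), `n_samples`.
#' @export
rfx_compare <- function(F, seed = 1L, alpha0 = 1, n_samples = 1e6,
                        max_iter = 200L, tol = 1e-8) {
  F <- as.matrix(F)
  if (ncol(F) < 2) stop("need at least 2 models")
  if (!all(is.finite(F))) stop("free energies must be finite")
  K <- ncol(F)
  N <- nrow(F)
  alpha <- rep(alpha0, K)
  for (it in seq_len(max_iter)) {
    lu <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    g <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
    if (it == max_iter)
      stop("RFX variational loop did not converge; last alpha: ",
           paste(signif(alpha, 4), collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # Dirichlet draws via normalized gammas
  draws <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                  n_samples, K)
  winner <- max.col(draws, ties.method = "first")
  xp <- tabulate(winner, K) / n_samples
  nm <- colnames(F)
  structure(list(
    dirichlet_alpha = setNames(alpha, nm),
    expected_prob = setNames(alpha / sum(alpha), nm),
    exceedance_prob = setNames(xp, nm),
    ffx_posterior = ffx_compare(F),
    best_per_subject = if (!is.null(nm)) nm[max.col(F, ties.method = "first")]
                       else max.col(F, ties.method = "first"),
    n_subjects = N, n_samples = n_samples),
    class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>\n")
  m <- rbind(expected = x$expected_prob, exceedance = x$exceedance_prob)
  print(round(m, 4))
  invisible(x)
}

#' Read/write free-energy evidence matrices
#'
#' CSV with one row per subject, one column per model.
#' @param F subjects x models matrix.
#' @param path file path.
#' @export
write_evidence <- function(F, path) {
  write.csv(as.data.frame(F), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) as.matrix(read.csv(path, check.names = FALSE))
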