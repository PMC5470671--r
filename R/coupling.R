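#' Coupling parameters of a model
#'
#' Coupling is parameterized at band resolution: each directed edge
#' carries a bands x bands matrix mapping source-band power to the rate
#' of change of target-band power; linear edges are restricted to the
#' within-band diagonal, nonlinear edges may populate off-diagonal
#' (cross-frequency) entries. Each source has an intrinsic (within
#' source) matrix of the same form whose diagonal holds the
#' self-decay rates (negative for stability), and an input weight per
#' band. A global log rate scale `logtau` multiplies the whole state
#' equation.
#'
#' @param model a [model_spec()].
#' @param bands a [band_scheme()].
#' @return object of class `coupling_params` with all couplings zero and
#'   intrinsic decay at -2 per second.
#' @export
coupling_params <- function(model, bands = band_scheme()) {
  nb <- length(bands)
  bn <- names(bands)
  zero <- matrix(0, nb, nb, dimnames = list(bn, bn))
  ids <- edge_ids(model$edges)
  A <- setNames(rep(list(zero), length(ids)), ids)
  intrinsic <- setNames(rep(list(zero), length(model$sources)), model$sources)
  for (s in model$sources) diag(intrinsic[[s]]) <- -2
  C <- matrix(0, length(model$sources), nb,
              dimnames = list(model$sources, bn))
  structure(list(A = A, intrinsic = intrinsic, C = C, logtau = 0,
                 bands = bands, model = model$name),
            class = "coupling_params")
}

#' Check that parameters conform to a model architecture
#'
#' Linear edges (and linear intrinsic dynamics) must have zero
#' off-diagonal band entries; parameters must cover exactly the model's
#' edges.
#'
#' @param params a [coupling_params()].
#' @param model the [model_spec()] they should conform to.
#' @return invisibly `TRUE`; otherwise an error.
#' @export
check_conform <- function(params, model) {
  ids <- edge_ids(model$edges)
  if (!identical(sort(names(params$A)), sort(ids)))
    stop("params edges do not match model edges")
  offdiag <- function(M) M[row(M) != col(M)]
  for (i in seq_along(ids)) {
    if (!model$edges$nonlinear[i] &&
        any(offdiag(params$A[[ids[i]]]) != 0))
      stop("linear edge ", ids[i], " has nonzero cross-frequency entries")
  }
  if (!model$intrinsic_nonlinear &&
      any(vapply(params$intrinsic, function(M) any(offdiag(M) != 0), logical(1))))
    stop("linear intrinsic dynamics have nonzero cross-frequency entries")
  off <- setdiff(model$sources, model$input_targets)
  if (length(off) && any(params$C[off, ] != 0))
    stop("input weights on sources outside input_targets")
  invisible(TRUE)
}

#' Assemble the full state matrix on a frequency grid
#'
#' Expands band-level coupling to a `(n_sources*n_freq)` square matrix on
#' an arbitrary frequency grid. A band entry is spread uniformly over
#' the source-band's bins (divided by their count), so band-space and
#' grid-space dynamics agree for band-constant states. On the band-center
#' grid (one bin per band) the expansion is the identity.
#'
#' @param params a [coupling_params()].
#' @param model matching [model_spec()].
#' @param frequencies frequency grid, Hz; default the band centers.
#' @return list `A` (full matrix), `C` (stacked input vector),
#'   `index` (data frame mapping state rows to source/frequency).
#' @export
full_state_matrix <- function(params, model,
                              frequencies = band_centers(params$bands)) {
  bands <- params$bands
  nb <- length(bands)
  fb <- as.integer(band_of(frequencies, bands))
  if (anyNA(fb)) stop("frequencies outside the band scheme")
  nf <- length(frequencies)
  src <- model$sources
  ns <- length(src)
  n <- ns * nf
  # expansion of one band matrix to the grid
  nbin <- tabulate(fb, nb)
  expand <- function(M) {
    G <- M[fb, fb, drop = FALSE] / rep(nbin[fb], each = nf)
    dimnames(G) <- list(frequencies, frequencies)
    G
  }
  A <- matrix(0, n, n)
  idx <- function(s) ((match(s, src) - 1) * nf) + seq_len(nf)
  for (s in src) A[idx(s), idx(s)] <- expand(params$intrinsic[[s]])
  for (i in seq_len(nrow(model$edges))) {
    e <- model$edges[i, ]
    A[idx(e$to), idx(e$from)] <- A[idx(e$to), idx(e$from)] +
      expand(params$A[[edge_ids(model$edges)[i]]])
  }
  Cv <- numeric(n)
  for (s in src) Cv[idx(s)] <- params$C[s, fb] / nbin[fb]
  index <- data.frame(source = rep(src, each = nf),
                      frequency = rep(frequencies, ns))
  list(A = A, C = Cv, index = index, frequencies = frequencies)
}

#' Largest real part of the state-matrix spectrum
#' @keywords internal
stability_margin <- function(A) max(Re(eigen(A, only.values = TRUE)$values))

#' Draw random, stable coupling parameters
#'
#' Nonzero entries are drawn from Gaussians (within-band couplings sd
#' `sd_linear`, cross-band sd `sd_cross`, intrinsic decay `-2` with sd
#' 0.3, input weights sd `sd_input` on the input targets); draws are
#' rejected until the full band-space state matrix is stable.
#'
#' @param model a [model_spec()].
#' @param bands a [band_scheme()].
#' @param sd_linear,sd_cross,sd_input spread of the draws.
#' @param max_tries rejection budget before erroring.
#' @return a stable [coupling_params()].
#' @export
random_coupling <- function(model, bands = band_scheme(), sd_linear = 0.4,
                            sd_cross = 0.25, sd_input = 150,
                            max_tries = 50L) {
  nb <- length(bands)
  for (try in seq_len(max_tries)) {
    p <- coupling_params(model, bands)
    for (i in seq_len(nrow(model$edges))) {
      id <- edge_ids(model$edges)[i]
      d <- rnorm(nb, 0, sd_linear)
      M <- diag(d, nb)
      if (model$edges$nonlinear[i]) {
        M <- M + matrix(rnorm(nb * nb, 0, sd_cross), nb, nb) *
          (1 - diag(nb))
      }
      dimnames(M) <- dimnames(p$A[[id]])
      p$A[[id]] <- M
    }
    for (s in model$sources) {
      M <- diag(-2 + rnorm(nb, 0, 0.3), nb)
      if (model$intrinsic_nonlinear)
        M <- M + matrix(rnorm(nb * nb, 0, sd_cross), nb, nb) * (1 - diag(nb))
      dimnames(M) <- dimnames(p$intrinsic[[s]])
      p$intrinsic[[s]] <- M
    }
    p$C[model$input_targets, ] <- rnorm(length(model$input_targets) * nb,
                                        0, sd_input)
    if (stability_margin(full_state_matrix(p, model)$A) < -0.05) return(p)
  }
  stop("could not draw a stable coupling matrix in ", max_tries, " tries")
}
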