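#' Canonical frequency bands
#'
#' The four bands used throughout the pipeline: theta 4-8 Hz, alpha
#' 8-15 Hz, beta 15-30 Hz, gamma 30-48 Hz. Bins are assigned half-open
#' `[low, high)`; the upper edge of the last band is inclusive so the
#' full 4-48 Hz analysis range is covered.
#'
#' @param theta,alpha,beta,gamma numeric length-2 `c(low, high)` in Hz.
#' @return object of class `band_scheme`: a named list of band edges.
#' @export
band_scheme <- function(theta = c(4, 8), alpha = c(8, 15),
                        beta = c(15, 30), gamma = c(30, 48)) {
  b <- list(theta = theta, alpha = alpha, beta = beta, gamma = gamma)
  lows <- vapply(b, `[`, numeric(1), 1L)
  highs <- vapply(b, `[`, numeric(1), 2L)
  if (any(highs <= lows)) stop("each band must have low < high")
  if (any(diff(lows) <= 0)) stop("bands must be ordered by frequency")
  if (any(abs(highs[-length(b)] - lows[-1]) > 1e-9))
    stop("bands must be contiguous")
  structure(b, class = "band_scheme")
}

#' Assign frequencies to bands
#'
#' @param frequencies numeric vector, Hz.
#' @param bands a [band_scheme()].
#' @return factor with one level per band; `NA` for frequencies outside
#'   the covered range.
#' @export
band_of <- function(frequencies, bands = band_scheme()) {
  nm <- names(bands)
  lows <- vapply(bands, `[`, numeric(1), 1L)
  highs <- vapply(bands, `[`, numeric(1), 2L)
  idx <- rep(NA_integer_, length(frequencies))
  for (i in seq_along(bands)) {
    inb <- frequencies >= lows[i] & frequencies < highs[i]
    if (i == length(bands)) inb <- inb | frequencies == highs[i]
    idx[inb] <- i
  }
  factor(nm[idx], levels = nm)
}

#' Band centers of a scheme
#'
#' Midpoint frequency of each band; used as the reduced "band-space"
#' frequency grid on which models are fitted by default.
#'
#' @inheritParams band_of
#' @return named numeric vector, Hz.
#' @export
band_centers <- function(bands = band_scheme()) {
  vapply(bands, function(b) mean(b), numeric(1))
}

#' Band-averaging projector
#'
#' Matrix `P` (bands x frequencies) averaging a fine frequency grid into
#' bands; `P %*% x` is the band-mean of `x`.
#'
#' @param frequencies numeric frequency grid, Hz.
#' @inheritParams band_of
#' @return matrix with one row per band.
#' @export
band_projector <- function(frequencies, bands = band_scheme()) {
  f <- band_of(frequencies, bands)
  P <- matrix(0, length(bands), length(frequencies),
              dimnames = list(names(bands), frequencies))
  for (i in seq_along(bands)) {
    inb <- which(as.integer(f) == i)
    if (length(inb)) P[i, inb] <- 1 / length(inb)
  }
  P
}
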