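#' Band- and sign-resolved connection features
#'
#' For each directed edge and band, the excitatory feature is the mean
#' of the positive coupling entries whose *target* frequency lies in
#' the band, and the inhibitory feature the mean of the negative
#' entries (0 when a sign class is empty, so vectors have fixed
#' length). With 18 connections this yields the 144-attribute vector
#' (8 parameters per connection). Assignment by source frequency is
#' available via `assign_by = "source"`.
#'
#' @param fit a `dcm_fit` from [invert_dcm()], or a bare
#'   [coupling_params()] object (ground truth in simulations).
#' @param bands a [band_scheme()].
#' @param assign_by band of the `"target"` (default) or `"source"`
#'   frequency for cross-frequency entries.
#' @return object of class `feature_vector`: `values`, `names`
#'   (`edge.band.sign`), `kind = "connection"`, plus a `band` and
#'   `sign` label per entry.
#' @export
extract_connection_features <- function(fit, bands = band_scheme(),
                                        assign_by = c("target", "source")) {
  assign_by <- match.arg(assign_by)
  params <- if (inherits(fit, "dcm_fit")) fit$params else fit
  if (!inherits(params, "coupling_params"))
    stop("fit must be a dcm_fit or coupling_params object")
  bn <- names(bands)
  ids <- names(params$A)
  vals <- c(); nms <- c(); bnd <- c(); sgn <- c()
  for (id in ids) {
    M <- params$A[[id]]
    # rows of the band matrix are target bands, columns source bands
    grp <- if (assign_by == "target") row(M) else col(M)
    for (b in seq_along(bn)) {
      inb <- M[grp == b]
      pos <- inb[inb > 0]; neg <- inb[inb < 0]
      vals <- c(vals, if (length(pos)) mean(pos) else 0,
                if (length(neg)) mean(neg) else 0)
      nms <- c(nms, paste(id, bn[b], c("exc", "inh"), sep = "."))
      bnd <- c(bnd, bn[b], bn[b]); sgn <- c(sgn, "exc", "inh")
    }
  }
  structure(list(values = setNames(vals, nms), names = nms,
                 band = bnd, sign = sgn, kind = "connection"),
            class = "feature_vector")
}

#' Band- and sign-resolved source-spectrum features
#'
#' Per source and band: the mean of positive baseline-corrected power
#' bins and the mean of negative bins over the analysis window, giving
#' 8 attributes per source (40 for the five motor sources).
#'
#' @param spec a baseline-corrected [source_spectrogram()].
#' @param bands a [band_scheme()].
#' @return a `feature_vector` with `kind = "source"`.
#' @export
extract_source_features <- function(spec, bands = band_scheme()) {
  bn <- names(bands)
  fb <- as.integer(band_of(spec$frequencies, bands))
  vals <- c(); nms <- c(); bnd <- c(); sgn <- c()
  for (s in seq_along(spec$source_labels)) {
    for (b in seq_along(bn)) {
      x <- spec$power[s, fb == b, , drop = FALSE]
      pos <- x[x > 0]; neg <- x[x < 0]
      vals <- c(vals, if (length(pos)) mean(pos) else 0,
                if (length(neg)) mean(neg) else 0)
      nms <- c(nms, paste(spec$source_labels[s], bn[b], c("exc", "inh"),
                          sep = "."))
      bnd <- c(bnd, bn[b], bn[b]); sgn <- c(sgn, "exc", "inh")
    }
  }
  structure(list(values = setNames(vals, nms), names = nms,
                 band = bnd, sign = sgn, kind = "source"),
            class = "feature_vector")
}

#' Stack feature vectors into a labeled matrix
#'
#' @param features list of `feature_vector` objects (one per subject).
#' @return matrix subjects x attributes with a `band` attribute giving
#'   each column's band.
#' @export
feature_matrix <- function(features) {
  stopifnot(length(features) >= 1)
  nms <- features[[1]]$names
  X <- t(vapply(features, function(f) {
    if (!identical(f$names, nms)) stop("feature vectors are not aligned")
    f$values
  }, numeric(length(nms))))
  colnames(X) <- nms
  attr(X, "band") <- features[[1]]$band
  X
}

#' Write a feature matrix as CSV
#' @param X matrix from [feature_matrix()].
#' @param path file path.
#' @param labels optional outcome labels appended as a `label` column.
#' @export
write_features <- function(X, path, labels = NULL) {
  df <- as.data.frame(X)
  if (!is.null(labels)) df$label <- labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
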