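#' The five core motor sources
#'
#' Supplementary motor area (SMA), ipsi- and contralesional primary motor
#' cortex (iM1, cM1) and premotor cortex (iPM, cPM), with their MNI
#' coordinates (mm). After mid-sagittal flipping the ipsilesional
#' hemisphere is mapped to the left, so "i" sources carry left
#' coordinates.
#'
#' @return object of class `source_set`: data frame with `label`, `x`,
#'   `y`, `z`.
#' @export
default_source_set <- function() {
  s <- data.frame(
    label = c("SMA", "iM1", "cM1", "iPM", "cPM"),
    x = c(-2, -41, 49, -40, 40),
    y = c(-2, -26, -27, -12, -2),
    z = c(62, 56, 56, 52, 62),
    stringsAsFactors = FALSE
  )
  structure(s, class = c("source_set", "data.frame"))
}

#' MNI coordinates of the default sources as a labeled matrix
#' @return 5 x 3 matrix with source labels as row names.
#' @export
default_source_coords <- function() {
  s <- default_source_set()
  m <- as.matrix(s[, c("x", "y", "z")])
  rownames(m) <- s$label
  m
}

#' Default 32-channel 10-20 montage with mirror pairs
#'
#' Channel labels for a standard 32-electrode extended 10-20 layout plus
#' the left/right mirror pairing used by [flip_hemispheres()]. Midline
#' channels (z-line) are their own mirror.
#'
#' @return list with `channels` (character 32) and `pairs` (data frame
#'   `left`, `right`).
#' @export
default_montage <- function() {
  channels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
                "CP5", "CP1", "CP2", "CP6", "TP9", "TP10",
                "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10")
  pairs <- data.frame(
    left = c("Fp1", "F7", "F3", "FC5", "FC1", "T7", "C3", "CP5", "CP1",
             "TP9", "P7", "P3", "PO9", "O1"),
    right = c("Fp2", "F8", "F4", "FC6", "FC2", "T8", "C4", "CP6", "CP2",
              "TP10", "P8", "P4", "PO10", "O2"),
    stringsAsFactors = FALSE
  )
  list(channels = channels, pairs = pairs)
}
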