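#' Phase-shifted frame triplet
#'
#' Bundles the three sequential patterned images of one structured
#' illumination acquisition. The sinusoidal excitation pattern is
#' phase-shifted by one-third of the grid period between frames, so the
#' in-focus signal is modulated while out-of-focus background is not.
#'
#' @param x1,x2,x3 Non-negative numeric matrices of identical dimensions.
#' @param grid_period_px Pattern period at the detector, in pixels.
#' @return An object of class `frame_triplet`.
#' @export
frame_triplet <- function(x1, x2, x3, grid_period_px = 12) {
  if (!is.matrix(x1) || !is.matrix(x2) || !is.matrix(x3))
    stop("frames must be matrices")
  if (!identical(dim(x1), dim(x2)) || !identical(dim(x1), dim(x3)))
    stop("the three frames must share dimensions")
  if (min(x1, x2, x3) < 0) stop("intensities must be >= 0")
  structure(list(x1 = x1, x2 = x2, x3 = x3,
                 phase_step = 1 / 3,
                 grid_period_px = grid_period_px),
            class = "frame_triplet")
}

#' Square-law optical-section reconstruction
#'
#' Demodulates a phase-shifted triplet into a single optically sectioned
#' image via square-law detection:
#' `I = sqrt((x1 - x2)^2 + (x1 - x3)^2 + (x2 - x3)^2)`.
#' Any signal common to all three frames (uniform or defocused background)
#' cancels exactly; a sinusoidal component of amplitude `M` maps to
#' `sqrt(9/2) * M` regardless of its local phase.
#'
#' @param t A [frame_triplet()], or a matrix given together with `x2`,
#'   `x3`.
#' @param x2,x3 Second and third frames when `t` is a plain matrix.
#' @param pixel_size_um Pixel size recorded on the output.
#' @return An object of class `sectioned_frame` with fields `image`
#'   (non-negative matrix) and `pixel_size_um`.
#' @examples
#' t <- frame_triplet(matrix(1, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
#' square_law_reconstruct(t)$image[1, 1]  # sqrt(2)
#' @export
square_law_reconstruct <- function(t, x2 = NULL, x3 = NULL,
                                   pixel_size_um = 0.645) {
  if (!inherits(t, "frame_triplet")) t <- frame_triplet(t, x2, x3)
  img <- sqrt((t$x1 - t$x2)^2 + (t$x1 - t$x3)^2 + (t$x2 - t$x3)^2)
  structure(list(image = img, pixel_size_um = pixel_size_um),
            class = "sectioned_frame")
}

#' Flat-field reference image
#'
#' Wraps an image of a uniform fluorescent calibration slide as the
#' reference for illumination correction. The image is rescaled so its
#' mean is exactly 1; every pixel must be strictly positive.
#'
#' @param image Positive numeric matrix.
#' @return An object of class `flat_field_reference`.
#' @export
flat_field_reference <- function(image) {
  if (!is.matrix(image)) stop("reference must be a matrix")
  if (any(!is.finite(image)) || any(image <= 0))
    stop("reference image must be strictly positive and finite everywhere")
  structure(list(image = image / mean(image)),
            class = "flat_field_reference")
}

#' Flat-field (illumination) correction
#'
#' Divides a frame pixelwise by an intensity-normalized reference image,
#' removing the static illumination profile. A uniform reference is the
#' identity.
#'
#' @param frame Numeric matrix.
#' @param ref A [flat_field_reference()] (or a positive matrix, which is
#'   normalized first).
#' @return Corrected matrix, same dimensions as `frame`.
#' @export
flat_field_correct <- function(frame, ref) {
  if (!inherits(ref, "flat_field_reference")) ref <- flat_field_reference(ref)
  if (!identical(dim(frame), dim(ref$image)))
    stop("frame and reference dimensions differ")
  frame / ref$image
}

#' Rescale an image to 16-bit grayscale
#'
#' Linear min-max map onto `[0, 65535]`, rounded to integers, used when
#' exporting reconstructed sections. A constant image maps to all zeros
#' (degenerate policy, reported as a warning) so batch pipelines keep
#' running.
#'
#' @param image Finite numeric matrix.
#' @return Integer-valued matrix in `[0, 65535]`.
#' @export
rescale_to_16bit <- function(image) {
  if (any(!is.finite(image))) stop("image contains non-finite values")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: rescaled to all zeros")
    return(array(0, dim = dim(image)))
  }
  round((image - rng[1]) / (rng[2] - rng[1]) * 65535)
}

#' Optical calibration from a USAF 1951 target
#'
#' Resolution bookkeeping for the imaging system: the spatial frequency of
#' group `g`, element `e` of a USAF 1951 chart is `2^(g + (e-1)/6)` line
#' pairs per mm; the full pitch is its inverse. Field of view follows from
#' the sensor size and pixel pitch, and the lateral resolution is taken as
#' 3 pixel widths (the finest element resolved by the reference system,
#' group 9 element 1 at 512 lp/mm, spans about 3 pixels).
#'
#' @param group,element USAF group (-2..9 typical) and element (1..6).
#' @param pixel_size_um Pixel size at the sample, um (default 0.645).
#' @param n_px Sensor width in pixels (default 2048).
#' @return List with `lp_per_mm`, `pitch_um`, `fov_mm`,
#'   `lateral_resolution_um`.
#' @examples
#' optical_calibration(9, 1)  # 512 lp/mm, 1.953 um pitch
#' @export
optical_calibration <- function(group = 9L, element = 1L,
                                pixel_size_um = 0.645, n_px = 2048L) {
  if (element < 1 || element > 6) stop("element must be in 1..6")
  if (group < -2 || group > 11) stop("group outside USAF 1951 range")
  lp <- 2^(group + (element - 1) / 6)
  list(lp_per_mm = lp,
       pitch_um = 1000 / lp,
       fov_mm = n_px * pixel_size_um / 1000,
       lateral_resolution_um = 3 * pixel_size_um)
}

#' Read / write a single-plane grayscale TIFF
#'
#' Thin wrappers over the `tiff` package using the package's internal
#' convention: images are numeric matrices in `[0, 1]` (16-bit on disk).
#'
#' @param path File path.
#' @param image Numeric matrix with values in `[0, 1]`.
#' @return `read_frame_tif()` returns a numeric matrix; `write_frame_tif()`
#'   returns `path` invisibly.
#' @export
read_frame_tif <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' @rdname read_frame_tif
#' @export
write_frame_tif <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}
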