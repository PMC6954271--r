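#' Reconstruct and stitch an acquisition into panels and a panorama
#'
#' Convenience pipeline over the module primitives: every frame triplet
#' is square-law reconstructed (optionally flat-field corrected first),
#' tiles are placed at their stage offsets (optionally refined by overlap
#' correlation) and stitched per panel, and panels are concatenated into
#' the rolled-out panorama.
#'
#' @param acq A [simulate_acquisition()] result (or any object with the
#'   same structure holding real tile triplets).
#' @param flat_field Optional [flat_field_reference()] applied to each
#'   raw frame before reconstruction.
#' @param refine Refine tile offsets by overlap correlation.
#' @param blend Blend mode passed to [stitch_panel()].
#' @return List with `panels` (list of [stitch_panel()] results) and
#'   `panorama` (a [assemble_rollout()] result).
#' @export
reconstruct_acquisition <- function(acq, flat_field = NULL, refine = TRUE,
                                    blend = "feather") {
  stopifnot(inherits(acq, "phantom_acquisition"))
  mmpx <- acq$mm_per_px
  ny <- acq$surface_dim[1L]
  panels <- lapply(acq$panels, function(p) {
    tiles <- lapply(p$tiles, function(t) {
      tr <- t$triplet
      if (!is.null(flat_field)) {
        tr$x1 <- flat_field_correct(tr$x1, flat_field)
        tr$x2 <- flat_field_correct(tr$x2, flat_field)
        tr$x3 <- flat_field_correct(tr$x3, flat_field)
      }
      square_law_reconstruct(tr)$image
    })
    off <- data.frame(
      ix = vapply(p$tiles, `[[`, 1L, "ix"),
      iy = vapply(p$tiles, `[[`, 1L, "iy"),
      x_px = vapply(p$tiles, function(t) round(t$stage_x_mm / mmpx), 1),
      y_px = vapply(p$tiles, function(t) round(t$stage_y_mm / mmpx), 1))
    if (refine)
      off <- refine_offsets(tiles, off, acq$plan$overlap_fraction)
    pan <- stitch_panel(tiles, off, blend = blend,
                        panel_index = p$panel_index,
                        nominal_width_px = p$width_px,
                        nominal_length_px = ny)
    # trim the tile bounding box to the nominal panel footprint so panel
    # coordinates match the unrolled surface
    pan$image <- pan$image[seq_len(min(ny, nrow(pan$image))),
                           seq_len(min(p$width_px, ncol(pan$image))),
                           drop = FALSE]
    pan
  })
  list(panels = panels, panorama = assemble_rollout(panels))
}
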