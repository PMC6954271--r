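#' Serpentine (boustrophedon) tile order
#'
#' Stage-scan ordering that alternates row direction so every consecutive
#' pair of frames is grid-adjacent (one step apart), minimising stage
#' travel.
#'
#' @param nx,ny Grid dimensions (columns, rows), both >= 1.
#' @return Data frame with 0-based `ix`, `iy` in visit order.
#' @examples
#' serpentine_coords(2, 2)  # (0,0) (1,0) (1,1) (0,1)
#' @export
serpentine_coords <- function(nx, ny) {
  stopifnot(nx >= 1, ny >= 1)
  rows <- lapply(seq_len(ny) - 1L, function(iy) {
    ix <- if (iy %% 2L == 0L) seq_len(nx) - 1L else rev(seq_len(nx) - 1L)
    data.frame(ix = ix, iy = iy)
  })
  do.call(rbind, rows)
}

#' Refine tile offsets by correlation on overlap strips
#'
#' Translation-only stitching refinement: each tile (in raster order) is
#' matched against its left neighbour (or top neighbour for the first
#' column) by maximising normalized cross-correlation of the shared
#' overlap region over integer shifts within `search_px`. Refined
#' positions accumulate along the grid. Degenerate overlaps (smaller than
#' 8 px in either direction, or featureless) keep the nominal offset with
#' a warning.
#'
#' @param tiles List of tile matrices, one per row of `nominal_offsets`.
#' @param nominal_offsets Data frame with columns `ix`, `iy`, `x_px`,
#'   `y_px` (0-based nominal tile origins).
#' @param overlap_fraction Nominal overlap fraction; 0 disables
#'   refinement (pass-through).
#' @param search_px Maximum shift searched in each direction.
#' @return `nominal_offsets` with refined `x_px`, `y_px` and the applied
#'   per-tile corrections `dx`, `dy`.
#' @export
refine_offsets <- function(tiles, nominal_offsets, overlap_fraction,
                           search_px = 8L) {
  off <- nominal_offsets
  off$dx <- 0; off$dy <- 0
  if (overlap_fraction <= 0) return(off)
  idx <- function(ix, iy) which(off$ix == ix & off$iy == iy)

  ord <- order(off$iy, off$ix)
  for (k in ord) {
    ix <- off$ix[k]; iy <- off$iy[k]
    ref <- if (ix > 0) idx(ix - 1L, iy) else if (iy > 0) idx(ix, iy - 1L)
    else next
    if (length(ref) != 1L) next
    nom_dx <- nominal_offsets$x_px[k] - nominal_offsets$x_px[ref]
    nom_dy <- nominal_offsets$y_px[k] - nominal_offsets$y_px[ref]
    sh <- correlation_shift(tiles[[ref]], tiles[[k]], nom_dx, nom_dy,
                            search_px)
    if (is.null(sh)) {
      warning(sprintf("tile (%d,%d): degenerate overlap, nominal offset kept",
                      ix, iy))
      sh <- c(0, 0)
    }
    off$x_px[k] <- off$x_px[ref] + nom_dx + sh[1L]
    off$y_px[k] <- off$y_px[ref] + nom_dy + sh[2L]
    off$dx[k] <- off$x_px[k] - nominal_offsets$x_px[k]
    off$dy[k] <- off$y_px[k] - nominal_offsets$y_px[k]
  }
  off
}

# Best (sx, sy) maximising NCC of the overlap of A and B when B sits at
# (nom_dx + sx, nom_dy + sy) relative to A. NULL if degenerate.
correlation_shift <- function(A, B, nom_dx, nom_dy, search_px) {
  best <- NULL; best_ncc <- -Inf
  for (sy in -search_px:search_px) for (sx in -search_px:search_px) {
    dx <- nom_dx + sx; dy <- nom_dy + sy
    ax <- max(1L, 1L + dx):min(ncol(A), ncol(B) + dx)
    ay <- max(1L, 1L + dy):min(nrow(A), nrow(B) + dy)
    if (length(ax) < 8L || length(ay) < 8L) next
    v <- ncc(A[ay, ax], B[ay - dy, ax - dx])
    if (is.na(v)) next
    if (v > best_ncc) { best_ncc <- v; best <- c(sx, sy) }
  }
  if (is.null(best) || !is.finite(best_ncc)) return(NULL)
  best
}

#' Stitch a tile grid into one panel image
#'
#' Places tiles on a canvas sized to their bounding box at the given
#' (possibly refined) offsets. Overlaps are combined by `"feather"`
#' blending (linear distance-to-edge weight ramp) or `"overwrite"`
#' (later tiles win; every output pixel equals some input pixel).
#'
#' @param tiles List of tile matrices matching `offsets` rows.
#' @param offsets Data frame with `ix`, `iy`, `x_px`, `y_px`.
#' @param blend `"feather"` or `"overwrite"`.
#' @param panel_index Panel identity recorded on the result.
#' @param nominal_width_px,nominal_length_px Optional nominal panel size;
#'   stored for trimming at assembly.
#' @return An object of class `panel_image` with fields `image`,
#'   `panel_index`, `frame_offsets`, `nominal_width_px`,
#'   `nominal_length_px`.
#' @export
stitch_panel <- function(tiles, offsets, blend = c("feather", "overwrite"),
                         panel_index = NA_integer_,
                         nominal_width_px = NULL, nominal_length_px = NULL) {
  blend <- match.arg(blend)
  if (length(tiles) != nrow(offsets))
    stop("tiles and offsets length mismatch")
  for (k in seq_along(tiles))
    if (!is.matrix(tiles[[k]]))
      stop(sprintf("missing tile at grid position (%d,%d)",
                   offsets$ix[k], offsets$iy[k]))
  x0 <- min(offsets$x_px); y0 <- min(offsets$y_px)
  wpx <- max(offsets$x_px + vapply(tiles, ncol, 1L)) - x0
  hpx <- max(offsets$y_px + vapply(tiles, nrow, 1L)) - y0
  canvas <- matrix(0, hpx, wpx)
  if (length(tiles) == 1L) {
    canvas <- tiles[[1L]]                       # single tile is identity
  } else if (blend == "feather") {
    wsum <- matrix(0, hpx, wpx)
    for (k in seq_along(tiles)) {
      t <- tiles[[k]]
      wx <- pmin(seq_len(ncol(t)), rev(seq_len(ncol(t))), 16L)
      wy <- pmin(seq_len(nrow(t)), rev(seq_len(nrow(t))), 16L)
      wt <- outer(wy, wx, pmin)
      rs <- offsets$y_px[k] - y0 + seq_len(nrow(t))
      cs <- offsets$x_px[k] - x0 + seq_len(ncol(t))
      canvas[rs, cs] <- canvas[rs, cs] + t * wt
      wsum[rs, cs] <- wsum[rs, cs] + wt
    }
    canvas <- canvas / pmax(wsum, 1e-12)
    canvas[wsum == 0] <- 0
  } else {
    for (k in seq_along(tiles)) {
      t <- tiles[[k]]
      rs <- offsets$y_px[k] - y0 + seq_len(nrow(t))
      cs <- offsets$x_px[k] - x0 + seq_len(ncol(t))
      canvas[rs, cs] <- t
    }
  }
  structure(list(image = canvas, panel_index = panel_index,
                 frame_offsets = offsets,
                 nominal_width_px = nominal_width_px,
                 nominal_length_px = nominal_length_px),
            class = "panel_image")
}

#' @export
print.panel_image <- function(x, ...) {
  cat(sprintf("<panel_image> #%s: %d x %d px (%d tiles)\n",
              x$panel_index, nrow(x$image), ncol(x$image),
              nrow(x$frame_offsets)))
  invisible(x)
}

#' Default anatomical labels for a rotation sequence
#'
#' Rotation starts at the posterior centre, so panel `k` sits at azimuth
#' `(k - 1) * 360 / n` degrees; labels follow the nearest compass sector
#' posterior / left / anterior / right. For `n = 10` the sequence begins
#' and ends at posterior.
#'
#' @param n Number of panels.
#' @return Character vector of length `n`.
#' @export
anatomical_labels <- function(n) {
  sectors <- c("posterior", "left", "anterior", "right")
  ang <- (seq_len(n) - 1L) * 360 / n
  sectors[(((ang + 45) %/% 90) %% 4) + 1L]
}

#' Assemble panels into the rolled-out circumference panorama
#'
#' Concatenates stitched panels horizontally in rotation order (starting
#' at the posterior centre). Panels are trimmed or zero-padded to their
#' nominal width when recorded; heights are zero-padded to the maximum
#' (an error if the mismatch exceeds `pad_limit_px`).
#'
#' @param panels List of [stitch_panel()] results (or plain matrices).
#' @param organ_labels Optional label per panel; defaults to
#'   [anatomical_labels()].
#' @param pad_limit_px Largest tolerated height mismatch.
#' @return An object of class `rolled_out_panorama`: `image`,
#'   `panel_boundaries` (0-based start column of each panel),
#'   `anatomical_labels`, `total_pixels`.
#' @export
assemble_rollout <- function(panels, organ_labels = NULL,
                             pad_limit_px = 64L) {
  imgs <- lapply(panels, function(p) {
    img <- as_image(p)
    if (is.list(p) && !is.null(p$nominal_width_px)) {
      w <- p$nominal_width_px
      if (ncol(img) >= w) img <- img[, seq_len(w), drop = FALSE]
      else img <- cbind(img, matrix(0, nrow(img), w - ncol(img)))
    }
    if (is.list(p) && !is.null(p$nominal_length_px)) {
      h <- p$nominal_length_px
      if (nrow(img) >= h) img <- img[seq_len(h), , drop = FALSE]
      else img <- rbind(img, matrix(0, h - nrow(img), ncol(img)))
    }
    img
  })
  hs <- vapply(imgs, nrow, 1L)
  if (max(hs) - min(hs) > pad_limit_px)
    stop("panel height mismatch exceeds pad limit")
  H <- max(hs)
  imgs <- lapply(imgs, function(m)
    if (nrow(m) < H) rbind(m, matrix(0, H - nrow(m), ncol(m))) else m)
  ws <- vapply(imgs, ncol, 1L)
  pano <- do.call(cbind, imgs)
  if (is.null(organ_labels)) organ_labels <- anatomical_labels(length(imgs))
  if (length(organ_labels) != length(imgs))
    stop("label count must equal panel count")
  structure(list(image = pano,
                 panel_boundaries = cumsum(c(0L, ws[-length(ws)])),
                 panel_widths = ws,
                 anatomical_labels = organ_labels,
                 total_pixels = length(pano)),
            class = "rolled_out_panorama")
}

#' @export
print.rolled_out_panorama <- function(x, ...) {
  cat(sprintf("<rolled_out_panorama> %d x %d px, %d panels (%s ... %s)\n",
              nrow(x$image), ncol(x$image), length(x$panel_widths),
              x$anatomical_labels[1L],
              x$anatomical_labels[length(x$anatomical_labels)]))
  invisible(x)
}

#' Raw-pixel accounting for an acquisition
#'
#' Total raw pixels collected: frames times sensor pixels (each SIM frame
#' is computed from three raw phase images; `per_phase = TRUE` counts
#' only reconstructed frames).
#'
#' @param n_frames Number of reconstructed frames (mosaic tiles).
#' @param frame_px Sensor width in pixels (square sensor assumed).
#' @return Total pixel count.
#' @examples
#' raw_pixel_count(2700)  # about 1.13e10 over a full circumference run
#' @export
raw_pixel_count <- function(n_frames, frame_px = 2048L) {
  as.numeric(n_frames) * as.numeric(frame_px)^2
}
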