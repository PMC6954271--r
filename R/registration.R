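#' Detect ink fiducial markers on a panel
#'
#' Finds the painted central line and hash marks on a (reconstructed or
#' ground-truth) panel. Ink quenches fluorescence, so markers are dark
#' notches: the central line is located as the strongest dip of the
#' row-mean intensity profile below its running-median baseline; hash
#' marks as dips of the column-mean profile over a band around the line.
#' Dips count only where they exceed `min_depth` of the local baseline
#' and the baseline itself carries signal (out-of-contact columns, which
#' reconstruct to zero, are ignored).
#'
#' @param panel A `panel_image`, panorama, or plain matrix.
#' @param mm_per_px Pixel pitch, used to size the smoothing window.
#' @param ink_polarity Only `"dark"` is implemented (fluorescence void).
#' @param band_mm Axial half-extent of the hash search band around the
#'   central line.
#' @param smooth_mm Running-median baseline window.
#' @param min_depth Minimum relative dip depth counted as ink.
#' @return An object of class `marker_set`: `central_line_y_px`,
#'   `hash_x_positions_px` (sorted), `confidence` in `[0, 1]`. Empty set
#'   with confidence 0 (and a warning) when no markers are found.
#' @export
detect_fiducials <- function(panel, mm_per_px, ink_polarity = "dark",
                             band_mm = 3, smooth_mm = 2, min_depth = 0.25) {
  if (!identical(ink_polarity, "dark"))
    stop("only dark ink (fluorescence void) is implemented")
  img <- as_image(panel)
  if (length(img) == 0L) stop("panel is empty")
  win_r <- odd_window(smooth_mm / mm_per_px)

  prof_y <- rowMeans(img)
  dip_y <- profile_dips(prof_y, win_r, min_depth)
  if (length(dip_y$pos) == 0L) {
    warning("no fiducial markers detected")
    return(marker_set(NA_real_, numeric(), 0))
  }
  line_y <- dip_y$pos[which.max(dip_y$depth)]
  line_conf <- min(1, dip_y$depth[which.max(dip_y$depth)])

  band <- max(1L, round(line_y - band_mm / mm_per_px)):
    min(nrow(img), round(line_y + band_mm / mm_per_px))
  prof_x <- colMeans(img[band, , drop = FALSE])
  dip_x <- profile_dips(prof_x, win_r, min_depth)

  marker_set(line_y, sort(dip_x$pos),
             confidence = min(1, mean(c(line_conf, dip_x$depth))))
}

odd_window <- function(w) {
  w <- max(5L, round(w))
  if (w %% 2L == 0L) w + 1L else w
}

# Locate dips of a profile below its running-median baseline. Returns
# centroid positions and relative depths of contiguous significant runs.
profile_dips <- function(p, win, min_depth) {
  base <- stats::runmed(p, min(win, odd_window(length(p) / 2 - 1)))
  floor_lvl <- 0.2 * stats::quantile(p, 0.9, names = FALSE)
  depth <- (base - p) / pmax(base, 1e-12)
  sig <- depth > min_depth & base > floor_lvl
  if (!any(sig)) return(list(pos = numeric(), depth = numeric()))
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  pos <- dep <- numeric(length(keep))
  for (j in seq_along(keep)) {
    i <- starts[keep[j]]:ends[keep[j]]
    pos[j] <- sum(i * depth[i]) / sum(depth[i])   # depth-weighted centroid
    dep[j] <- max(depth[i])
  }
  list(pos = pos, depth = dep)
}

#' @rdname detect_fiducials
#' @param central_line_y_px,hash_x_positions_px,confidence Fields of a
#'   manually constructed marker set.
#' @export
marker_set <- function(central_line_y_px, hash_x_positions_px,
                       confidence = 1) {
  if (is.unsorted(hash_x_positions_px, strictly = TRUE) &&
      length(hash_x_positions_px) > 1L)
    stop("hash positions must be strictly increasing")
  structure(list(central_line_y_px = central_line_y_px,
                 hash_x_positions_px = as.numeric(hash_x_positions_px),
                 confidence = confidence),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> line y = %.1f px, %d hashes, confidence %.2f\n",
              x$central_line_y_px, length(x$hash_x_positions_px),
              x$confidence))
  invisible(x)
}

#' Measure hash-mark spacing
#'
#' Mean spacing between adjacent hash marks, in mm. Hash marks falling in
#' the out-of-contact gap between panels are invisible on reconstructed
#' panoramas, so adjacent detected marks can be an integer multiple of
#' the true spacing apart; each gap is therefore divided by its rounded
#' multiple of the smallest gap before averaging (for fully visible
#' marker sets this is exactly the mean adjacent spacing).
#'
#' @param markers A [marker_set()] with at least 2 hashes.
#' @param mm_per_px Pixel pitch.
#' @return Spacing in mm.
#' @export
measure_hash_spacing <- function(markers, mm_per_px) {
  stopifnot(inherits(markers, "marker_set"))
  x <- markers$hash_x_positions_px
  if (length(x) < 2L) stop("need at least 2 hash marks")
  d <- diff(sort(x))
  unit <- min(d)
  k <- pmax(1, round(d / unit))
  sum(d) / sum(k) * mm_per_px
}

#' Align panels using fiducial markers
#'
#' Computes per-panel corrections so the central ink line is collinear
#' across panels (axial offsets) and the hash-mark sequence stays
#' periodic at the stencil spacing across panel seams (circumferential
#' shifts), and flags adjacent panel pairs whose content is duplicated
#' (rod slippage). Panels without detectable markers keep zero offsets
#' with a warning.
#'
#' @param panels List of panel images (matrices or `panel_image`s).
#' @param marker_sets Optional precomputed [detect_fiducials()] results.
#' @param mm_per_px Pixel pitch.
#' @param spacing_mm Stencil hash spacing.
#' @param repeat_threshold Duplicate-overlap fraction above which a pair
#'   is flagged as a repeat.
#' @return An object of class `alignment_result`: `offsets` (data frame
#'   `panel`, `axial_offset_px`, `circ_shift_px`, `has_markers`) and
#'   `duplicate_flags` (data frame `pair`, `overlap_fraction`,
#'   `is_repeat`).
#' @export
align_panels <- function(panels, marker_sets = NULL, mm_per_px,
                         spacing_mm = 10, repeat_threshold = 0.5) {
  n <- length(panels)
  if (is.null(marker_sets))
    marker_sets <- lapply(panels, detect_fiducials, mm_per_px = mm_per_px)
  has <- vapply(marker_sets, function(m)
    is.finite(m$central_line_y_px) && m$confidence > 0, TRUE)
  if (!all(has))
    warning("markers missing on ", sum(!has),
            " panel(s); zero offsets kept there")

  line_y <- vapply(marker_sets, function(m) m$central_line_y_px, 1)
  ref_y <- stats::median(line_y[has])
  axial <- ifelse(has, round(ref_y - line_y), 0)

  # circumferential: keep hash phase (position mod spacing, in global
  # panorama coordinates) consistent with the first marked panel
  sp_px <- spacing_mm / mm_per_px
  widths <- vapply(panels, function(p) ncol(as_image(p)), 1L)
  starts <- cumsum(c(0, widths[-n]))
  phase0 <- NA_real_
  circ <- numeric(n)
  for (i in seq_len(n)) {
    hx <- marker_sets[[i]]$hash_x_positions_px
    if (!has[i] || length(hx) == 0L) next
    ph <- stats::median((hx + starts[i]) %% sp_px)
    if (is.na(phase0)) { phase0 <- ph; next }
    delta <- (phase0 - ph) %% sp_px
    if (delta > sp_px / 2) delta <- delta - sp_px
    circ[i] <- round(delta)
  }

  dup <- lapply(seq_len(max(0L, n - 1L)), function(i) {
    d <- detect_duplicate_overlap(panels[[i]], panels[[i + 1L]],
                                  repeat_threshold = repeat_threshold)
    data.frame(pair = i, overlap_fraction = d$overlap_fraction,
               is_repeat = d$is_repeat)
  })
  structure(list(
    offsets = data.frame(panel = seq_len(n) - 1L,
                         axial_offset_px = as.integer(axial),
                         circ_shift_px = as.integer(circ),
                         has_markers = has),
    duplicate_flags = if (length(dup)) do.call(rbind, dup) else
      data.frame(pair = integer(), overlap_fraction = numeric(),
                 is_repeat = logical())),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d panels, %d repeat pair(s)\n",
              nrow(x$offsets), sum(x$duplicate_flags$is_repeat)))
  invisible(x)
}

#' Apply an alignment to a panel list
#'
#' Shifts each panel by its axial offset and circumferential shift
#' (zero-filled translation) and applies the repeated-panel policy: for a
#' pair flagged as a repeat, either the duplicated span is trimmed from
#' the later panel (`"trim"`) or the later panel is dropped (`"drop"`).
#'
#' @param panels List of panel images.
#' @param alignment An [align_panels()] result.
#' @param policy `"trim"` or `"drop"`.
#' @return List of corrected panel matrices (possibly fewer than input
#'   under `"drop"`).
#' @export
apply_alignment <- function(panels, alignment, policy = c("trim", "drop")) {
  policy <- match.arg(policy)
  stopifnot(inherits(alignment, "alignment_result"))
  out <- lapply(seq_along(panels), function(i) {
    m <- shift_fill(as_image(panels[[i]]),
                    dy = alignment$offsets$axial_offset_px[i],
                    dx = alignment$offsets$circ_shift_px[i])
    m
  })
  flags <- alignment$duplicate_flags
  drop_idx <- integer()
  for (j in seq_len(nrow(flags))) {
    if (!flags$is_repeat[j]) next
    i2 <- flags$pair[j] + 1L            # the later panel of the pair
    if (policy == "drop") {
      drop_idx <- c(drop_idx, i2)
    } else {
      w <- ncol(out[[i2]])
      cut <- min(w - 1L, round(flags$overlap_fraction[j] * w))
      out[[i2]] <- out[[i2]][, (cut + 1L):w, drop = FALSE]
    }
  }
  if (length(drop_idx)) out <- out[-drop_idx]
  out
}

#' Duplicate-content overlap between adjacent panels
#'
#' Rod slippage can make adjacent panels image (partly) the same tissue.
#' One panel is slid over the other along the circumferential axis; at
#' each shift the two frames are correlated over the intersection of
#' their tissue supports (pixels carrying signal in both), after removing
#' per-row and per-column means so that frame-fixed structure — the
#' contact-patch outline, the central ink line, hash marks — cannot
#' masquerade as shared tissue. The overlap fraction is the widest frame
#' overlap whose support correlation exceeds `ncc_min`; both slide
#' directions are searched, making the measure symmetric.
#'
#' @param panel_a,panel_b Panel images of equal height (cropped to the
#'   common height otherwise).
#' @param repeat_threshold Overlap fraction at or above which the pair is
#'   declared a repeat.
#' @param ncc_min Support correlation required to accept an overlap.
#' @param coarse_px Coarse search stride along the shift axis.
#' @param eps Signal threshold defining the tissue support.
#' @return List with `overlap_fraction` in `[0, 1]` and `is_repeat`.
#' @export
detect_duplicate_overlap <- function(panel_a, panel_b,
                                     repeat_threshold = 0.5,
                                     ncc_min = 0.8, coarse_px = 4L,
                                     eps = 1e-6) {
  A <- as_image(panel_a); B <- as_image(panel_b)
  h <- min(nrow(A), nrow(B))
  A <- A[seq_len(h), , drop = FALSE]; B <- B[seq_len(h), , drop = FALSE]
  W <- min(ncol(A), ncol(B))

  # correlation over the joint tissue support, two-way centred
  support_ncc <- function(Ab, Bb) {
    keep <- (Ab > eps) & (Bb > eps)
    if (sum(keep) < max(256L, 0.05 * length(Ab))) return(NA_real_)
    centre <- function(M) {
      M[!keep] <- NA
      M <- sweep(M, 1L, rowMeans(M, na.rm = TRUE))
      M <- sweep(M, 2L, colMeans(M, na.rm = TRUE))
      M
    }
    ncc(centre(Ab)[keep], centre(Bb)[keep])
  }
  # shift s: column j of the trailing panel shows the same tissue as
  # column j + s of the leading panel; frame overlap is (W - s) / W
  at_shift <- function(P, Q, s)
    support_ncc(P[, (s + 1L):W, drop = FALSE],
                Q[, seq_len(W - s), drop = FALSE])
  scan <- function(P, Q) {
    for (s in seq(0L, W - 16L, by = coarse_px)) {
      # coarse pass is slack (the true shift can fall between strides);
      # candidates are confirmed at single-pixel resolution
      v <- at_shift(P, Q, s)
      if (is.na(v) || v < ncc_min - 0.2) next
      fine <- max(0L, s - coarse_px):min(W - 16L, s + coarse_px)
      fv <- vapply(fine, at_shift, 1, P = P, Q = Q)
      hit <- which(!is.na(fv) & fv >= ncc_min)
      if (length(hit)) return(W - fine[min(hit)])
    }
    0L
  }
  o <- max(scan(A, B), scan(B, A))
  frac <- o / W
  list(overlap_fraction = frac, is_repeat = frac >= repeat_threshold)
}

#' Seam continuity against a reference image
#'
#' Normalized cross-correlation between a panorama and a ground-truth
#' reference in a window around a panel seam, computed over pixels that
#' carry signal in the panorama (reconstructed out-of-contact pixels are
#' zero and uninformative).
#'
#' @param panorama,reference Equal-size matrices (or panorama objects).
#' @param boundary_x 0-based seam column.
#' @param half_px Window half-width.
#' @param eps Signal threshold defining informative pixels.
#' @return NCC value, or `NA` if the window carries no signal.
#' @export
seam_ncc <- function(panorama, reference, boundary_x, half_px = 150L,
                     eps = 1e-6) {
  P <- as_image(panorama); R <- as_image(reference)
  cols <- max(1L, boundary_x - half_px + 1L):
    min(ncol(P), ncol(R), boundary_x + half_px)
  P <- P[, cols, drop = FALSE]
  R <- R[seq_len(nrow(P)), cols, drop = FALSE]
  keep <- P > eps
  if (sum(keep) < 16L) return(NA_real_)
  ncc(P[keep], R[keep])
}
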