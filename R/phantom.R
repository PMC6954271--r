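#' Synthetic ground-truth organ surface
#'
#' Generates an unrolled (cylinder-coordinate) fluorescence map of an
#' organ surface: circumference `pi * d` mm across (x, circumferential)
#' by `length_mm` down (y, axial). The texture emulates an
#' acridine-orange-stained specimen surface with three feature classes:
#' bright curvilinear nerve tracts (~130 um wide), dark circular adipose
#' voids, and punctate bright nuclei (~10 um). Feature counts are Poisson
#' draws at the requested densities; everything is reproducible for a
#' fixed seed.
#'
#' @param diameter_mm,length_mm Organ diameter and apex-to-base length
#'   (mm).
#' @param mm_per_px Pixel pitch of the map (default 0.005 mm, fine enough
#'   to render single nuclei).
#' @param feature_params Named list overriding any of: `base_intensity`
#'   (0.55), `texture_sd` (0.05), `nerve_per_cm2` (3), `nerve_width_mm`
#'   (0.13), `nerve_length_mm` (3), `nerve_intensity` (0.9),
#'   `adipose_per_cm2` (4), `adipose_diameter_mm` (0.5),
#'   `adipose_intensity` (0.3), `nuclei_per_mm2` (20),
#'   `nucleus_diameter_mm` (0.01), `nucleus_intensity` (0.95).
#' @param seed Integer seed (required; all randomness flows through it).
#' @return An object of class `ground_truth_surface`: `image` (matrix,
#'   rows = axial y, cols = circumferential x, values in `[0, 1]`),
#'   `mm_per_px`, `diameter_mm`, `length_mm`, `feature_log` (data frame
#'   of placed features).
#' @examples
#' s <- generate_surface(2, 3, mm_per_px = 0.01, seed = 1,
#'                       feature_params = list(nuclei_per_mm2 = 0,
#'                                             nerve_width_mm = 0.15))
#' dim(s$image)
#' @export
generate_surface <- function(diameter_mm, length_mm, mm_per_px = 0.005,
                             feature_params = list(), seed) {
  if (missing(seed)) stop("a seed is required")
  if (diameter_mm <= 0 || length_mm <= 0 || mm_per_px <= 0)
    stop("dimensions and mm_per_px must be > 0")
  p <- utils::modifyList(list(
    base_intensity = 0.55, texture_sd = 0.05,
    nerve_per_cm2 = 3, nerve_width_mm = 0.13, nerve_length_mm = 3,
    nerve_intensity = 0.9,
    adipose_per_cm2 = 4, adipose_diameter_mm = 0.5, adipose_intensity = 0.3,
    nuclei_per_mm2 = 20, nucleus_diameter_mm = 0.01,
    nucleus_intensity = 0.95), feature_params)

  # smallest requested feature must span >= 2 px to be renderable
  sizes <- c(if (p$nerve_per_cm2 > 0) p$nerve_width_mm,
             if (p$adipose_per_cm2 > 0) p$adipose_diameter_mm,
             if (p$nuclei_per_mm2 > 0) p$nucleus_diameter_mm)
  if (length(sizes) && min(sizes) / mm_per_px < 2)
    stop("resolution too coarse to render the smallest requested feature (",
         format(min(sizes)), " mm at ", format(mm_per_px), " mm/px)")

  circ_mm <- pi * diameter_mm
  nx <- round(circ_mm / mm_per_px)
  ny <- round(length_mm / mm_per_px)
  area_mm2 <- circ_mm * length_mm
  area_cm2 <- area_mm2 / 100

  with_seed(seed, {
    img <- matrix(stats::rnorm(ny * nx, 0, p$texture_sd), ny, nx)
    img <- p$base_intensity + box_blur(img, 2L) * 3   # correlated texture
    log <- list()

    # linear indices of the disc (cx, cy, r_px); assignment happens in
    # this frame so the image is modified without full copies
    disc_idx <- function(cx, cy, r_px) {
      x0 <- max(1L, floor(cx - r_px)); x1 <- min(nx, ceiling(cx + r_px))
      y0 <- max(1L, floor(cy - r_px)); y1 <- min(ny, ceiling(cy + r_px))
      if (x0 > x1 || y0 > y1) return(integer())
      xs <- x0:x1; ys <- y0:y1
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      idx <- (rep(xs, each = length(ys)) - 1L) * ny + rep(ys, length(xs))
      idx[as.vector(d2 <= r_px^2)]
    }

    # nerve tracts: random-walk polylines stamped as thick bright curves
    n_nerve <- stats::rpois(1L, p$nerve_per_cm2 * area_cm2)
    rw <- max(1, p$nerve_width_mm / 2 / mm_per_px)
    for (i in seq_len(n_nerve)) {
      cx <- stats::runif(1, 1, nx); cy <- stats::runif(1, 1, ny)
      ang <- stats::runif(1, 0, 2 * pi)
      steps <- max(2L, round(p$nerve_length_mm / mm_per_px / max(1, rw / 2)))
      for (s in seq_len(steps)) {
        idx <- disc_idx(cx, cy, rw)
        img[idx] <- p$nerve_intensity
        ang <- ang + stats::rnorm(1, 0, 0.15)
        cx <- cx + cos(ang) * max(1, rw / 2)
        cy <- cy + sin(ang) * max(1, rw / 2)
      }
      log[[length(log) + 1L]] <- data.frame(
        type = "nerve", x_mm = cx * mm_per_px, y_mm = cy * mm_per_px,
        size_mm = p$nerve_width_mm)
    }

    n_adip <- stats::rpois(1L, p$adipose_per_cm2 * area_cm2)
    for (i in seq_len(n_adip)) {
      cx <- stats::runif(1, 1, nx); cy <- stats::runif(1, 1, ny)
      idx <- disc_idx(cx, cy, p$adipose_diameter_mm / 2 / mm_per_px)
      img[idx] <- p$adipose_intensity
      log[[length(log) + 1L]] <- data.frame(
        type = "adipose", x_mm = cx * mm_per_px, y_mm = cy * mm_per_px,
        size_mm = p$adipose_diameter_mm)
    }

    n_nuc <- if (p$nuclei_per_mm2 > 0)
      stats::rpois(1L, p$nuclei_per_mm2 * area_mm2) else 0L
    if (n_nuc > 0) {
      cxs <- stats::runif(n_nuc, 1, nx); cys <- stats::runif(n_nuc, 1, ny)
      for (i in seq_len(n_nuc)) {
        idx <- disc_idx(cxs[i], cys[i], p$nucleus_diameter_mm / 2 / mm_per_px)
        img[idx] <- p$nucleus_intensity
      }
      log[[length(log) + 1L]] <- data.frame(
        type = "nucleus", x_mm = cxs * mm_per_px, y_mm = cys * mm_per_px,
        size_mm = p$nucleus_diameter_mm)
    }

    img[img < 0] <- 0; img[img > 1] <- 1
    structure(
      list(image = img, mm_per_px = mm_per_px,
           diameter_mm = diameter_mm, length_mm = length_mm,
           feature_log = if (length(log)) do.call(rbind, log) else
             data.frame(type = character(), x_mm = numeric(),
                        y_mm = numeric(), size_mm = numeric()),
           fiducials = NULL),
      class = "ground_truth_surface")
  })
}

#' @export
print.ground_truth_surface <- function(x, ...) {
  cat(sprintf("<ground_truth_surface> %d x %d px (%.1f x %.1f mm), %d features\n",
              nrow(x$image), ncol(x$image),
              ncol(x$image) * x$mm_per_px, nrow(x$image) * x$mm_per_px,
              nrow(x$feature_log)))
  invisible(x)
}

#' Ink fiducial specification
#'
#' Describes the stencil pattern painted in histological ink on the organ
#' circumference: one central line running around the circumference plus
#' short hash marks at regular spacing. Ink quenches fluorescence, so ink
#' pixels are dark.
#'
#' @param central_line_mm Axial position of the central line (mm);
#'   `NULL` places it mid-length.
#' @param hash_spacing_mm Spacing between hash marks along the
#'   circumference (default 10 mm).
#' @param hash_length_mm Axial extent of each hash mark.
#' @param line_width_mm Stroke width of the painted lines.
#' @param ink_intensity Multiplicative attenuation of underlying tissue
#'   signal at ink pixels (must be < 1 so ink is strictly darker).
#' @return An object of class `fiducial_spec`.
#' @export
fiducial_spec <- function(central_line_mm = NULL, hash_spacing_mm = 10,
                          hash_length_mm = 4, line_width_mm = 0.3,
                          ink_intensity = 0.05) {
  if (hash_spacing_mm <= 0) stop("hash_spacing_mm must be > 0")
  if (ink_intensity < 0 || ink_intensity >= 1)
    stop("ink_intensity must be in [0, 1)")
  structure(list(central_line_mm = central_line_mm,
                 hash_spacing_mm = hash_spacing_mm,
                 hash_length_mm = hash_length_mm,
                 line_width_mm = line_width_mm,
                 ink_intensity = ink_intensity),
            class = "fiducial_spec")
}

#' Paint ink fiducials onto a ground-truth surface
#'
#' Draws the stencil pattern of [fiducial_spec()]: a dark central line
#' along the full circumference and `floor(pi * d / spacing)` hash marks
#' centred at `(k + 1/2) * spacing` along the circumference. Ink is
#' applied multiplicatively so every ink pixel is strictly darker than
#' the tissue it covers. Hash positions are appended to the feature log.
#'
#' @param surface A [generate_surface()] result.
#' @param spec A [fiducial_spec()].
#' @return The surface with ink applied and `fiducials` metadata set.
#' @export
apply_fiducials <- function(surface, spec = fiducial_spec()) {
  stopifnot(inherits(surface, "ground_truth_surface"),
            inherits(spec, "fiducial_spec"))
  mmpx <- surface$mm_per_px
  if (spec$hash_spacing_mm / mmpx < 2)
    stop("hash spacing below 2 px at this resolution")
  img <- surface$image
  ny <- nrow(img); nx <- ncol(img)
  circ_mm <- pi * surface$diameter_mm
  line_mm <- if (is.null(spec$central_line_mm))
    surface$length_mm / 2 else spec$central_line_mm
  hw <- max(1L, round(spec$line_width_mm / 2 / mmpx))

  ly <- round(line_mm / mmpx)
  rows <- max(1L, ly - hw):min(ny, ly + hw)
  img[rows, ] <- img[rows, ] * spec$ink_intensity

  n_hash <- floor(circ_mm / spec$hash_spacing_mm)
  hx_mm <- (seq_len(n_hash) - 0.5) * spec$hash_spacing_mm
  hx_mm <- hx_mm[hx_mm <= circ_mm]
  hlen <- round(spec$hash_length_mm / 2 / mmpx)
  hrows <- max(1L, ly - hlen):min(ny, ly + hlen)
  for (x in hx_mm) {
    cx <- round(x / mmpx)
    cols <- max(1L, cx - hw):min(nx, cx + hw)
    img[hrows, cols] <- img[hrows, cols] * spec$ink_intensity
  }

  surface$image <- img
  surface$fiducials <- list(spec = spec, central_line_mm = line_mm,
                            hash_x_mm = hx_mm)
  surface$feature_log <- rbind(
    surface$feature_log,
    data.frame(type = "hash", x_mm = hx_mm, y_mm = line_mm,
               size_mm = spec$hash_length_mm))
  surface
}

#' Simulate a full circumferential SIM acquisition
#'
#' Forward model of the rotational imaging protocol on a synthetic
#' surface. The circumference is divided into `plan$n_panels` panels
#' (rotation starts at the posterior centre); each panel is covered by a
#' serpentine grid of frame triplets. Pixels inside the tissue-glass
#' contact patch of the geometry module (disc of radius
#' [cap_base_radius()] clipped to the face half-width, drawn in unrolled
#' coordinates about the panel centre) receive modulated signal
#' `x_i = B + truth * (1 + m sin(phi + 2 pi i / 3))`; out-of-contact
#' pixels receive only unmodulated defocused background, which square-law
#' reconstruction rejects exactly. Slippage events shift a panel's source
#' window circumferentially (rotational, degrees) and/or axially (mm).
#'
#' @param surface A [generate_surface()] result (fiducials optional).
#' @param plan An [plan_acquisition()] result for the same organ.
#' @param organ A [compressible_organ()] matching the surface diameter.
#' @param optics Named list overriding: `grid_period_px` (12, must be
#'   >= 4), `modulation_depth` (0.7), `background_level` (0.08),
#'   `defocus_strength` (0.6), `defocus_blur_mm` (0.5), `photon_noise`
#'   (FALSE), `photons_per_unit` (5000), `seed` (0).
#' @param slippage List of [slippage_event()]s.
#' @return An object of class `phantom_acquisition`: per-panel tile
#'   triplets in serpentine order with stage coordinates, ground-truth
#'   panel crops (as imaged, i.e. including slippage), contact masks,
#'   panel pixel boundaries, and the generating parameters.
#' @export
simulate_acquisition <- function(surface, plan, organ,
                                 optics = list(), slippage = list()) {
  stopifnot(inherits(surface, "ground_truth_surface"),
            inherits(plan, "acquisition_plan"),
            inherits(organ, "compressible_organ"))
  o <- utils::modifyList(list(
    grid_period_px = 12, modulation_depth = 0.7, background_level = 0.08,
    defocus_strength = 0.6, defocus_blur_mm = 0.5,
    photon_noise = FALSE, photons_per_unit = 5000, seed = 0), optics)
  if (o$grid_period_px < 4)
    stop("grid_period_px must be >= 4 (pattern unresolvable)")
  if (o$modulation_depth <= 0 || o$modulation_depth > 1)
    stop("modulation_depth must be in (0, 1]")

  mmpx <- surface$mm_per_px
  img <- surface$image
  ny <- nrow(img); nx <- ncol(img)
  n <- plan$n_panels
  W_mm <- pi * surface$diameter_mm / n
  bounds_px <- round((0:n) * W_mm / mmpx)   # panel pixel boundaries
  a_px <- cap_base_radius(organ) / mmpx
  w_px <- organ$radius_mm * (1 - organ$compressibility) * tan(pi / n) / mmpx
  yc_px <- ny / 2

  slip_rot <- numeric(n); slip_ax <- numeric(n)
  for (ev in slippage) {
    stopifnot(inherits(ev, "slippage_event"))
    if (ev$panel_index < 0 || ev$panel_index >= n)
      stop("slippage panel_index out of range")
    slip_rot[ev$panel_index + 1L] <- ev$rotational_deg
    slip_ax[ev$panel_index + 1L] <- ev$axial_mm
  }

  defocus <- o$defocus_strength *
    box_blur(img, max(1L, round(o$defocus_blur_mm / mmpx / 2)))

  tile_px <- round(plan$frame_fov_mm / mmpx)
  step_px <- max(1L, round(plan$frame_fov_mm * (1 - plan$overlap_fraction) / mmpx))
  order_df <- serpentine_coords(plan$frames_x, plan$frames_y)

  panels <- with_seed(o$seed, lapply(seq_len(n), function(k) {
    wk <- bounds_px[k + 1L] - bounds_px[k]
    # source columns: nominal window shifted by rotational slip, wrapped;
    # the shift is applied in mm before rounding so a slip of exactly one
    # panel pitch lands on the previous panel's pixel window
    shift_mm <- slip_rot[k] / 360 * pi * surface$diameter_mm
    start_px <- round(((k - 1L) * W_mm + shift_mm) / mmpx)
    cols <- ((start_px + seq_len(wk) - 1L) %% nx) + 1L
    truth <- img[, cols, drop = FALSE]
    defoc <- defocus[, cols, drop = FALSE]
    ax_px <- round(slip_ax[k] / mmpx)
    if (ax_px != 0) {
      truth <- shift_fill(truth, dy = -ax_px)
      defoc <- shift_fill(defoc, dy = -ax_px)
    }
    # contact patch about the panel centre, in panel-local coordinates
    u <- (seq_len(wk) - (wk + 1) / 2)
    v <- (seq_len(ny) - yc_px)
    mask <- outer(v^2, u^2, "+") <= a_px^2
    mask <- mask & matrix(abs(u) <= w_px, ny, wk, byrow = TRUE)

    tiles <- lapply(seq_len(nrow(order_df)), function(t) {
      ix <- order_df$ix[t]; iy <- order_df$iy[t]
      x0 <- ix * step_px; y0 <- iy * step_px
      xs <- x0 + seq_len(tile_px); ysq <- y0 + seq_len(tile_px)
      crop <- function(m) {
        out <- matrix(0, tile_px, tile_px)
        vx <- xs[xs <= ncol(m)]; vy <- ysq[ysq <= nrow(m)]
        out[seq_along(vy), seq_along(vx)] <- m[vy, vx, drop = FALSE]
        out
      }
      tr <- crop(truth); df <- crop(defoc)
      mk <- matrix(FALSE, tile_px, tile_px)
      vx <- xs[xs <= wk]; vy <- ysq[ysq <= ny]
      mk[seq_along(vy), seq_along(vx)] <- mask[vy, vx, drop = FALSE]
      phase <- 2 * pi * matrix(seq_len(tile_px) - 1L, tile_px, tile_px,
                               byrow = TRUE) / o$grid_period_px
      fr <- lapply(0:2, function(i) {
        x <- o$background_level + ifelse(
          mk, tr * (1 + o$modulation_depth * sin(phase + 2 * pi * i / 3)),
          df)
        if (o$photon_noise)
          x <- stats::rpois(length(x), x * o$photons_per_unit) /
            o$photons_per_unit
        matrix(pmax(x, 0), tile_px, tile_px)
      })
      list(ix = ix, iy = iy,
           stage_x_mm = x0 * mmpx, stage_y_mm = y0 * mmpx,
           triplet = frame_triplet(fr[[1L]], fr[[2L]], fr[[3L]],
                                   grid_period_px = o$grid_period_px))
    })
    list(panel_index = k - 1L, tiles = tiles, truth = truth,
         contact_mask = mask, width_px = wk,
         rotational_deg = slip_rot[k], axial_mm = slip_ax[k])
  }))

  structure(list(panels = panels, plan = plan, organ = organ,
                 optics = o, mm_per_px = mmpx,
                 bounds_px = bounds_px, tile_px = tile_px,
                 step_px = step_px, surface_dim = dim(img)),
            class = "phantom_acquisition")
}

#' @export
print.phantom_acquisition <- function(x, ...) {
  cat(sprintf("<phantom_acquisition> %d panels x %d tiles (%d px, step %d px)\n",
              length(x$panels), length(x$panels[[1L]]$tiles),
              x$tile_px, x$step_px))
  invisible(x)
}

#' Slippage event
#'
#' A rotational and/or axial slip of the organ on its mounting rod before
#' a given panel is imaged, displacing that panel's source window.
#'
#' @param panel_index 0-based panel index.
#' @param rotational_deg Signed rotational slip in degrees (`-360/n`
#'   makes the panel re-image its predecessor's window).
#' @param axial_mm Signed axial slip in mm.
#' @return An object of class `slippage_event`.
#' @export
slippage_event <- function(panel_index, rotational_deg = 0, axial_mm = 0) {
  if (panel_index < 0) stop("panel_index must be >= 0")
  structure(list(panel_index = as.integer(panel_index),
                 rotational_deg = rotational_deg, axial_mm = axial_mm),
            class = "slippage_event")
}

#' Write a phantom acquisition to disk
#'
#' Writes every frame as a 16-bit TIFF named
#' `panel<k>_x<ix>_y<iy>_p<phase>.tif` plus a `manifest.csv` with columns
#' `panel, ix, iy, stage_x_mm, stage_y_mm, phase_index, file`.
#'
#' @param acq A [simulate_acquisition()] result.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_acquisition <- function(acq, dir) {
  stopifnot(inherits(acq, "phantom_acquisition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (p in acq$panels) for (t in p$tiles) for (i in 0:2) {
    f <- sprintf("panel%02d_x%02d_y%02d_p%d.tif",
                 p$panel_index, t$ix, t$iy, i)
    frame <- t$triplet[[c("x1", "x2", "x3")[i + 1L]]]
    write_frame_tif(frame / max(1, max(frame)), file.path(dir, f))
    rows[[length(rows) + 1L]] <- data.frame(
      panel = p$panel_index, ix = t$ix, iy = t$iy,
      stage_x_mm = t$stage_x_mm, stage_y_mm = t$stage_y_mm,
      phase_index = i, file = f)
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
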