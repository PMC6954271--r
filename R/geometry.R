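#' Compressible-organ model
#'
#' Describes an excised organ (the motivating case is a radical
#' prostatectomy specimen) as a compressible sphere resting under its own
#' weight against a glass slide. Flattening depth is `h = r * c`, where `c`
#' is the dimensionless compressibility coefficient (fraction of the radius
#' lost to flattening).
#'
#' @param diameter_mm Organ diameter in mm (`d = 2r`).
#' @param length_mm Apex-to-base length in mm.
#' @param compressibility Compressibility coefficient `c` in `[0, 1)`.
#'   Default 0.2, the typical value for dense glandular tissue.
#'
#' @return An object of class `compressible_organ` with fields
#'   `radius_mm`, `diameter_mm`, `length_mm`, `compressibility`.
#' @examples
#' organ <- compressible_organ(diameter_mm = 40, length_mm = 35)
#' cap_base_radius(organ)
#' @export
compressible_organ <- function(diameter_mm, length_mm, compressibility = 0.2) {
  stopifnot(is.numeric(diameter_mm), length(diameter_mm) == 1L,
            is.numeric(length_mm), length(length_mm) == 1L)
  if (diameter_mm <= 0) stop("diameter_mm must be > 0")
  if (length_mm <= 0) stop("length_mm must be > 0")
  check_compressibility(compressibility)
  structure(
    list(radius_mm = diameter_mm / 2,
         diameter_mm = diameter_mm,
         length_mm = length_mm,
         compressibility = compressibility),
    class = "compressible_organ")
}

#' @export
print.compressible_organ <- function(x, ...) {
  cat(sprintf("<compressible_organ> d = %g mm, L = %g mm, c = %g (h = %.3g mm)\n",
              x$diameter_mm, x$length_mm, x$compressibility,
              x$radius_mm * x$compressibility))
  invisible(x)
}

check_compressibility <- function(c) {
  if (!is.numeric(c) || anyNA(c) || any(c < 0) || any(c >= 1))
    stop("compressibility must lie in [0, 1)")
  invisible(c)
}

#' Radius of the tissue-glass contact disc
#'
#' Base radius `a` of the spherical cap cut off by the slide plane:
#' `a = sqrt(2 r h - h^2)` with flattening depth `h = r c`, hence
#' `a = r * sqrt(2c - c^2)`.
#'
#' @param organ A [compressible_organ()].
#' @return Contact disc radius in mm.
#' @export
cap_base_radius <- function(organ) {
  stopifnot(inherits(organ, "compressible_organ"))
  c <- organ$compressibility
  organ$radius_mm * sqrt(2 * c - c^2)
}

#' Area of the tissue-glass contact patch
#'
#' Area of the base disc of the spherical cap,
#' `A = pi * a^2 = pi (2 r^2 c - r^2 c^2)`. Scales as `r^2`.
#'
#' @inheritParams cap_base_radius
#' @return Contact area in mm^2.
#' @export
contact_patch_area <- function(organ) {
  pi * cap_base_radius(organ)^2
}

#' Four-aspect surface coverage of a compressible sphere
#'
#' Fraction of the sphere surface imageable by flattening the specimen
#' against four orthogonal planes (one 90-degree manual rotation between
#' acquisitions): `S_I = 4 * (pi a^2) / (4 pi r^2) = 2c - c^2`, independent
#' of the radius. Valid only up to the compressibility at which the four
#' contact discs first touch (see [max_four_aspect_compressibility()]);
#' beyond that the planes intersect and the model no longer applies, so
#' larger `c` is an error rather than a clipped value.
#'
#' @param c Compressibility coefficient in `[0, 1 - 1/sqrt(2)]`.
#' @return Coverage fraction in `[0, 0.5]`.
#' @examples
#' four_aspect_coverage(0.2)  # 0.36
#' @export
four_aspect_coverage <- function(c) {
  check_compressibility(c)
  cmax <- max_four_aspect_compressibility()
  if (any(c > cmax + 1e-12))
    stop("four-aspect model only valid for c <= 1 - 1/sqrt(2); ",
         "see max_four_aspect_compressibility()")
  2 * c - c^2
}

#' Maximum compressibility of the four-aspect model
#'
#' The flattening fraction at which the four contact discs touch:
#' from `a = R/sqrt(2) = R - h`, `h/R = 1 - 1/sqrt(2)` (about 0.29).
#' At this bound the four-aspect coverage is exactly 50%.
#'
#' @return `1 - 1/sqrt(2)`, exactly.
#' @export
max_four_aspect_compressibility <- function() {
  1 - 1 / sqrt(2)
}

#' Surface coverage of the n-rotation polygonal imaging scheme
#'
#' Coverage model for imaging the organ circumference in `n` standardized
#' strips with the organ re-flattened against a tangent plane between
#' rotations (the cross-section is a circle inscribed in a regular n-gon;
#' the canonical protocol uses `n = 10`, a decagon). Two constructions are
#' provided:
#'
#' * `"clipped_disc"` (default): each face contributes the contact disc of
#'   radius `a = r sqrt(2c - c^2)` clipped to the face's azimuthal
#'   half-width `w = r (1 - c) tan(pi/n)`. Clipped area is `pi a^2` when
#'   `w >= a` (no clipping; reduces to the four-aspect model), otherwise
#'   `2 [ w sqrt(a^2 - w^2) + a^2 asin(w/a) ]`. Coverage is
#'   `n * clipped_area / (4 pi r^2)`.
#' * `"band_limit"`: the `n -> Inf` limit, a contact band of compressed
#'   circumference `2 pi r (1 - c)` and axial extent `2a`, giving coverage
#'   `(1 - c) sqrt(2c - c^2)` exactly.
#'
#' Both are radius-independent and both give 48% (0.4804 and 0.4800) at
#' the canonical `c = 0.2`, `n = 10`.
#'
#' @param c Compressibility coefficient in `[0, 1)`.
#' @param n Number of rotations/panels (`>= 3`). Ignored for
#'   `"band_limit"`.
#' @param mode `"clipped_disc"` or `"band_limit"`.
#' @param radius_mm Sphere radius used to report the per-panel contact
#'   area; the coverage fraction itself does not depend on it.
#' @return An object of class `coverage_result` with fields `model`,
#'   `n_panels`, `coverage_fraction`, `contact_area_per_panel` (mm^2) and
#'   `face_half_width` (mm, clipped-disc mode only).
#' @examples
#' polygonal_coverage(0.2, n = 10)$coverage_fraction        # 0.4804
#' polygonal_coverage(0.2, mode = "band_limit")$coverage_fraction  # 0.48
#' @export
polygonal_coverage <- function(c, n = 10L,
                               mode = c("clipped_disc", "band_limit"),
                               radius_mm = 1) {
  mode <- match.arg(mode)
  check_compressibility(c)
  a <- sqrt(2 * c - c^2)                 # unit-radius contact disc radius
  if (mode == "band_limit") {
    frac <- (1 - c) * a
    res <- list(model = "band_limit", n_panels = NA_integer_,
                coverage_fraction = frac,
                contact_area_per_panel = NA_real_,
                face_half_width = NA_real_)
  } else {
    if (!is.numeric(n) || length(n) != 1L || n < 3) stop("n must be >= 3")
    w <- (1 - c) * tan(pi / n)           # face azimuthal half-width, unit r
    clip <- clipped_disc_area(a, w)
    res <- list(model = "clipped_disc", n_panels = as.integer(n),
                coverage_fraction = n * clip / (4 * pi),
                contact_area_per_panel = clip * radius_mm^2,
                face_half_width = w * radius_mm)
  }
  structure(res, class = "coverage_result")
}

# Area of a disc of radius a clipped to the vertical slab |x| <= w.
clipped_disc_area <- function(a, w) {
  if (a == 0) return(0)
  if (w >= a) return(pi * a^2)
  2 * (w * sqrt(a^2 - w^2) + a^2 * asin(w / a))
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> model = %s%s, coverage = %.4f (%.1f%%)\n",
              x$model,
              if (!is.na(x$n_panels)) sprintf(", n = %d", x$n_panels) else "",
              x$coverage_fraction, 100 * x$coverage_fraction))
  invisible(x)
}

#' Numerical oracle for the polygonal coverage model
#'
#' Independent check of [polygonal_coverage()]: integrates the per-face
#' clipped contact disc numerically — the chord length `2 sqrt(a^2 - x^2)`
#' of the disc of radius `a` is accumulated over a midpoint grid of the
#' clipped azimuthal extent `|x| <= min(w, a)` — and returns
#' `n * area / (4 pi r^2)`. Deterministic; never calls the closed form.
#'
#' @inheritParams polygonal_coverage
#' @param resolution Number of quadrature points (`>= 100`).
#' @return Coverage fraction.
#' @export
coverage_numeric_oracle <- function(c, n = 10L, resolution = 400L) {
  check_compressibility(c)
  if (resolution < 100) stop("resolution must be >= 100")
  if (n < 3) stop("n must be >= 3")
  a <- sqrt(2 * c - c^2)
  if (a == 0) return(0)
  w <- min((1 - c) * tan(pi / n), a)
  h <- 2 * w / resolution
  xs <- seq(-w + h / 2, w - h / 2, length.out = resolution)
  area <- sum(2 * sqrt(pmax(a^2 - xs^2, 0))) * h
  n * area / (4 * pi)
}

#' Plan a circumferential panel acquisition
#'
#' Computes the panel geometry and frame grid for imaging the full organ
#' circumference in `n_panels` rotations. Diameter and length are first
#' rounded up to whole millimetres (ruler-measurement policy); each panel
#' then has width `pi * d / n` (the arc length of a `360/n` degree central
#' angle) and the full specimen length. The frame grid uses a step of
#' `frame_fov * (1 - overlap)` with ceiling counts so the panel is fully
#' tiled.
#'
#' @param diameter_mm,length_mm Organ dimensions in mm (rounded up to
#'   whole mm before planning).
#' @param n_panels Number of rotations (default 10).
#' @param frame_fov_mm Single-frame field of view in mm (default 1.3, a
#'   2048 px camera at 0.645 um per pixel).
#' @param overlap_fraction Fraction of each frame shared with its
#'   neighbour, in `[0, 1)`.
#' @return An object of class `acquisition_plan`.
#' @examples
#' plan_acquisition(50, 40, n_panels = 10, frame_fov_mm = 1.3,
#'                  overlap_fraction = 0)
#' @export
plan_acquisition <- function(diameter_mm, length_mm, n_panels = 10L,
                             frame_fov_mm = 1.3, overlap_fraction = 0.1) {
  if (diameter_mm <= 0 || length_mm <= 0) stop("dimensions must be > 0")
  if (frame_fov_mm <= 0) stop("frame_fov_mm must be > 0")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  if (n_panels < 3) stop("n_panels must be >= 3")
  d <- ceiling(diameter_mm)
  L <- ceiling(length_mm)
  panel_width <- pi * d / n_panels
  step <- frame_fov_mm * (1 - overlap_fraction)
  frames_x <- as.integer(ceiling(panel_width / step))
  frames_y <- as.integer(ceiling(L / step))
  structure(
    list(n_panels = as.integer(n_panels),
         central_angle_deg = 360 / n_panels,
         diameter_mm = d,
         panel_width_mm = panel_width,
         panel_length_mm = as.numeric(L),
         frame_fov_mm = frame_fov_mm,
         overlap_fraction = overlap_fraction,
         frames_x = frames_x,
         frames_y = frames_y,
         total_frames = as.integer(n_panels) * frames_x * frames_y),
    class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf(paste0(
    "<acquisition_plan> %d panels x %g deg\n",
    "  panel: %.3f x %g mm; frames %d x %d (fov %g mm, overlap %g)\n",
    "  total frames: %d (x3 phase images)\n"),
    x$n_panels, x$central_angle_deg, x$panel_width_mm, x$panel_length_mm,
    x$frames_x, x$frames_y, x$frame_fov_mm, x$overlap_fraction,
    x$total_frames))
  invisible(x)
}
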