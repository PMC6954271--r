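# Shared phantom fixtures, built once per test run and cached.
#
# The standard phantom is a d = 40 mm, L = 30 mm organ at compressibility
# 0.2 imaged in 10 rotations, rendered at 0.05 mm/px (coarse enough to be
# fast; nucleus size is scaled up to stay renderable at that pitch).

phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = phantom_cache))
    assign(key, force(expr), envir = phantom_cache)
  get(key, envir = phantom_cache)
}

std_mm_per_px <- 0.05

std_feature_params <- function()
  list(nucleus_diameter_mm = 0.2, nuclei_per_mm2 = 0.5)

std_organ <- function() compressible_organ(40, 30, compressibility = 0.2)

std_plan <- function()
  plan_acquisition(40, 30, n_panels = 10, frame_fov_mm = 6.4,
                   overlap_fraction = 0.1)

std_surface <- function() cached("surface", {
  apply_fiducials(
    generate_surface(40, 30, std_mm_per_px, std_feature_params(), seed = 42),
    fiducial_spec())
})

std_acq <- function() cached("acq", {
  simulate_acquisition(std_surface(), std_plan(), std_organ())
})

std_recon <- function() cached("recon", {
  suppressWarnings(reconstruct_acquisition(std_acq()))
})

# acquisition with a known axial slip on panel 4 (0-based)
slipped_acq <- function() cached("slipped", {
  simulate_acquisition(std_surface(), std_plan(), std_organ(),
                       slippage = list(slippage_event(4, axial_mm = 2)))
})

slipped_recon <- function() cached("slipped_recon", {
  suppressWarnings(reconstruct_acquisition(slipped_acq()))
})

# contact mask of the clean phantom in panorama coordinates
std_contact_mask <- function() cached("mask", {
  do.call(cbind, lapply(std_acq()$panels, function(p) p$contact_mask))
})

# independent brute-force Otsu oracle: same 256-bin histogram, threshold
# chosen by direct loop over all candidate splits
otsu_oracle_threshold <- function(v, levels = 256L) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), levels),
    nbins = levels)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  best_k <- NA_integer_; best <- -Inf
  n <- sum(counts)
  for (k in seq_len(levels - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):levels] * mids[(k + 1):levels]) / n1
    sb2 <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (sb2 > best) { best <- sb2; best_k <- k }
  }
  breaks[best_k + 1L]
}

# 12-triangle unit cube mesh (mm)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),    # z = 0
    c(5, 6, 8), c(5, 8, 7),    # z = 1
    c(1, 2, 6), c(1, 6, 5),    # y = 0
    c(3, 7, 8), c(3, 8, 4),    # y = 1
    c(1, 5, 7), c(1, 7, 3),    # x = 0
    c(2, 4, 8), c(2, 8, 6))    # x = 1
  surface_mesh(v, f)
}
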