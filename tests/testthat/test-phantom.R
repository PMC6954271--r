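test_that("surface generation is seed-deterministic with the declared
           geometry and Poisson feature counts", {
  fp <- list(nuclei_per_mm2 = 100, nucleus_diameter_mm = 0.012,
             nerve_per_cm2 = 0, adipose_per_cm2 = 0)
  s1 <- generate_surface(1, 3.2, mm_per_px = 0.005, fp, seed = 9)
  s2 <- generate_surface(1, 3.2, mm_per_px = 0.005, fp, seed = 9)
  expect_identical(s1$image, s2$image)
  expect_false(identical(
    s1$image,
    generate_surface(1, 3.2, mm_per_px = 0.005, fp, seed = 10)$image))

  # width_px * mm_per_px = pi * d within one pixel
  expect_equal(ncol(s1$image), round(pi * 1 / 0.005))
  expect_true(all(s1$image >= 0 & s1$image <= 1))

  # Poisson draw at density 100 / mm^2 over the surface area
  lambda <- 100 * pi * 1 * 3.2
  n_nuc <- sum(s1$feature_log$type == "nucleus")
  expect_lt(abs(n_nuc - lambda), 4 * sqrt(lambda))

  # spec example: d = 40 mm at 0.02 mm/px is 6283 px wide
  expect_equal(round(pi * 40 / 0.02), 6283)

  expect_error(generate_surface(40, 30, mm_per_px = 0.05, seed = 1),
               "too coarse")   # 10 um nuclei are not renderable at 50 um/px
})

test_that("fiducials are placed at exact spacing and strictly darker than
           tissue", {
  surf <- std_surface()
  expect_equal(length(surf$fiducials$hash_x_mm), floor(pi * 40 / 10))  # 12
  expect_equal(diff(surf$fiducials$hash_x_mm),
               rep(10, length(surf$fiducials$hash_x_mm) - 1L))
  # ink attenuates multiplicatively, so marked pixels are darker than the
  # same pixels before inking
  raw <- cached("surface_raw", generate_surface(
    40, 30, std_mm_per_px, std_feature_params(), seed = 42))
  ly <- round(surf$fiducials$central_line_mm / std_mm_per_px)
  expect_true(all(surf$image[ly, ] < raw$image[ly, ]))
  expect_error(
    apply_fiducials(raw, fiducial_spec(hash_spacing_mm = 0.05)),
    "2 px")
})

test_that("simulated triplets invert exactly through the square law on
           contact pixels and reject out-of-contact background", {
  acq <- std_acq()
  p <- acq$panels[[1L]]
  m <- acq$optics$modulation_depth
  # reconstruct one tile and compare against (3/sqrt(2)) * m * truth
  t <- p$tiles[[8L]]
  rec <- square_law_reconstruct(t$triplet)$image
  x0 <- round(t$stage_x_mm / acq$mm_per_px)
  y0 <- round(t$stage_y_mm / acq$mm_per_px)
  sub_mask <- p$contact_mask[y0 + seq_len(acq$tile_px),
                             x0 + seq_len(min(acq$tile_px,
                                              p$width_px - x0))]
  sub_truth <- p$truth[y0 + seq_len(acq$tile_px),
                       x0 + seq_len(ncol(sub_mask))]
  rec <- rec[, seq_len(ncol(sub_mask))]
  inc <- sub_mask & sub_truth > 0
  expect_gt(sum(inc), 100)
  expect_equal(rec[inc], (3 / sqrt(2)) * m * sub_truth[inc],
               tolerance = 1e-6)
  # out-of-contact pixels reconstruct to (numerically) zero
  expect_lt(max(rec[!sub_mask]), 1e-2 * stats::median(rec[inc]))

  expect_error(
    simulate_acquisition(std_surface(), std_plan(), std_organ(),
                         optics = list(grid_period_px = 3)),
    "unresolvable")
})

test_that("rotational slippage of one panel pitch re-images the previous
           window", {
  acq <- cached("repeat_acq", simulate_acquisition(
    std_surface(), std_plan(), std_organ(),
    slippage = list(slippage_event(2, rotational_deg = -36))))
  # panels 1 and 2 (0-based) now share their source window
  w <- min(acq$panels[[2L]]$width_px, acq$panels[[3L]]$width_px)
  expect_equal(acq$panels[[3L]]$truth[, seq_len(w)],
               acq$panels[[2L]]$truth[, seq_len(w)])
})

test_that("acquisition writes a tile manifest and TIFFs that round-trip", {
  surf <- generate_surface(4, 4, mm_per_px = 0.05, seed = 3,
                           feature_params = list(
                             nuclei_per_mm2 = 0, adipose_per_cm2 = 20,
                             nerve_per_cm2 = 10, nerve_length_mm = 1))
  plan <- plan_acquisition(4, 4, n_panels = 4, frame_fov_mm = 2,
                           overlap_fraction = 0.1)
  acq <- simulate_acquisition(surf, plan,
                              compressible_organ(4, 4, 0.2))
  dir <- tempfile()
  write_acquisition(acq, dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3 * sum(vapply(acq$panels, function(p)
    length(p$tiles), 1L)))
  expect_true(all(file.exists(file.path(dir, man$file))))
  img <- read_frame_tif(file.path(dir, man$file[1]))
  expect_equal(dim(img), c(acq$tile_px, acq$tile_px))
  unlink(dir, recursive = TRUE)
})
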