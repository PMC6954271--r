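test_that("fiducial detection recovers line and hash positions on the
           ground-truth surface", {
  surf <- std_surface()
  ms <- detect_fiducials(surf, mm_per_px = std_mm_per_px)
  expect_equal(ms$central_line_y_px, 15 / std_mm_per_px, tolerance = 2)
  truth_px <- surf$fiducials$hash_x_mm / std_mm_per_px
  expect_equal(length(ms$hash_x_positions_px), 12L)   # floor(pi*40/10)
  expect_lt(max(abs(sort(ms$hash_x_positions_px) - truth_px)), 2)
  expect_gt(ms$confidence, 0.5)
  # unmarked image yields an empty set with zero confidence
  expect_warning(
    empty <- detect_fiducials(matrix(0.5, 60, 60), mm_per_px = 0.05),
    "no fiducial")
  expect_equal(length(empty$hash_x_positions_px), 0L)
  expect_equal(empty$confidence, 0)
})

test_that("hash spacing is measured at the stencil value, tolerating
           invisible marks", {
  # synthetic positions: 100 px apart at 0.1 mm/px
  ms <- marker_set(50, c(0, 100, 200))
  expect_equal(measure_hash_spacing(ms, 0.1), 10)
  # a missing middle mark must not bias the estimate
  ms2 <- marker_set(50, c(0, 100, 300, 400))
  expect_equal(measure_hash_spacing(ms2, 0.1), 10)
  expect_error(measure_hash_spacing(marker_set(50, c(3)), 0.1),
               "at least 2")
  # on the reconstructed phantom panorama: 10.0 +/- 0.1 mm
  msp <- detect_fiducials(std_recon()$panorama, mm_per_px = std_mm_per_px)
  expect_gte(length(msp$hash_x_positions_px), 2L)
  expect_equal(measure_hash_spacing(msp, std_mm_per_px), 10,
               tolerance = 0.01)
})

test_that("alignment is zero for clean panels and idempotent", {
  rec <- std_recon()
  al <- suppressWarnings(align_panels(rec$panels,
                                      mm_per_px = std_mm_per_px))
  expect_true(all(abs(al$offsets$axial_offset_px) <= 1))
  expect_true(all(abs(al$offsets$circ_shift_px) <= 1))
  expect_false(any(al$duplicate_flags$is_repeat))
  # idempotence: aligning the corrected panels changes nothing
  corr <- apply_alignment(rec$panels, al)
  al2 <- suppressWarnings(align_panels(corr, mm_per_px = std_mm_per_px))
  expect_true(all(abs(al2$offsets$axial_offset_px) <= 1))
  expect_true(all(abs(al2$offsets$circ_shift_px) <= 1))
})

test_that("injected axial slippage is detected and corrected so seams
           regain continuity", {
  rec <- slipped_recon()
  al <- suppressWarnings(align_panels(rec$panels,
                                      mm_per_px = std_mm_per_px))
  # panel 4 (0-based) slipped +2 mm axially; recovered within 2 px
  expect_equal(al$offsets$axial_offset_px[5], 2 / std_mm_per_px,
               tolerance = 2)
  expect_true(all(al$offsets$axial_offset_px[-5] == 0))

  tr <- std_surface()$image
  raw_pano <- assemble_rollout(rec$panels)
  corr_pano <- assemble_rollout(apply_alignment(rec$panels, al))
  b <- corr_pano$panel_boundaries[-1]
  raw_seams <- vapply(b, function(x) seam_ncc(raw_pano, tr, x), 1)
  corr_seams <- vapply(b, function(x) seam_ncc(corr_pano, tr, x), 1)
  expect_lt(min(raw_seams), 0.95)          # the slip is visible before
  expect_true(all(corr_seams > 0.95))      # and gone after correction
})

test_that("duplicate-content detection measures the shared span and is
           symmetric", {
  rec <- std_recon()
  A <- rec$panels[[3]]$image
  # identical panels: full overlap
  d <- detect_duplicate_overlap(A, A)
  expect_gt(d$overlap_fraction, 0.95)
  expect_true(d$is_repeat)
  # independent textures: no overlap
  set.seed(13)
  t1 <- box_blur(matrix(stats::runif(200 * 150), 200), 2)
  t2 <- box_blur(matrix(stats::runif(200 * 150), 200), 2)
  d0 <- detect_duplicate_overlap(t1, t2)
  expect_lt(d0$overlap_fraction, 0.1)
  expect_false(d0$is_repeat)
  # symmetry within one pixel on the full-repeat phantom
  acq <- cached("repeat_acq", simulate_acquisition(
    std_surface(), std_plan(), std_organ(),
    slippage = list(slippage_event(2, rotational_deg = -36))))
  rec2 <- cached("repeat_recon",
                 suppressWarnings(reconstruct_acquisition(acq)))
  dab <- detect_duplicate_overlap(rec2$panels[[2]]$image,
                                  rec2$panels[[3]]$image)
  dba <- detect_duplicate_overlap(rec2$panels[[3]]$image,
                                  rec2$panels[[2]]$image)
  expect_gt(dab$overlap_fraction, 0.95)
  expect_equal(dab$overlap_fraction, dba$overlap_fraction,
               tolerance = 1 / ncol(rec2$panels[[2]]$image))
})

test_that("a 90 % duplicated panel is flagged and the repeat policy
           applied", {
  acq <- simulate_acquisition(
    std_surface(), std_plan(), std_organ(),
    slippage = list(slippage_event(3, rotational_deg = -0.9 * 36)))
  rec <- suppressWarnings(reconstruct_acquisition(acq))
  d <- detect_duplicate_overlap(rec$panels[[3]]$image,
                                rec$panels[[4]]$image)
  expect_equal(d$overlap_fraction, 0.9, tolerance = 0.05)
  expect_true(d$is_repeat)

  al <- suppressWarnings(align_panels(rec$panels,
                                      mm_per_px = std_mm_per_px))
  expect_true(al$duplicate_flags$is_repeat[3])
  dropped <- apply_alignment(rec$panels, al, policy = "drop")
  expect_equal(length(dropped), 9L)
  trimmed <- apply_alignment(rec$panels, al, policy = "trim")
  expect_equal(length(trimmed), 10L)
  expect_lt(ncol(trimmed[[4]]), ncol(rec$panels[[4]]$image))
})
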