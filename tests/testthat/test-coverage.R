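test_that("Otsu threshold equals the exhaustive between-class-variance
           maximizer", {
  set.seed(2)
  # bimodal Gaussian mixture
  img <- matrix(c(stats::rnorm(5000, 0.2, 0.05),
                  stats::rnorm(5000, 0.8, 0.05)), 100)
  thr <- otsu_threshold(img)
  expect_equal(thr, otsu_oracle_threshold(as.numeric(img)))
  truth <- rep(c(FALSE, TRUE), each = 5000)
  expect_lt(mean((img > thr) != truth), 0.01)

  # oracle equivalence on assorted histograms, including integer-valued
  for (s in 1:4) {
    set.seed(s)
    v <- switch(s,
                stats::runif(2000),
                stats::rexp(2000),
                sample(0:255, 3000, replace = TRUE,
                       prob = (1 + (0:255 %% 7))),
                c(stats::rnorm(500, 10, 1), stats::rnorm(1500, 30, 4)))
    expect_equal(otsu_threshold(matrix(v, 1)), otsu_oracle_threshold(v))
  }
  expect_warning(m <- otsu_tissue_mask(matrix(5, 4, 4)), "constant")
  expect_false(any(m))
})

test_that("Otsu classification agrees with EBImage", {
  set.seed(6)
  img <- matrix(c(stats::runif(3000, 0, 0.35),
                  stats::runif(1000, 0.5, 1)), 50)
  # inside an empty histogram gap the variance criterion ties, so the
  # two implementations may pick different gap bins; the resulting
  # classifications must still agree
  expect_equal(otsu_tissue_mask(img),
               img > EBImage::otsu(img, range = range(img), levels = 256))
  # on a gap-free bimodal image the thresholds themselves agree to a bin
  img2 <- matrix(c(stats::rnorm(3000, 0.3, 0.08),
                   stats::rnorm(1000, 0.7, 0.08)), 50)
  expect_equal(otsu_threshold(img2),
               EBImage::otsu(img2, range = range(img2), levels = 256),
               tolerance = 2 * diff(range(img2)) / 256)
})

test_that("mask area and coverage percentage follow the pixel-pitch
           arithmetic", {
  expect_equal(area_from_mask(matrix(TRUE, 1000, 1000), 0.645),
               1e6 * 0.645^2 * 1e-8)
  expect_equal(area_from_mask(matrix(FALSE, 10, 10), 0.645), 0)
  expect_equal(area_from_mask(matrix(TRUE, 2048, 2048), 0.645),
               (2048 * 0.645e-4)^2)      # 0.01745 cm^2 per full frame
  expect_equal(coverage_percent(26.63, 67.56), 39.42, tolerance = 1e-3)
  expect_equal(coverage_percent(30.64, 67.56), 45.35, tolerance = 1e-3)
  expect_equal(coverage_percent(0, 50), 0)
  expect_error(coverage_percent(10, 0), "surface_area")
})

test_that("mesh surface areas follow the half-cross-product rule", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  expect_equal(mesh_surface_area(tri), 0.005)     # 0.5 mm^2
  expect_equal(mesh_surface_area(cube_mesh()), 0.06)  # 6 mm^2
  ico <- icosphere(20, subdivisions = 4)
  expect_equal(mesh_surface_area(ico), 4 * pi * 400 / 100,
               tolerance = 0.005)
  expect_error(surface_mesh(matrix(0, 3, 3), rbind(c(1, 2, 4))),
               "out of range")
})

test_that("ascii mesh readers agree with each other and the constructor", {
  m <- icosphere(5, subdivisions = 1)
  ply <- tempfile(fileext = ".ply")
  write_surface_mesh(m, ply)
  m2 <- read_surface_mesh(ply)
  expect_equal(mesh_surface_area(m2), mesh_surface_area(m),
               tolerance = 1e-5)
  # OBJ with quad face is fan-triangulated
  obj <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), obj)
  expect_equal(mesh_surface_area(read_surface_mesh(obj)), 0.01) # 1 mm^2
  stl <- tempfile(fileext = ".stl")
  writeLines(c("solid t", "facet normal 0 0 1", "outer loop",
               "vertex 0 0 0", "vertex 2 0 0", "vertex 0 2 0",
               "endloop", "endfacet", "endsolid t"), stl)
  expect_equal(mesh_surface_area(read_surface_mesh(stl)), 0.02) # 2 mm^2
  unlink(c(ply, obj, stl))
})

test_that("case-series summary reproduces printed-table statistics with
           population SDs", {
  tab <- read_case_table(system.file("extdata", "table1.csv",
                                     package = "circumscan"))
  rep <- summarize_cases(tab)
  man <- rep$summary[rep$summary$method == "manual", ]
  expect_equal(man$mean_sim_area_cm2, 21.95)
  expect_equal(man$sd_sim_area_cm2, 5.18)
  expect_equal(man$mean_surface_area_cm2, 67.56)
  expect_equal(man$sd_surface_area_cm2, 11.49)
  expect_equal(man$mean_coverage_pct, 33.27)
  expect_equal(man$sd_coverage_pct, 9.56)
  expect_equal(man$mean_elapsed_min, 43)
  expect_equal(man$sd_elapsed_min, 6)
  # the population/sample discriminator: sample SD does NOT reproduce it
  i <- tab$method == "manual"
  expect_gt(stats::sd(tab$sim_area_cm2[i]), 5.18 + 0.1)

  apps <- rep$summary[rep$summary$method == "apps", ]
  expect_equal(apps$mean_coverage_pct, 42.39)
  expect_equal(apps$mean_elapsed_min, 36)
  expect_equal(unname(rep$throughput["manual"]), 0.5)
  expect_equal(unname(rep$throughput["apps"]), 0.8)
  expect_equal(rep$throughput_ratio, 1.6)
  # single record: SD 0
  one <- summarize_cases(tab[1, ])
  expect_equal(one$summary$sd_sim_area_cm2, 0)
  expect_error(summarize_cases(tab[0, ]), "no case")
})

test_that("pathology sampling fraction and improvement factor", {
  expect_equal(pathology_sampling_fraction(), 100 * 4 / 3000)
  expect_equal(round(pathology_sampling_fraction(), 3), 0.133)
  expect_equal(round(coverage_improvement_factor(42.39)), 318)
})

test_that("phantom panorama coverage matches the geometric model within
           2 percentage points", {
  pano <- std_recon()$panorama
  mask <- otsu_tissue_mask(pano$image)
  area <- area_from_mask(mask, pixel_size_um = std_mm_per_px * 1000)
  mesh_area <- mesh_surface_area(icosphere(20, subdivisions = 4))
  measured <- coverage_percent(area, mesh_area)
  predicted <- 100 * polygonal_coverage(0.2, 10)$coverage_fraction
  expect_lt(abs(measured - predicted), 2)
})
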