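test_that("an empty phantom contains no scoreable voxels", {
  ph <- patient_phantom(grid = c(2L, 128L, 128L), aortic_center = c(1, 64, 64))
  v <- build_phantom(ph)
  expect_true(all(v$voxels < 130))
  expect_equal(score_volume(v, 120)$total_score, 0)
  expect_equal(ground_truth_score(ph)$total_score, 0)
  expect_equal(as.character(ground_truth_score(ph)$risk_class), "0")
})

test_that("disc rasterization matches brute-force pixel enumeration", {
  sp <- 250 / 512
  # 4 mm^2 disc centered on a pixel: radius sqrt(4/pi) mm
  r_px <- sqrt(4 / pi) / sp
  k <- disc_pixel_count(c(256, 256), r_px)
  ph <- patient_phantom(list(lesion_spec(1, c(256, 256), 4.0, 320)),
                        aortic_center = c(1, 100, 100))
  gt <- ground_truth_score(ph)
  expect_equal(gt$lesions$n_pixels, k)
  expect_equal(gt$lesions$area_mm2, k * sp^2)
  # fractional centers change the achievable pixel count; oracle agrees
  for (ctr in list(c(200.3, 310.7), c(150.5, 150.5))) {
    ph2 <- patient_phantom(list(lesion_spec(1, ctr, 7.5, 500)),
                           aortic_center = c(1, 400, 400))
    r2 <- sqrt(7.5 / pi) / sp
    expect_equal(ground_truth_score(ph2)$lesions$n_pixels,
                 disc_pixel_count(ctr, r2))
  }
})

test_that("noiseless blood pool reads back exactly", {
  ph <- patient_phantom(grid = c(1L, 128L, 128L), aortic_center = c(1, 64, 64),
                        blood_pool_hu = 48.5)
  v <- build_phantom(ph)
  st <- suppressWarnings(roi_stats(v, ph$aortic_center))
  expect_equal(st$signal, round(48.5))  # integer HU volume
  expect_equal(st$noise, 0)
  expect_warning(roi_stats(v, ph$aortic_center), "SNR undefined")
})

test_that("invalid phantom geometries are rejected with identification", {
  expect_error(
    patient_phantom(list(lesion_spec(1, c(2, 2), 10, 300)),
                    grid = c(1L, 128L, 128L), aortic_center = c(1, 64, 64)),
    "lesion 1 extends outside")
  expect_error(
    patient_phantom(list(lesion_spec(1, c(20, 20), 4, 300),
                         lesion_spec(1, c(21, 21), 4, 300)),
                    grid = c(1L, 128L, 128L), aortic_center = c(1, 90, 90)),
    "lesions 1 and 2 overlap")
  expect_error(
    patient_phantom(list(lesion_spec(1, c(64, 64), 4, 300)),
                    grid = c(1L, 128L, 128L), aortic_center = c(1, 64, 64)),
    "blood pool")
  expect_error(patient_phantom(bmi = 70), "bmi")
  expect_error(lesion_spec(1, c(10, 10), -1, 300), "target_area")
})

test_that("volumes round-trip through NIfTI with spacing metadata", {
  ph <- patient_phantom(list(lesion_spec(1, c(30, 96), 4, 350)),
                        grid = c(2L, 128L, 128L), aortic_center = c(1, 90, 64))
  v <- build_phantom(ph)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(v2$pixel_spacing, v$pixel_spacing, tolerance = 1e-6)
  expect_equal(v2$slice_thickness, v$slice_thickness, tolerance = 1e-6)
  unlink(path)
  # single-slice volumes are 2D to NIfTI but keep their in-plane spacing
  ph1 <- patient_phantom(list(lesion_spec(1, c(30, 96), 4, 350)),
                         grid = c(1L, 128L, 128L), aortic_center = c(1, 90, 64))
  v1 <- build_phantom(ph1)
  p1 <- tempfile(fileext = ".nii.gz")
  write_volume(v1, p1)
  v1b <- read_volume(p1)
  expect_identical(dim(v1b$voxels), dim(v1$voxels))
  expect_equal(v1b$pixel_spacing, v1$pixel_spacing, tolerance = 1e-6)
  expect_equal(score_volume(v1b, 120)$total_score,
               score_volume(v1, 120)$total_score)
  unlink(p1)
})
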