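test_that("NIfTI and DICOM round trips preserve voxels and metadata", {
  v <- toy_volume()
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  write_ct_volume(v, nii)
  v2 <- read_ct_volume(nii)
  expect_equal(v2$voxels, v$voxels)
  expect_equal(v2$spacing, v$spacing)
  expect_equal(v2$fov_diameter_mm, v$fov_diameter_mm)

  dcm <- withr::local_tempdir()
  write_ct_volume(v, dcm, format = "dicom")
  v3 <- read_ct_volume(dcm)
  expect_identical(v3$voxels, v$voxels)
  expect_equal(v3$spacing, v$spacing)
  expect_equal(v3$fov_diameter_mm, v$fov_diameter_mm)

  # read -> write -> read is stable
  dcm2 <- withr::local_tempdir()
  write_ct_volume(v3, dcm2, format = "dicom")
  expect_identical(read_ct_volume(dcm2)$voxels, v$voxels)
})

test_that("DICOM rescale affine maps stored values to HU", {
  # a stored raw value of 100 with slope 1, intercept -1024 must read as
  # -924 HU; writing HU -924 with that intercept stores exactly raw 100
  v <- ct_volume(array(-924, c(4, 4, 1)), c(1, 1, 1), 4)
  d <- withr::local_tempdir()
  renalqct:::write_ct_dicom_series(v, d, intercept = -1024, slope = 1)
  el <- renalqct:::read_dicom_file(file.path(d, "slice0001.dcm"))
  stored <- readBin(el[["7FE0,0010"]]$bytes, "integer", n = 16, size = 2,
                    endian = "little")
  expect_true(all(stored == 100L))
  expect_true(all(read_ct_volume(d)$voxels == -924))
})

test_that("a directory mixing two series is rejected naming the slice", {
  v <- toy_volume(dims = c(8, 8, 2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  renalqct:::write_ct_dicom_series(v, d1, series_uid = "1.2.3.4")
  renalqct:::write_ct_dicom_series(v, d2, series_uid = "1.2.3.5")
  file.copy(file.path(d2, "slice0001.dcm"), file.path(d1, "intruder.dcm"))
  expect_error(read_ct_volume(d1), "mixes DICOM series.*intruder",
               ignore.case = TRUE)
})

test_that("missing rescale metadata is rejected", {
  v <- toy_volume(dims = c(8, 8, 1))
  d <- withr::local_tempdir()
  renalqct:::write_ct_dicom_series(v, d)
  # strip the rescale elements by rewriting the file without tags 0028,1052/3
  f <- file.path(d, "slice0001.dcm")
  raw <- readBin(f, "raw", n = file.info(f)$size)
  el <- renalqct:::read_dicom_file(f)
  keep <- setdiff(names(el), c("0028,1052", "0028,1053"))
  body <- unlist(lapply(keep, function(tag) {
    ge <- strtoi(strsplit(tag, ",")[[1]], 16L)
    renalqct:::dcm_element_bytes(ge[1], ge[2], el[[tag]]$vr, el[[tag]]$bytes)
  }))
  con <- file(f, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  close(con)
  expect_error(read_ct_volume(d), "rescale")
})

test_that("pydicom parses the DICOM files this package writes", {
  v <- toy_volume(dims = c(8, 8, 1))
  d <- withr::local_tempdir()
  write_ct_volume(v, d, format = "dicom")
  out <- suppressWarnings(system2(
    "python",
    c("-c", shQuote(sprintf(
      "import pydicom; ds = pydicom.dcmread('%s'); print(int(ds.pixel_array.sum()))",
      file.path(d, "slice0001.dcm")))),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0L)
  expect_equal(as.numeric(tail(out, 1)), sum(v$voxels + 1024))
})

test_that("polygon rasterization matches an exhaustive point-in-polygon scan", {
  set.seed(7)
  v <- toy_volume(dims = c(30, 30, 1), spacing = c(0.7, 0.7, 1), fov = 21)
  # random simple polygon: points on a jittered circle, ordered by angle
  ang <- sort(runif(7, 0, 2 * pi))
  rad <- runif(7, 3, 9)
  verts <- cbind(10 + rad * cos(ang), 10 + rad * sin(ang))
  roi <- ct_roi("poly", "axial", 0, vertices_mm = verts)
  mask <- renalqct:::rasterize_roi(roi, c(30, 30), c(0.7, 0.7))
  # oracle: pracma's independent point-in-polygon test on every voxel centre
  centres <- expand.grid(x = (0:29) * 0.7, y = (0:29) * 0.7)
  oracle <- pracma::inpolygon(centres$x, centres$y, verts[, 1], verts[, 2],
                              boundary = TRUE)
  # boundary handling may differ only for centres exactly on an edge; none
  # exist for this jittered geometry
  expect_equal(as.vector(mask), oracle)
  expect_gt(sum(mask), 0)
})

test_that("roi_mean_hu averages correctly and respects invariants", {
  u <- ct_volume(array(37, c(20, 20, 2)), c(1, 1, 1), 20)
  rs <- roi_set(square_roi("a"), square_roi("b", 4, 8), square_roi("c", 1, 6))
  res <- roi_mean_hu(u, rs)
  expect_equal(unname(res$per_roi), c(37, 37, 37))
  expect_equal(res$mean_of_means, 37)

  # kidney-level value is the unweighted mean of per-ROI means and is
  # bounded by them
  v <- toy_volume(dims = c(20, 20, 1), fov = 20)
  res2 <- roi_mean_hu(v, rs)
  expect_equal(res2$mean_of_means, mean(res2$per_roi))
  expect_gte(res2$mean_of_means, min(res2$per_roi))
  expect_lte(res2$mean_of_means, max(res2$per_roi))

  # invariance under vertex rotation preserving the polygon
  sq <- square_roi("a")
  rot <- ct_roi("a", "axial", 0, vertices_mm = sq$vertices_mm[c(3, 4, 1, 2), ])
  expect_equal(roi_mean_hu(v, roi_set(rot))$per_roi,
               roi_mean_hu(v, roi_set(sq))$per_roi)

  # an ROI enclosing no voxel centres errors with its label
  tiny <- ct_roi("empty", "axial", 0,
                 vertices_mm = cbind(c(0.1, 0.4, 0.4, 0.1) + 0.2,
                                     c(0.1, 0.1, 0.4, 0.4) + 0.2))
  expect_error(roi_mean_hu(v, roi_set(tiny)), "encloses no voxel")
})

test_that("ROI sets round-trip through the JSON schema", {
  rs <- roi_set(square_roi("cortex_1"), square_roi("cortex_2", 3, 9, plane = "coronal"))
  f <- withr::local_tempfile(fileext = ".json")
  write_roi_set(rs, f)
  rs2 <- read_roi_set(f)
  expect_equal(names(rs2), names(rs))
  expect_equal(rs2$cortex_1$vertices_mm, rs$cortex_1$vertices_mm + 0)
  expect_equal(rs2$cortex_2$plane, "coronal")
})

test_that("degenerate ROI and cohort inputs are rejected", {
  expect_error(ct_roi("bow", "axial", 0,
                      vertices_mm = cbind(c(0, 4, 0, 4), c(0, 4, 4, 0))),
               "self-intersect")
  expect_error(roi_set(square_roi("x"), square_roi("x")), "unique")
  tab <- data.frame(animal = "a", side = "top", group = "g",
                    measured_hu = 1, size_index = 1, corrected_hu = NA,
                    fibrosis_score = 1, blue_fraction = NA, bun = NA)
  expect_error(renalqct:::validate_cohort_table(tab), "side")
  tab$side <- "left"; tab$fibrosis_score <- 7
  expect_error(renalqct:::validate_cohort_table(tab), "0, 4")
})

test_that("cohort tables round-trip through CSV with the fixed header", {
  coh <- simulate_cohort(seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(coh, f)
  expect_identical(names(utils::read.csv(f)), renalqct:::.cohort_columns)
  back <- read_cohort_table(f)
  expect_equal(back$measured_hu, coh$measured_hu)
  expect_equal(back$animal, coh$animal)
})
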