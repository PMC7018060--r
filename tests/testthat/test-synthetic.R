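test_that("generators are reproducible under a fixed seed", {
  expect_identical(simulate_phantom_observations(seed = 7),
                   simulate_phantom_observations(seed = 7))
  expect_identical(simulate_cohort(seed = 7), simulate_cohort(seed = 7))
  expect_identical(render_trichrome(0.3, seed = 7),
                   render_trichrome(0.3, seed = 7))
  # and the session RNG stream is left untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_cohort(seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("noiseless phantom observations lie exactly on the configured lines", {
  obs <- simulate_phantom_observations(noise_sd = 0, B = c(60, 130, 230, 430),
                                       A = c(8, 9, 14, 20), seed = 2)
  truth <- attr(obs, "truth")
  for (r in unique(obs$region)) {
    i <- which(unique(obs$region) == r)
    sub <- obs[obs$region == r, ]
    expect_equal(sub$mean_hu, truth$B[i] - truth$A[i] * log(sub$tsi))
  }
})

test_that("phantom noise SD matches its configuration at large n", {
  obs <- simulate_phantom_observations(n_per_region = 5000, noise_sd = 1,
                                       regions = "P1", B = 60, A = 8,
                                       seed = 13)
  resid <- obs$mean_hu - (60 - 8 * log(obs$tsi))
  expect_equal(sd(resid), 1, tolerance = 0.03)
})

test_that("cohort generator honours its degenerate configurations", {
  # zero effect and zero bias: measured equals true exactly when noiseless
  coh <- simulate_cohort(effect_hu_per_score = 0, A = 0, noise_sd = 0,
                         animal_hu_sd = 0, seed = 3)
  expect_equal(coh$measured_hu, coh$true_hu)
  expect_true(all(coh$measured_hu == coh$measured_hu[1]))
  # score-free null: groups share one HU distribution
  expect_equal(length(unique(coh$group)), 3L)
})

test_that("configured prevalence is realized at scale", {
  coh <- simulate_cohort(n_per_group = c(total_body = 1000), prevalence = 0.66,
                         seed = 17)
  expect_equal(mean(binarize_fibrosis(coh$fibrosis_score)), 0.66,
               tolerance = 0.03)
})

test_that("cohort pipeline recovers the configured fibrosis effect", {
  coh <- simulate_cohort(n_per_group = c(total_body = 50, chest_only = 50),
                         seed = 23)
  truth <- attr(coh, "truth")
  rec <- correct_cohort(coh, truth$A)
  fit <- stats::lm(corrected_hu ~ fibrosis_score, rec)
  est <- coef(fit)[2]; se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(est - truth$effect_hu_per_score), 3 * se)
})

test_that("rendered slices expose consistent geometry, masks and TSI", {
  # all-air slice: TSI identically zero
  air <- render_ct_slice(matrix_size = 64)
  expect_equal(as.numeric(tsi_from_slice(air$slice, air$spacing, 320)), 0)
  # constant-HU organ reads back exactly through its mask
  sl <- render_ct_slice(matrix_size = 128,
                        body = list(axes = c(70, 60), hu = 0),
                        organs = list(list(label = "kidney",
                                           center = c(20, 5),
                                           axes = c(15, 10), hu = 37)))
  expect_true(all(sl$slice[sl$masks$kidney] == 37))
  vol <- ct_volume(array(sl$slice, c(128, 128, 1)), c(sl$spacing, sl$spacing, 1),
                   sl$fov_diameter_mm)
  roi <- ct_roi("kidney", "axial", 0, mask = sl$masks$kidney)
  expect_equal(roi_mean_hu(vol, roi_set(roi))$mean_of_means, 37)
  # geometry violations error out
  expect_error(render_ct_slice(body = list(axes = c(200, 200), hu = 0)),
               "outside")
  expect_error(render_ct_slice(matrix_size = 64,
                               body = list(axes = c(60, 60), hu = 0),
                               organs = list(list(label = "x",
                                                  center = c(55, 0),
                                                  axes = c(10, 10), hu = 40))),
               "outside")
})

test_that("raster TSI agrees with the analytic area-weighted value", {
  # body disk radius 80 mm at 0 HU in a 320 mm FOV
  sl <- render_ct_slice(matrix_size = 256, body = list(axes = c(80, 80), hu = 0))
  t_raster <- as.numeric(tsi_from_slice(sl$slice, sl$spacing, 320))
  frac <- (80 / 160)^2
  mean_hu <- frac * 0 + (1 - frac) * (-1024)
  t_analytic <- (mean_hu + 1024) * pi * 160^2 / 1e7
  expect_equal(t_raster, t_analytic, tolerance = 0.01)
  # the agreement holds across random geometries
  set.seed(77)
  for (i in 1:15) {
    ax <- runif(2, 40, 120); hu <- runif(1, -100, 100)
    sl <- render_ct_slice(matrix_size = 256, body = list(axes = ax, hu = hu))
    frac <- prod(ax) / 160^2   # ellipse area over FOV disc area
    t_an <- ((frac * hu + (1 - frac) * (-1024)) + 1024) * pi * 160^2 / 1e7
    t_ra <- as.numeric(tsi_from_slice(sl$slice, sl$spacing, 320))
    expect_equal(t_ra, t_an, tolerance = 0.02)
  }
})

test_that("trichrome renderer hits its target fraction and class purity", {
  img <- render_trichrome(0, width = 60, height = 60, seed = 1)
  expect_equal(as.numeric(blue_area_fraction(img)), 0)
  img3 <- render_trichrome(0.3, width = 120, height = 120, seed = 2)
  expect_equal(attr(img3, "realized_fraction"), 0.3, tolerance = 0.005)
  expect_equal(as.numeric(blue_area_fraction(img3)), 0.3, tolerance = 0.01)
  expect_error(render_trichrome(1.4), "\\[0, 1\\]")
})
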