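# Synthetic phantom generator: analytic volumes, determinism, cohorts.

test_that("phantom_spec validation names the offending field", {
  expect_error(phantom_spec(semi_axes = c(-1, 10, 10)), "semi_axes")
  expect_error(phantom_spec(deform_amplitude = 0.5), "deform_amplitude")
  expect_error(phantom_spec(noise_sd = -0.1), "noise_sd")
  expect_error(phantom_spec(views_present = c("sagittal")), "axial")
  expect_error(phantom_spec(views_present = c("axial", "oblique")),
               "views_present")
})

test_that("sphere phantom reproduces the closed-form volume", {
  sp <- phantom_spec(semi_axes = c(20, 20, 20), deform_amplitude = 0,
                     noise_sd = 0, bias_amplitude = 0)
  pt <- generate_phantom(sp)
  expect_equal(pt$truth$true_volume, 4 / 3 * pi * 20^3 / 1000,
               tolerance = 1e-12)
  expect_equal(pt$truth$ellipsoid_diameters, c(40, 40, 40))
  # gland voxels brighter than background on the axial view
  ax <- pt$exam$views$axial
  expect_gt(mean(ax$data[pt$exam$mask$data == 1]),
            mean(ax$data[pt$exam$mask$data == 0]))
})

test_that("voxelized volume matches the analytic ellipsoid volume within 1%", {
  sp <- phantom_spec(semi_axes = c(25, 20, 30), deform_amplitude = 0,
                     noise_sd = 0)
  pt <- generate_phantom(sp)
  v_ref <- ellipsoid_true_volume(25, 20, 30)
  expect_equal(v_ref, 62.8319, tolerance = 1e-5)
  expect_lt(abs(mask_volume(pt$truth$mask3d) - v_ref) / v_ref, 0.01)
})

test_that("discretization error decreases with grid refinement", {
  errs <- vapply(c(1.0, 0.5), function(h) {
    sp <- phantom_spec(semi_axes = c(18, 14, 21), deform_amplitude = 0,
                       noise_sd = 0, fine_spacing = h, extent_mm = 50)
    pt <- generate_phantom(sp)
    abs(mask_volume(pt$truth$mask3d) - pt$truth$true_volume)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("views subset semantics and mask presence", {
  sp <- phantom_spec(views_present = "axial", extent_mm = 48,
                     semi_axes = c(15, 12, 16))
  pt <- generate_phantom(sp)
  expect_named(pt$exam$views, "axial")
  expect_s3_class(pt$exam$mask, "seg_mask")
  expect_length(pt$exam$view_masks, 0)
})

test_that("identical seed and spec give a bit-identical phantom", {
  sp <- phantom_spec(seed = 31, extent_mm = 48, semi_axes = c(15, 12, 16))
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$exam$views$axial$data, p2$exam$views$axial$data)
  expect_identical(p1$truth$mask3d$data, p2$truth$mask3d$data)
  expect_identical(p1$truth$true_volume, p2$truth$true_volume)
})

test_that("ellipsoid_true_volume closed forms and symmetry", {
  expect_equal(ellipsoid_true_volume(10, 10, 10), 4.18879, tolerance = 1e-5)
  expect_equal(ellipsoid_true_volume(25, 20, 30), 62.8319, tolerance = 1e-4)
  expect_equal(ellipsoid_true_volume(12, 17, 23),
               ellipsoid_true_volume(17, 12, 23))
  expect_error(ellipsoid_true_volume(-1, 10, 10), "positive")
})

test_that("per-view renderings agree after resampling back to the fine grid", {
  sp <- phantom_spec(extent_mm = 63, seed = 3)
  pt <- generate_phantom(sp)
  fine_sp <- pt$truth$mask3d$spacing
  back <- lapply(c("axial", "sagittal", "coronal"), function(vw) {
    m <- if (vw == "axial") pt$exam$mask else pt$exam$view_masks[[vw]]
    reslice_view(resample_to_reference(m, fine_sp), "axial")
  })
  for (i in 1:2) {
    for (j in (i + 1):3) expect_gte(dsc(back[[i]], back[[j]]), 0.95)
  }
})

test_that("cohort scenarios control the available views", {
  ax <- tiny_cohort(5, seed = 10, scenario = "axial_only")
  for (ct in ax) expect_named(ct$exam$views, "axial")
  mx <- tiny_cohort(6, seed = 10, scenario = "mixed")
  for (ct in mx) expect_true("axial" %in% names(ct$exam$views))
  n_views <- vapply(mx, function(ct) length(ct$exam$views), integer(1))
  expect_true(any(n_views < 3))  # some exams drop an orthogonal view
})

test_that("cohorts are reproducible from the seed", {
  c1 <- tiny_cohort(4, seed = 77)
  c2 <- tiny_cohort(4, seed = 77)
  expect_identical(lapply(c1, function(ct) ct$exam$views$axial$data),
                   lapply(c2, function(ct) ct$exam$views$axial$data))
  expect_identical(vapply(c1, function(ct) ct$truth$true_volume, numeric(1)),
                   vapply(c2, function(ct) ct$truth$true_volume, numeric(1)))
  expect_error(make_cohort(3, variability = list(semi_axes = c(20, 10))),
               "variability")
})

test_that("cohort mean volume matches the analytic mean of the distribution", {
  # semi-axes iid uniform [15, 35]: E[V] = 4/3 pi E[a]E[b]E[c] / 1000 and
  # Var[V] = (4 pi / 3000)^2 (E[a^2]^3 - E[a]^6) for independent axes
  co <- make_cohort(100,
                    base_spec = phantom_spec(view_spacings = list(
                      axial = c(1.5, 4.5), sagittal = c(1.5, 4.5),
                      coronal = c(1.5, 4.5)), fine_spacing = 1.5),
                    variability = list(semi_axes = c(15, 35),
                                       deform_amplitude = c(0, 0),
                                       noise_sd = c(0, 0),
                                       bias_amplitude = c(0, 0),
                                       center_offset = c(0, 0)),
                    scenario = "axial_only", seed = 5)
  vols <- vapply(co, function(ct) ct$truth$true_volume, numeric(1))
  m1 <- 25            # E[a], uniform [15, 35]
  m2 <- (35^3 - 15^3) / (3 * 20)  # E[a^2]
  k <- 4 * pi / 3 / 1000
  mu <- k * m1^3
  sdv <- k * sqrt(m2^3 - m1^6)
  expect_lt(abs(mean(vols) - mu), 3 * sdv / sqrt(length(vols)))
})

test_that("cohorts write NIfTI volumes and a manifest", {
  co <- tiny_cohort(2, seed = 9)
  dir <- tempfile()
  manifest <- write_cohort(co, dir)
  df <- read.csv(file.path(dir, "cohort_manifest.csv"))
  expect_equal(nrow(df), 2)
  expect_true(all(c("id", "true_volume_ml", "W_mm") %in% names(df)))
  f <- file.path(dir, "exam_001_axial.nii.gz")
  expect_true(file.exists(f))
  v <- read_volume(f)
  expect_equal(v$data, co[[1]]$exam$views$axial$data, tolerance = 1e-6)
})
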