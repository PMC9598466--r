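test_that("template construction is deterministic and self-consistent", {
  tpl <- shared_template()
  tpl2 <- make_template()
  expect_identical(tpl$volume$data, tpl2$volume$data)
  expect_identical(tpl$tpm$face$data, tpl2$tpm$face$data)

  total <- Reduce(`+`, lapply(tpl$tpm, function(v) v$data))
  expect_lt(max(abs(total - 1)), 1e-6)

  # face class carries no probability on the nose
  expect_equal(max(tpl$tpm$face$data[tpl$masks$nose]), 0)

  # canonical inner skull strictly inside the brain+skull boundary
  inside_mask <- tpl$masks$brain | tpl$masks$skull
  vol <- ng_volume(array(as.numeric(inside_mask), dim(inside_mask)),
                   tpl$volume$affine)
  at_verts <- sample_volume(vol, tpl$canonical_inner_skull$vertices,
                            method = "nearest")
  expect_true(all(at_verts == 1))
  expect_identical(nrow(tpl$canonical_inner_skull$vertices), 2562L)

  expect_error(make_template(c(32, 32, 32)), "grid too small")
  expect_error(make_template(voxel_size_mm = -1), "positive")
  # big enough voxel count but too small a field of view
  expect_error(make_template(c(48, 48, 48), voxel_size_mm = 2),
               "too small to contain")
})

test_that("fiducials sit on the head surface", {
  tpl <- shared_template()
  d <- point_to_surface_distance(tpl$fiducials, tpl$scalp)$distance
  expect_lt(max(d), mean(voxel_size(tpl$volume)))
})

test_that("phantom subjects carry a valid invertible ground-truth field", {
  ph <- shared_phantom(seed = 42)
  ph2 <- make_head_phantom(shared_template(), 5, seed = 42)
  expect_identical(ph$volume$data, ph2$volume$data)      # determinism
  expect_identical(ph$fiducials_mri, ph2$fiducials_mri)

  vox <- mean(voxel_size(ph$volume))
  expect_lt(inverse_consistency_mm(ph$true_deformation), 0.1 * vox)
  expect_gt(min(jacobian_determinant(ph$true_deformation)), 0)

  expect_equal(sum(ph$masks$brain & ph$masks$face), 0L)
  expect_equal(sum(ph$masks$nose & ph$masks$face), 0L)
  expect_true(all(ph$masks$nose <= ph$masks$head))

  # zero deformation, zero noise: the subject is the template
  ph0 <- make_head_phantom(shared_template(), 0, intensity_noise_sd = 0,
                           seed = 1)
  expect_lt(max(abs(ph0$volume$data - shared_template()$volume$data)), 1e-9)
  expect_error(make_head_phantom(shared_template(), 80, seed = 1),
               "invertible")
})

test_that("digitized point sampling respects noise, labels and transforms", {
  ph <- shared_phantom(seed = 42)
  pts0 <- sample_head_points(ph, noise_sd_mm = 0, fiducial_noise_sd_mm = 0,
                             seed = 4)
  expect_identical(length(pts0), 118L)
  expect_identical(sum(pts0$labels == "scalp"), 100L)  # ~100 scalp points
  d <- point_to_surface_distance(
    subset_points(pts0, pts0$labels %in% c("scalp", "nose")),
    ph$true_scalp)$distance
  expect_lt(max(d), 1e-9)  # noiseless points lie exactly on the surface

  # device transform round trip: inverse map returns points to the surface
  dev <- random_rigid(25, 40, seed = 6, from = "mri_world", to = "device")
  pts <- sample_head_points(ph, noise_sd_mm = 1, fiducial_noise_sd_mm = 0,
                            device_transform = dev, seed = 4)
  back <- apply_transform(invert_transform(dev), pts)
  db <- point_to_surface_distance(
    subset_points(back, back$labels %in% c("scalp", "nose")),
    ph$true_scalp)$distance
  expect_lt(max(db), 5)  # within a few noise sd
  expect_gt(max(db), 1e-4)  # noise actually applied

  expect_error(sample_head_points(ph, n_scalp = 1, n_nose = 0, seed = 1),
               "at least 3")
  # a phantom with no nose surface cannot provide nose points
  ph_non <- ph
  ph_non$scalp_nose_vertex <- rep(FALSE, length(ph$scalp_nose_vertex))
  expect_error(sample_head_points(ph_non, n_nose = 5, seed = 1), "no nose")
})

test_that("stored arrays are reproducible across runs at strict tolerance", {
  tpl <- shared_template()
  a <- make_head_phantom(tpl, 3, seed = 9)
  b <- make_head_phantom(tpl, 3, seed = 9)
  expect_equal(a$true_deformation$disp, b$true_deformation$disp,
               tolerance = 1e-12)
  expect_equal(a$true_scalp$vertices, b$true_scalp$vertices,
               tolerance = 1e-12)
})
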