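test_that("point-to-surface distance is exact for the canonical cases", {
  tri <- ng_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                 matrix(c(1, 2, 3), 1, 3))
  # on a vertex
  expect_equal(point_to_surface_distance(c(10, 0, 0), tri)$distance, 0)
  # perpendicular above the interior
  r <- point_to_surface_distance(c(2, 2, 5), tri)
  expect_equal(r$distance, 5, tolerance = 1e-12)
  expect_equal(r$closest[1, ], c(2, 2, 0), tolerance = 1e-12)
  # beyond an edge: distance to the edge segment
  expect_equal(point_to_surface_distance(c(-3, 5, 4), tri)$distance, 5,
               tolerance = 1e-12)

  # unit icosphere queried from (2,0,0): analytic distance 1 within the
  # chordal discretization of the level-4 sphere
  ic <- make_icosphere(4)
  d <- point_to_surface_distance(c(2, 0, 0), ic)$distance
  expect_equal(d, 1, tolerance = 2e-3)
  expect_error(point_to_surface_distance(c(0, 0, 0),
                                         ng_mesh(matrix(0, 0, 3),
                                                 matrix(0L, 0, 3))),
               "empty mesh")
})

test_that("ICP refits points sampled from the surface to near-zero RMS", {
  ph <- shared_phantom(seed = 42)
  pts <- sample_head_points(ph, noise_sd_mm = 0, fiducial_noise_sd_mm = 0,
                            seed = 8)
  hp <- subset_points(pts, pts$labels %in% c("scalp", "nose"))
  co <- icp_register(hp, ph$true_scalp, n_init = 1)
  expect_lt(co$rms, 1e-4)
  expect_lt(max(abs(co$transform$matrix - diag(4))), 1e-3)
  # the RMS objective never increases across iterations
  expect_true(all(diff(co$rms_trace) <= 1e-9))
})

test_that("ICP recovers a seeded rigid perturbation within the capture range", {
  ph <- shared_phantom(seed = 42)
  pts <- sample_head_points(ph, noise_sd_mm = 0, fiducial_noise_sd_mm = 0,
                            seed = 8)
  hp <- subset_points(pts, pts$labels %in% c("scalp", "nose"))
  T_true <- random_rigid(10, 8, seed = 21)
  moved <- apply_transform(invert_transform(T_true), hp$points)
  co <- icp_register(moved, ph$true_scalp, n_init = 10, seed = 3)
  d <- transform_discrepancy(co$transform, T_true)
  expect_lt(d$rotation_deg, 0.5)
  expect_lt(d$translation_mm, 1)

  # best of 10 starts can never beat fewer starts from the same init
  co1 <- icp_register(moved, ph$true_scalp, n_init = 1)
  expect_lte(co$rms, co1$rms + 1e-12)
  expect_lte(min(co$all_rms), co$rms + 1e-12)
  expect_equal(co$rms, sqrt(mean(co$per_point_residuals^2)),
               tolerance = 1e-9)
  expect_error(icp_register(matrix(c(NA, 0, 0), 1, 3), ph$true_scalp),
               "3 points")
})

test_that("two-step coregistration reduces to the fiducial fit without head points", {
  ph <- shared_phantom(seed = 42)
  dev <- random_rigid(15, 25, seed = 2, from = "mri_world", to = "device")
  fid_dev <- apply_transform(dev, ph$fiducials_mri)
  rownames(fid_dev) <- rownames(ph$fiducials_mri)
  only_fids <- head_points(fid_dev, c("nasion", "lpa", "rpa"), "device")
  co <- coregister_two_step(only_fids, ph$fiducials_mri, ph$true_scalp)
  direct <- fit_rigid_landmarks(fid_dev, ph$fiducials_mri)
  expect_equal(co$transform$matrix, direct$matrix, tolerance = 1e-9)
  expect_identical(co$n_points_used, 0L)

  bad <- head_points(fid_dev[1:2, ], c("nasion", "lpa"), "device")
  expect_error(coregister_two_step(bad, ph$fiducials_mri, ph$true_scalp),
               "missing fiducial")
})

test_that("noiseless two-step coregistration recovers the device pose", {
  ph <- shared_phantom(seed = 42)
  dev <- random_rigid(20, 30, seed = 5, from = "mri_world", to = "device")
  pts <- sample_head_points(ph, noise_sd_mm = 0, fiducial_noise_sd_mm = 0,
                            device_transform = dev, seed = 12)
  co <- coregister_two_step(pts, ph$fiducials_mri, ph$true_scalp, seed = 1)
  d <- transform_discrepancy(co$transform, invert_transform(dev))
  expect_lt(d$translation_mm, 0.5)
  expect_lt(d$rotation_deg, 0.5)
})

test_that("head points compensate perturbed fiducials (step 2 beats step 1)", {
  ph <- shared_phantom(seed = 42)
  dev <- random_rigid(20, 30, seed = 5, from = "mri_world", to = "device")
  with_seed(31, {
    pts <- sample_head_points(ph, noise_sd_mm = 0,
                              fiducial_noise_sd_mm = 5,
                              device_transform = dev, seed = 13)
  })
  co <- coregister_two_step(pts, ph$fiducials_mri, ph$true_scalp, seed = 2)
  T_true <- invert_transform(dev)
  # evaluate both steps as mean mapping error over the head points
  hp <- subset_points(pts, pts$labels %in% c("scalp", "nose"))
  map_err <- function(T) mean(sqrt(rowSums(
    (apply_transform(T, hp$points) - apply_transform(T_true, hp$points))^2)))
  expect_lt(map_err(co$transform), map_err(co$fiducial_transform))
})
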