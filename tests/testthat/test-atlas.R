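test_that("affine registration is exact for identical and re-gridded volumes", {
  tpl <- shared_template()
  A <- affine_register(tpl$volume, tpl$volume)
  expect_lt(max(abs(A - diag(4))), 1e-3)

  # same world-space content on a different grid: identity world affine
  sub <- noseguard:::downsample_volume(tpl$volume, 2L)
  A2 <- affine_register(tpl$volume, sub)
  expect_lt(max(abs(A2 - diag(4))), 0.05)

  flat <- ng_volume(array(1, dim(tpl$volume$data)), tpl$volume$affine)
  expect_error(affine_register(flat, tpl$volume), "all-constant")
})

test_that("affine registration recovers a seeded affine warp", {
  tpl <- shared_template()
  M <- with_seed(19, {
    ang <- runif(3, -8, 8) * pi / 180
    sc <- runif(3, 0.96, 1.04)
    Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]),
                   0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0, sin(ang[2]), 0,
                   cos(ang[2])), 3, 3)
    A <- diag(4)
    A[1:3, 1:3] <- Rz %*% Ry %*% diag(sc)
    A[1:3, 4] <- runif(3, -8, 8)
    A
  })
  # subject = template pushed through M (sampled via the inverse)
  gw <- noseguard:::grid_world(tpl$volume)
  Minv <- solve(M)
  back <- gw %*% t(Minv[1:3, 1:3]) +
    matrix(Minv[1:3, 4], nrow(gw), 3, byrow = TRUE)
  sub <- ng_volume(array(sample_volume(tpl$volume, back),
                         dim(tpl$volume$data)), tpl$volume$affine)
  A_est <- affine_register(sub, tpl$volume)
  # mean landmark error over the head after applying the estimate
  hm <- as.vector(shared_template()$masks$head)
  est <- gw %*% t(A_est[1:3, 1:3]) +
    matrix(A_est[1:3, 4], nrow(gw), 3, byrow = TRUE)
  tru <- gw %*% t(M[1:3, 1:3]) + matrix(M[1:3, 4], nrow(gw), 3, byrow = TRUE)
  expect_lt(mean(sqrt(rowSums((est - tru)^2))[hm]),
            mean(voxel_size(tpl$volume)))
})

test_that("nonlinear registration is a regularized null on identical images", {
  tpl <- shared_template()
  f <- nonlinear_register(tpl$volume, tpl$volume)
  mag <- sqrt(f$disp[, , , 1]^2 + f$disp[, , , 2]^2 + f$disp[, , , 3]^2)
  expect_lt(mean(mag), 0.2 * mean(voxel_size(tpl$volume)))
  expect_gt(min(jacobian_determinant(f)), 0)
})

test_that("nonlinear registration energy decreases within every pyramid level", {
  ph <- shared_phantom(seed = 42)
  tpl <- shared_template()
  f <- nonlinear_register(ph$volume, tpl$volume,
                          affine_register(ph$volume, tpl$volume))
  for (lev in attr(f, "diagnostics")) {
    expect_gt(length(lev$mse), 1)
    expect_lt(lev$mse[length(lev$mse)], lev$mse[1])
  }
  expect_gt(min(jacobian_determinant(f)), 0)

  # inverse consistency of the estimated field: template -> subject ->
  # template intensities within 5% normalized RMS on the head
  gw <- noseguard:::grid_world(tpl$volume)
  hm <- as.vector(tpl$masks$head)
  round_trip <- apply_deformation(f, apply_deformation(f, gw),
                                  inverse = TRUE)
  tv <- as.vector(tpl$volume$data)
  resampled <- sample_volume(tpl$volume, round_trip)
  nrmse <- sqrt(mean((resampled - tv)[hm]^2)) / sd(tv[hm])
  expect_lt(nrmse, 0.05)
})

test_that("tissue labeling returns normalized classes in subject space", {
  ph <- shared_phantom(seed = 42)
  tpl <- shared_template()
  tp <- label_tissues(ph$volume, tpl, ph$true_deformation)
  total <- Reduce(`+`, lapply(tp, function(v) v$data))
  expect_lt(max(abs(total - 1)), 1e-6)

  # deep-brain voxels (brain eroded by 2 voxels) carry no face probability
  not_brain <- !ph$masks$brain
  dim(not_brain) <- dim(ph$masks$brain)
  core <- ph$masks$brain & !noseguard:::cpp_dilate(not_brain, 2)
  expect_gt(sum(core), 100)
  expect_lt(max(tp$face$data[core]), 0.1)

  # grid mismatch between field and TPM is rejected
  small <- noseguard:::downsample_volume(ph$volume, 2L)
  bad_field <- deformation_field(array(0, c(dim(small$data), 3)),
                                 small$affine)
  expect_error(label_tissues(ph$volume, tpl, bad_field), "grid")
})
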