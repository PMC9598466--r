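test_that("rigid transforms validate, invert and compose", {
  expect_error(rigid_transform(matrix(2 * diag(4), 4, 4)), "orthonormal")
  m <- diag(4)
  m[1:3, 1:3] <- diag(c(1, 1, -1))   # reflection
  expect_error(rigid_transform(m), "proper")

  T1 <- random_rigid(40, 50, seed = 1)
  T2 <- random_rigid(40, 50, seed = 2)
  p <- matrix(rnorm(30, sd = 40), 10, 3)
  expect_equal(apply_transform(compose_transforms(T2, T1), p),
               apply_transform(T2, apply_transform(T1, p)),
               tolerance = 1e-12)
  expect_equal(apply_transform(T1, apply_transform(invert_transform(T1), p)),
               p, tolerance = 1e-9)
  Tinv <- invert_transform(T1)
  expect_lt(max(abs(Tinv$matrix %*% T1$matrix - diag(4))), 1e-9)
})

test_that("head point sets enforce labels and frames", {
  p <- rbind(c(0, 100, 0), c(-70, 0, 0), c(70, 0, 0), c(0, 0, 90))
  pts <- head_points(p, c("nasion", "lpa", "rpa", "scalp"), "device")
  expect_s3_class(pts, "ng_points")
  expect_error(head_points(p, c("nasion", "nasion", "rpa", "scalp"), "device"),
               "present 2 times")
  expect_error(head_points(p, c("a", "b", "c", "d"), "device"), "unknown")
  T <- rigid_transform(diag(4), from = "head", to = "mri_world")
  expect_error(apply_transform(T, pts), "frame mismatch")
  T2 <- rigid_transform(diag(4), from = "device", to = "head")
  expect_identical(apply_transform(T2, pts)$frame, "head")
})

test_that("head frame is Neuromag-style with origin on the LPA-RPA line", {
  T <- build_head_frame(c(0, 100, 0), c(-75, 0, 0), c(75, 0, 0))
  expect_lt(max(abs(T$matrix - diag(4))), 1e-12)

  # a rotated/translated copy maps back to canonical coordinates
  M <- random_rigid(60, 80, seed = 7)
  fid <- apply_transform(M, rbind(c(0, 100, 0), c(-75, 0, 0), c(75, 0, 0)))
  T2 <- build_head_frame(fid[1, ], fid[2, ], fid[3, ])
  back <- apply_transform(T2, fid)
  expect_lt(max(abs(back - rbind(c(0, 100, 0), c(-75, 0, 0), c(75, 0, 0)))),
            1e-9)

  # axis conventions, asserted exactly on a generic configuration
  nas <- c(13, 87, 22); lpa <- c(-64, -12, 3); rpa <- c(71, 5, -9)
  Th <- build_head_frame(nas, lpa, rpa)
  h <- apply_transform(Th, rbind(nas, lpa, rpa))
  expect_equal(h[1, c(1, 3)], c(0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)  # nasion on +y axis
  expect_gt(h[1, 2], 0)
  expect_equal(h[2:3, 2], c(0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)      # LPA/RPA in y = 0
  expect_equal(h[2:3, 3], c(0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)      # ... and z = 0
  expect_lt(h[2, 1], 0)
  expect_gt(h[3, 1], 0)

  expect_error(build_head_frame(c(0, 1, 0), c(1, 0, 0), c(1, 0, 0)),
               "degenerate")
  expect_error(build_head_frame(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0)),
               "degenerate")
})

test_that("landmark fitting recovers seeded rigid motions and never reflects", {
  src <- matrix(rnorm(24, sd = 50), 8, 3)
  expect_lt(max(abs(fit_rigid_landmarks(src, src)$matrix - diag(4))), 1e-9)

  T <- random_rigid(90, 100, seed = 3)
  dst <- apply_transform(T, src)
  Tf <- fit_rigid_landmarks(src, dst)
  expect_lt(max(abs(Tf$matrix - T$matrix)), 1e-9)

  # mirrored target: properness enforced, residual nonzero
  Tm <- fit_rigid_landmarks(src, src %*% diag(c(-1, 1, 1)))
  expect_equal(det(Tm$matrix[1:3, 1:3]), 1, tolerance = 1e-9)
  expect_gt(mean(rowSums((apply_transform(Tm, src) -
                            src %*% diag(c(-1, 1, 1)))^2)), 1)

  expect_error(fit_rigid_landmarks(src[1:2, ], src[1:2, ]), "at least 3")
  degen <- cbind(1:5, 0, 0)  # collinear
  expect_error(fit_rigid_landmarks(degen, degen), "rank-deficient")
})

test_that("landmark fitting is order-invariant and rigid-equivariant", {
  set.seed(11)
  src <- matrix(rnorm(30, sd = 30), 10, 3)
  dst <- apply_transform(random_rigid(30, 20, seed = 5), src) +
    matrix(rnorm(30, sd = 1), 10, 3)
  Tf <- fit_rigid_landmarks(src, dst)
  ord <- sample(10)
  expect_equal(fit_rigid_landmarks(src[ord, ], dst[ord, ])$matrix, Tf$matrix,
               tolerance = 1e-9)
  # pre-moving both sets by G conjugates the fit: T' = G T G^-1
  G <- random_rigid(45, 60, seed = 9)
  Tg <- fit_rigid_landmarks(apply_transform(G, src), apply_transform(G, dst))
  expect_equal(Tg$matrix,
               G$matrix %*% Tf$matrix %*% solve(G$matrix),
               tolerance = 1e-8)
})
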