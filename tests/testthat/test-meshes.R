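test_that("icosphere subdivision gives the canonical vertex counts", {
  ic0 <- make_icosphere(0)
  expect_identical(nrow(ic0$vertices), 12L)
  expect_identical(nrow(ic0$faces), 20L)
  for (L in 0:5) {
    ic <- make_icosphere(L)
    expect_identical(nrow(ic$vertices), as.integer(10 * 4^L + 2))
    expect_identical(euler_characteristic(ic), 2L)
    expect_equal(sqrt(rowSums(ic$vertices^2)), rep(1, nrow(ic$vertices)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(make_icosphere(-1), "non-negative")
})

test_that("scalp extraction reproduces an analytic ellipsoid within a voxel", {
  dims <- c(40, 40, 40)
  aff <- diag(c(4, 4, 4, 1)); aff[1:3, 4] <- -(dims - 1) / 2 * 4
  ref <- ng_volume(array(0, dims), aff)
  gw <- noseguard:::grid_world(ref)
  radii <- c(55, 65, 60)
  F <- sqrt((gw[, 1] / radii[1])^2 + (gw[, 2] / radii[2])^2 +
              (gw[, 3] / radii[3])^2)
  vol <- ng_volume(array(as.numeric(F <= 1) * 0.8, dims), aff)
  # an isolated noise blob away from the head
  vol$data[3, 3, 3] <- 0.9
  mesh <- extract_scalp(vol, 0.4)
  expect_identical(euler_characteristic(mesh), 2L)
  # radial deviation from the analytic surface
  vF <- sqrt((mesh$vertices[, 1] / radii[1])^2 +
               (mesh$vertices[, 2] / radii[2])^2 +
               (mesh$vertices[, 3] / radii[3])^2)
  rad <- sqrt(rowSums(mesh$vertices^2))
  expect_lt(max(abs(rad * (1 - 1 / vF))), 4)  # < 1 voxel
  # the noise blob is not part of the largest component
  expect_gt(min(sqrt(rowSums(mesh$vertices^2))), 30)
  expect_error(extract_scalp(ng_volume(array(0, dims), aff), 0.5), "empty")
})

test_that("canonical inner-skull warping preserves topology and truth", {
  ph <- shared_phantom(seed = 42)
  canon <- shared_template()$canonical_inner_skull
  warped <- warp_canonical_innerskull(canon, ph$true_deformation)
  expect_identical(dim(warped$vertices), dim(canon$vertices))
  expect_identical(warped$faces, canon$faces)
  cmp <- compare_surfaces(ph$true_inner_skull, warped)
  expect_lt(cmp$mean_mm, 1)

  # identity field leaves the mesh unchanged
  zero <- deformation_field(array(0, c(dim(ph$volume$data), 3)),
                            ph$volume$affine)
  same <- warp_canonical_innerskull(canon, zero)
  expect_equal(same$vertices, canon$vertices, tolerance = 1e-12)

  far <- ng_mesh(matrix(c(500, 500, 500), 1, 3), matrix(c(1, 1, 1), 1, 3))
  expect_error(warp_canonical_innerskull(far, ph$true_deformation),
               "outside")
})

test_that("surface comparison handles pose, symmetry and alignment", {
  mesh <- make_icosphere(2)
  mesh$vertices <- mesh$vertices * 60
  expect_equal(compare_surfaces(mesh, mesh)$mean_mm, 0)

  shifted <- mesh
  shifted$vertices <- sweep(mesh$vertices, 2, c(3, 0, 0), `+`)
  expect_equal(compare_surfaces(mesh, shifted, align = FALSE)$mean_mm, 3,
               tolerance = 1e-9)
  expect_lt(compare_surfaces(mesh, shifted, align = TRUE)$mean_mm, 1e-6)

  # unaligned comparison is symmetric; alignment never hurts
  set.seed(2)
  bumpy <- mesh
  bumpy$vertices <- mesh$vertices + matrix(rnorm(length(mesh$vertices)),
                                           ncol = 3)
  expect_equal(compare_surfaces(mesh, bumpy)$mean_mm,
               compare_surfaces(bumpy, mesh)$mean_mm)
  expect_lte(compare_surfaces(mesh, bumpy, align = TRUE)$mean_mm,
             compare_surfaces(mesh, bumpy, align = FALSE)$mean_mm + 1e-9)

  other <- make_icosphere(1)
  expect_error(compare_surfaces(mesh, other), "topology")
})

test_that("meshes round-trip through OBJ and STL text formats", {
  mesh <- make_icosphere(1)
  mesh$vertices <- mesh$vertices * 37.5
  for (ext in c("obj", "stl")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_mesh(mesh, f)
    back <- read_mesh(f)
    expect_identical(nrow(back$vertices), nrow(mesh$vertices))
    expect_identical(nrow(back$faces), nrow(mesh$faces))
    expect_identical(euler_characteristic(back), 2L)
    # same surface up to vertex reordering: compare sorted coordinates
    expect_equal(back$vertices[order(back$vertices[, 1], back$vertices[, 2],
                                     back$vertices[, 3]), ],
                 mesh$vertices[order(mesh$vertices[, 1], mesh$vertices[, 2],
                                     mesh$vertices[, 3]), ],
                 tolerance = 1e-6, ignore_attr = TRUE)
    unlink(f)
  }
})
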