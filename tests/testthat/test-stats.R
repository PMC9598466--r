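test_that("fiducial registration error is the mean of the three distances", {
  fids <- rbind(nasion = c(0, 90, 10), lpa = c(-70, 0, 0),
                rpa = c(70, 0, 0))
  idT <- rigid_transform(diag(4))
  expect_equal(fiducial_registration_error(idT, fids, fids), 0)

  off <- fids
  off["nasion", ] <- off["nasion", ] + c(0, 3, 0)  # one fiducial 3 mm off
  expect_equal(fiducial_registration_error(idT, off, fids), 1)

  # agrees with independent recomputation under a random transform
  T <- random_rigid(30, 40, seed = 14)
  meg <- fids + matrix(rnorm(9, sd = 4), 3, 3)
  ref <- mean(sqrt(rowSums((apply_transform(T, meg) - fids)^2)))
  expect_equal(fiducial_registration_error(T, meg, fids), ref,
               tolerance = 1e-12)
  expect_error(fiducial_registration_error(idT, fids[1:2, ], fids), "three")
})

test_that("nose-point exclusion applies the strict anterior-inferior rule", {
  p <- rbind(c(0, 20, -10),   # y > 0, z < 0: excluded
             c(0, 20, 10),    # z not negative: kept
             c(0, 0, -10),    # y not positive (boundary): kept
             c(5, -15, -30),  # posterior: kept
             c(0, 64, 0), c(-70, 0, 0), c(70, 0, 0))
  pts <- head_points(p, c("nose", "scalp", "scalp", "scalp",
                          "nasion", "lpa", "rpa"), "head")
  out <- exclude_nose_points(pts)
  expect_identical(length(out), 6L)
  expect_false(any(out$points[, 2] > 0 & out$points[, 3] < 0 &
                     out$labels %in% c("scalp", "nose")))
  # fiducials are never removed even if they satisfy the rule
  fid_in_zone <- head_points(rbind(c(0, 64, -5), c(-70, 0, 0), c(70, 0, 0)),
                             c("nasion", "lpa", "rpa"), "head")
  expect_identical(length(exclude_nose_points(fid_in_zone)), 3L)

  dev_pts <- head_points(p, pts$labels, "device")
  expect_error(exclude_nose_points(dev_pts), "head")
})

test_that("signed-rank p values match full sign enumeration, ties included", {
  set.seed(101)
  for (k in 1:20) {
    n <- sample(6:12, 1)
    x <- rnorm(n, 0.4)
    y <- rnorm(n)
    if (k %% 3 == 0) {
      # force tied absolute differences
      x <- y + sample(c(-2, -1, 1, 2), n, replace = TRUE)
    }
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p_value, brute_signed_rank_p(x, y), tolerance = 1e-12)
    swapped <- wilcoxon_signed_rank(y, x)
    expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
    expect_equal(swapped$statistic, -res$statistic, tolerance = 1e-12)
  }
  # agreement with the reference implementation in the absence of ties
  set.seed(7)
  x <- rnorm(15, 0.5); y <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(x, x), "zero")
  expect_error(wilcoxon_signed_rank(1:3, c(2, 3, 4)), "fewer than 5")
})

test_that("large-sample signed-rank approximation tracks the reference", {
  set.seed(33)
  x <- rnorm(60, 0.3); y <- rnorm(60)
  res <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE,
                     correct = TRUE)$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-9)
})

test_that("Welch t matches the closed form and the reference implementation", {
  x <- c(1.1, 2.3, 0.4, 1.9, 2.8, 0.2)
  expect_equal(welch_t(x, x + 0)$statistic, 0)
  expect_equal(welch_t(x, x + 0)$p_value, 1)

  set.seed(5)
  a <- rnorm(14, 1, 2); b <- rnorm(9, 0, 0.5)
  res <- welch_t(a, b)
  ref <- t.test(a, b, var.equal = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_gte(res$df, min(length(a), length(b)) - 1)
  expect_lte(res$df, length(a) + length(b) - 2)

  pres <- welch_t(a[1:9], b, paired = TRUE)
  pref <- t.test(a[1:9], b, paired = TRUE)
  expect_equal(pres$statistic, unname(pref$statistic), tolerance = 1e-12)
  expect_equal(pres$p_value, pref$p.value, tolerance = 1e-12)
  expect_error(welch_t(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("JZS BF01 matches an independent quadrature oracle and is monotone", {
  expect_gt(jzs_bf01(0, 20), 1)  # t = 0 favours the null
  for (case in list(c(0.5, 10), c(1.7, 27), c(2.34, 50), c(3.2, 15),
                    c(0.056, 51))) {
    got <- jzs_bf01(case[1], case[2])
    want <- jzs_bf01_oracle(case[1], case[2])
    expect_lt(abs(got - want) / want, 1e-6)
  }
  # alternative prior scale
  expect_lt(abs(jzs_bf01(1.2, 30, rscale = 1) -
                  jzs_bf01_oracle(1.2, 30, rscale = 1)) /
              jzs_bf01_oracle(1.2, 30, rscale = 1), 1e-6)
  # strictly decreasing in |t| at fixed n
  ts <- seq(0, 6, by = 0.25)
  bfs <- vapply(ts, jzs_bf01, numeric(1), n = 27)
  expect_true(all(diff(bfs) < 0))
  expect_error(jzs_bf01(Inf, 10), "finite")
  expect_error(jzs_bf01(1, 10, rscale = 0), "positive")
})
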