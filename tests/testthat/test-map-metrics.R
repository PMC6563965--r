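test_that("a single pRF's density map is its own unit-height Gaussian", {
  f <- data.frame(x0 = 1, y0 = -2, sigma = 1.5, variance_explained = 1)
  d <- prf_density(f, field_samples = 111)
  expect_equal(max(d$value), 1, tolerance = 1e-6)
  ix <- which(d$value == max(d$value), arr.ind = TRUE)
  expect_lt(abs(d$x[ix[2]] - 1), 0.06)
  expect_lt(abs(d$y[ix[1]] - (-2)), 0.06)
  g <- exp(-((d$x[60] - 1)^2 + (d$y[40] + 2)^2) / (2 * 1.5^2))
  expect_equal(d$value[40, 60], g, tolerance = 1e-9)
})

test_that("density is invariant to duplicating every fit", {
  f <- data.frame(x0 = c(0, 2), y0 = c(1, -1), sigma = c(1, 0.8),
                  variance_explained = 1)
  for (mode in c("max", "sum")) {
    d1 <- prf_density(f, field_samples = 61, mode = mode)
    d2 <- prf_density(rbind(f, f), field_samples = 61, mode = mode)
    expect_equal(d1$value, d2$value, tolerance = 1e-12)
  }
  expect_error(prf_density(data.frame(x0 = 1, y0 = 1, sigma = 1,
                                      variance_explained = 0)),
               "no usable")
})

test_that("the generator's hV4 tiling covers every quadrant densely", {
  patch <- patch30()
  hv4 <- patch$truth[patch$truth$area == "hV4", ]
  d <- prf_density(hv4)
  cov <- quadrant_coverage(d, quadrant_spec("right"))
  expect_true(all(cov$percent >= 80))
})

test_that("quadrant coverage responds to degenerate and missing maps", {
  d1 <- structure(list(value = matrix(1, 61, 61),
                       x = seq(-5.5, 5.5, length.out = 61),
                       y = rev(seq(-5.5, 5.5, length.out = 61)),
                       mode = "max", n_prf = 1), class = "density_map")
  cov1 <- quadrant_coverage(d1, quadrant_spec("left"))
  expect_equal(cov1$percent, rep(100, 4))
  d0 <- d1; d0$value[] <- 0
  expect_equal(quadrant_coverage(d0, quadrant_spec("left"))$percent,
               rep(0, 4))
  expect_error(quadrant_coverage(d1, quadrant_spec("left"),
                                 threshold = 1.2), "threshold")
})

test_that("coverage percentages fall monotonically with the density threshold", {
  set.seed(33)
  f <- data.frame(x0 = runif(40, -5, 5), y0 = runif(40, -5, 5),
                  sigma = runif(40, 0.5, 2), variance_explained = 1)
  d <- prf_density(f, field_samples = 101)
  quad <- quadrant_spec("left")
  cov <- vapply(c(0.5, 0.7, 0.9),
                function(th) quadrant_coverage(d, quad,
                                               threshold = th)$percent,
                numeric(4))
  expect_true(all(diff(t(cov)) <= 1e-12))
})

test_that("the missing-lower scenario loses only its lower quadrant", {
  patch <- memo("patch30_ml", make_retinotopic_patch(
    patch_spec(scenario = "missing_lower", seed = 42)))
  hv4 <- patch$truth[patch$truth$area == "hV4", ]
  expect_true(all(hv4$meridian_dist < 135))   # no lower-sector pRFs at all
  d <- prf_density(hv4)
  cov <- classify_completeness(quadrant_coverage(d, quadrant_spec("right")))
  expect_lt(cov$percent[4], 20)
  expect_false(cov$complete[4])
  expect_true(all(cov$percent[1:3] >= 20))
  expect_true(all(cov$complete[1:3]))
})

test_that("completeness uses round-half-up at the 20% cutoff", {
  expect_false(classify_completeness(19.4))
  expect_true(classify_completeness(19.5))
  expect_false(classify_completeness(1.3))
  expect_false(classify_completeness(17.4))
  expect_true(classify_completeness(20))
  p <- sort(runif(50, 0, 100))
  expect_true(all(diff(classify_completeness(p)) >= 0))  # monotone
})

test_that("angle maps are oriented so polar angle runs along image columns", {
  lat <- c(12, 8)
  f <- data.frame(polar_angle = rep(seq(200, 330, length.out = 12), 8),
                  variance_explained = 1)
  am <- render_angle_map(f, lat, seq_len(96))
  img <- am$image
  for (j in seq_len(ncol(img))) {
    cl <- img[, j][!is.na(img[, j])]
    expect_lt(diff(range(cl)), 1e-9)      # columns constant
  }
  # the column profile is a clean ramp
  expect_equal(smoothness(am)$smoothness, 1, tolerance = 1e-9)
})

test_that("angle-map orientation is invariant to rotating the lattice", {
  lat <- c(12, 8)
  ang <- rep(seq(200, 330, length.out = 12), 8)
  f1 <- data.frame(polar_angle = ang, variance_explained = 1)
  # rotate the lattice 90 degrees: voxel (r, c) -> (c, R + 1 - r)
  m1 <- matrix(ang, 12, 8)
  m2 <- t(m1)[, 12:1]
  f2 <- data.frame(polar_angle = as.vector(m2), variance_explained = 1)
  a1 <- render_angle_map(f1, c(12, 8), 1:96)
  a2 <- render_angle_map(f2, c(8, 12), 1:96)
  d1 <- dim(a1$image); d2 <- dim(a2$image)
  expect_setequal(d1, d2)
  p1 <- smoothness(a1)$column_profile
  p2 <- smoothness(a2)$column_profile
  if (length(p1) == length(p2) &&
      sum(abs(p1 - p2)) > sum(abs(p1 - rev(p2))))
    p2 <- rev(p2)
  expect_equal(p1, p2, tolerance = 1e-9)
  expect_error(render_angle_map(f1, c(12, 8), 1:2), "2 x 2")
})

test_that("the smoothness statistic is 1 for a ramp and grows with noise", {
  ramp <- matrix(rep(seq(0, 1, length.out = 50), each = 20), 20, 50)
  s <- smoothness(ramp)
  expect_equal(s$smoothness, 1, tolerance = 1e-9)
  expect_false(s$degenerate)
  set.seed(4)
  noisy <- ramp + matrix(rnorm(1000, sd = 0.15), 20, 50)
  s2 <- smoothness(noisy)
  expect_gt(s2$smoothness, s$smoothness)
  expect_warning(s0 <- smoothness(matrix(0.5, 10, 10)), "degenerate")
  expect_equal(s0$smoothness, 0)
  expect_error(smoothness(ramp[, 1:2]), "3 usable columns")
  # comparison helper: positive when the second map is smoother
  expect_gt(percent_smoother(s2, s), 0)
  expect_lt(percent_smoother(s, s2), 0)
})
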