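test_that("full-field drives every pRF with the same waveform, scaled", {
  mov <- small_movie("fullfield")
  y1 <- predict_timecourse(list(x0 = 0, y0 = 0, sigma = 1), mov)
  y2 <- predict_timecourse(list(x0 = 3, y0 = -2, sigma = 0.5), mov)
  expect_gt(stats::cor(y1, y2), 1 - 1e-9)
  yb <- predict_timecourse(list(x0 = 1, y0 = 1, sigma = 1, beta = 0,
                                baseline = 7), mov)
  expect_equal(yb, rep(7, 120))
  expect_error(predict_timecourse(list(x0 = 0, y0 = 0, sigma = 0), mov),
               "sigma")
})

test_that("coarse grid search returns the generating candidate", {
  mov <- small_movie("bowtie")
  grid <- expand.grid(x0 = c(-2.2, 0, 2.2), y0 = c(-2.2, 0, 2.2),
                      sigma = c(0.5, 1))
  truth <- grid[7, ]
  y <- 100 + 2 * predict_timecourse(
    list(x0 = truth$x0, y0 = truth$y0, sigma = truth$sigma), mov)
  res <- fit_prf_grid(y, mov, grid = grid)
  expect_false(res$degenerate)
  expect_equal(res$params$x0, truth$x0)
  expect_equal(res$params$y0, truth$y0)
  expect_equal(res$params$sigma, truth$sigma)
  expect_lt(res$rss, 1e-12 * sum((y - mean(y))^2) + 1e-9)
  # degenerate input is flagged, not fitted
  expect_true(fit_prf_grid(rep(5, 180), mov, grid = grid)$degenerate)
})

test_that("grid search agrees with an exhaustive independent RSS oracle", {
  mov <- small_movie("ring")
  grid <- data.frame(x0 = c(1.5, -2, 0), y0 = c(2, -1, -3),
                     sigma = c(0.6, 1.2, 0.9))
  set.seed(11)
  y <- 100 + 1.5 * predict_timecourse(
    list(x0 = -2, y0 = -1, sigma = 1.2), mov) + rnorm(168, sd = 2)
  # oracle: per candidate, ordinary least squares on the raw prediction
  oracle_rss <- vapply(seq_len(nrow(grid)), function(i) {
    p <- predict_timecourse(
      list(x0 = grid$x0[i], y0 = grid$y0[i], sigma = grid$sigma[i]), mov)
    sum(stats::lm(y ~ p)$residuals^2)
  }, 1)
  res <- fit_prf_grid(y, mov, grid = grid)
  expect_equal(which.min(oracle_rss), 2L)
  expect_equal(res$params$x0, grid$x0[2])
  expect_equal(res$rss, min(oracle_rss), tolerance = 1e-6)
})

test_that("refinement recovers an off-grid pRF and never worsens the fit", {
  movs <- list(small_movie("bowtie"), small_movie("ring"))
  truth <- list(x0 = 2.0, y0 = -1.0, sigma = 0.8)
  # one shared response amplitude over unit-range per-run predictions,
  # matching the joint-fit model
  unit <- function(p) (p - min(p)) / diff(range(p))
  y <- c(100 + 2 * unit(predict_timecourse(truth, movs[[1]])),
         100 + 2 * unit(predict_timecourse(truth, movs[[2]])))
  g <- fit_prf_grid(y, movs)
  ref <- fit_prf_refine(y, movs, start = g$params)
  f <- ref$fits[1, ]
  expect_lt(abs(f$x0 - truth$x0), 0.1)
  expect_lt(abs(f$y0 - truth$y0), 0.1)
  expect_lt(abs(f$sigma - truth$sigma), 0.1)
  expect_lte(f$rss, g$rss + 1e-9)
  expect_gt(f$variance_explained, 0.99)
})

test_that("refinement reduces RSS relative to the grid stage across noisy voxels", {
  mov <- small_movie("bowtie")
  set.seed(21)
  n <- 6
  Y <- t(vapply(seq_len(n), function(i) {
    100 + 2 * predict_timecourse(
      list(x0 = runif(1, -4, 4), y0 = runif(1, -4, 4),
           sigma = runif(1, 0.4, 1.5)), mov) + rnorm(180)
  }, numeric(180)))
  coarse <- fit_prf(Y, mov, refine = FALSE)
  fine <- fit_prf(Y, mov, refine = TRUE)
  expect_true(all(fine$fits$rss <= coarse$fits$rss + 1e-9))
})

test_that("prf_fit methods are mutually consistent", {
  mov <- small_movie("ring")
  set.seed(5)
  Y <- rbind(100 + 2 * predict_timecourse(list(x0 = 1, y0 = 2, sigma = 1),
                                          mov) + rnorm(168, sd = 0.5),
             rep(3, 168))
  fit <- fit_prf(Y, mov)
  expect_true(fit$fits$degenerate[2])
  expect_equal(dim(coef(fit)), c(2L, 5L))
  pr <- predict(fit)
  expect_equal(pr[1, ] + residuals(fit)[1, ], Y[1, ], tolerance = 1e-9)
  expect_equal(fit$fits$rss[1], sum(residuals(fit)[1, ]^2),
               tolerance = 1e-6)
  s <- summary(fit)
  expect_equal(s$n_degenerate, 1L)
})

test_that("Fourier phase and coherence behave at and off the stimulus frequency", {
  n <- 120
  t <- 0:(n - 1)
  phi <- 1.3
  y <- cos(2 * pi * 12 * t / n - phi)
  pm <- fft_phase_map(y, 12)
  expect_equal(pm$coherence, 1, tolerance = 1e-9)
  expect_equal(pm$phase, phi, tolerance = 1e-9)
  # white noise: coherence hugs the noise floor
  set.seed(9)
  noise <- matrix(rnorm(50 * n), 50, n)
  pmn <- fft_phase_map(noise, 12)
  expect_gt(mean(pmn$coherence < 0.5), 0.9)
  expect_lt(stats::median(pmn$coherence), 0.3)
  expect_error(fft_phase_map(y, 60), "n_cycles")
})

test_that("travelling-wave phase reproduces the ground-truth polar angle ordering", {
  sim <- memo("sim20c_bowtie",
              simulate_bold(small_patch_clean(), protocols = "bowtie"))
  patch <- small_patch_clean()
  hv4 <- patch$areas$hV4
  # double wedge stimulates each angle twice per revolution
  pm <- fft_phase_map(sim$integrated$bowtie[hv4, ], 2 * 15)
  truth_ang <- 2 * patch$truth$meridian_dist[hv4] * pi / 180
  # positively responding voxels: inverted voxels are phase-flipped by
  # half a response cycle, which is the artefact under study
  keep <- pm$coherence > 0.5 &
    patch$truth$class_integrated[hv4] == "positive"
  expect_gt(mean(keep), 0.85)
  expect_gt(abs(circular_cor(pm$phase[keep], truth_ang[keep])), 0.9)
})
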