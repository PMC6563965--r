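test_that("mean maps normalise by the brightest voxel and ignore time order", {
  y <- rbind(rep(50, 10), rep(100, 10))
  m <- normalized_mean_map(y)
  expect_equal(as.numeric(m), c(0.5, 1))
  expect_equal(attr(m, "normalising_max"), 100)
  set.seed(2)
  yy <- matrix(rexp(60, 1 / 50), 6, 10)
  perm <- sample(10)
  expect_equal(as.numeric(normalized_mean_map(yy)),
               as.numeric(normalized_mean_map(yy[, perm])))
  expect_error(normalized_mean_map(matrix(c(1, NA), 1)), "non-finite")
  expect_error(normalized_mean_map(matrix(-c(1, 2), 1)), "non-positive")
})

test_that("eclipse voxels are darker than the rest of the patch", {
  sim <- small_sim()
  patch <- small_patch()
  m <- normalized_mean_map(sim$series$d2.5mm$fullfield)
  ecl <- patch$eclipse_voxels
  expect_lt(stats::median(m[ecl]), stats::median(m[-ecl]))
  expect_lt(mean(m[ecl]), mean(m[-ecl]))
})

test_that("correlation labels follow the sign rule with flagged degenerates", {
  ref <- ff_reference()
  y <- rbind(as.numeric(ref), -as.numeric(ref), rep(4, 120))
  cm <- correlate_reference(y, ref)
  expect_equal(cm$r, c(1, -1, 0), tolerance = 1e-12)
  expect_equal(as.character(cm$label), c("positive", "inverted", "positive"))
  expect_equal(cm$flagged, c(FALSE, FALSE, TRUE))
  expect_error(correlate_reference(y[, 1:50], ref), "lengths differ")
})

test_that("noiseless synthetic classes are recovered exactly from the correlation sign", {
  sim <- small_sim_clean()
  patch <- small_patch_clean()
  cm <- correlate_reference(sim$integrated$fullfield, ff_reference())
  truth_neg <- patch$truth$class_integrated != "positive"
  expect_identical(cm$label == "inverted", truth_neg)
  # and per depth layer
  for (ly in patch$layers) {
    cml <- correlate_reference(sim$series[[ly]]$fullfield, ff_reference())
    expect_identical(cml$label == "inverted",
                     patch$truth[[paste0("class_", ly)]] != "positive",
                     label = ly)
  }
})

test_that("flipping is an involution that negates r and preserves the mean map", {
  sim <- small_sim()
  ref <- ff_reference()
  y <- sim$integrated$fullfield
  cm <- correlate_reference(y, ref)
  y2 <- flip_timecourses(y, cm)
  expect_gt(length(attr(y2, "flipped")), 0)
  cm2 <- correlate_reference(y2, ref)
  idx <- attr(y2, "flipped")
  expect_equal(cm2$r[idx], -cm$r[idx], tolerance = 1e-12)
  expect_equal(as.numeric(normalized_mean_map(y2)),
               as.numeric(normalized_mean_map(y)), tolerance = 1e-12)
  # applying the same flip twice restores the series exactly
  y3 <- flip_timecourses(y2, cm)
  expect_equal(y3, y, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the flip threshold spares weak negative correlations", {
  ref <- ff_reference()
  y <- rbind(series_with_cor(-0.05, as.numeric(ref)),
             series_with_cor(-0.30, as.numeric(ref)))
  cm <- correlate_reference(y, ref)
  expect_equal(cm$r, c(-0.05, -0.30), tolerance = 1e-9)
  out <- flip_timecourses(y, cm, threshold = 0.1)
  expect_equal(attr(out, "flipped"), 2L)
  expect_equal(out[1, ], y[1, ])
  expect_false(isTRUE(all.equal(out[2, ], y[2, ])))
  expect_error(flip_timecourses(y, cm, threshold = -1), "non-negative")
})

test_that("eclipse detection finds the injected shadow and rejects speckle", {
  # uniform map: no dark cluster at all
  uni <- structure(rep(1, 400), normalising_max = 100, class = "mean_map")
  expect_length(detect_eclipse(uni, c(20, 20))$voxels, 0)
  # isolated dark voxels below the size filter are excluded
  v <- rep(1, 400)
  v[c(5, 111, 222, 333)] <- 0.3
  spk <- structure(v / max(v), normalising_max = 100, class = "mean_map")
  expect_length(detect_eclipse(spk, c(20, 20))$voxels, 0)
  # the synthetic eclipse at the superficial layer is recovered well
  sim <- sim30()
  patch <- patch30()
  m25 <- normalized_mean_map(sim$series$d2.5mm$fullfield)
  roi <- detect_eclipse(m25, c(30, 30), layer = "d2.5mm")
  expect_gte(jaccard(roi$voxels, patch$eclipse_voxels), 0.8)
})

test_that("superficial-layer detection outperforms the depth-integrated map", {
  sim <- sim30()
  patch <- patch30()
  gt <- patch$eclipse_voxels
  j25 <- jaccard(detect_eclipse(
    normalized_mean_map(sim$series$d2.5mm$fullfield), c(30, 30))$voxels, gt)
  jint <- jaccard(detect_eclipse(
    normalized_mean_map(sim$integrated$fullfield), c(30, 30))$voxels, gt)
  expect_gt(j25, jint)
})

test_that("eclipse ROIs round-trip through the text index format", {
  roi <- eclipse_roi(c(3L, 7L, 12L), provenance = "manual",
                     layer = "d2.5mm")
  f <- withr::local_tempfile(fileext = ".txt")
  write_eclipse_roi(roi, f)
  got <- read_eclipse_roi(f)
  expect_identical(got$voxels, roi$voxels)
  expect_identical(got$provenance, "manual")
  expect_identical(got$layer, "d2.5mm")
  expect_error(eclipse_roi(c(1L, 1L)), "unique")
})

test_that("NBRs are separated from inverted voxels by eccentricity", {
  ref <- ff_reference()
  y <- rbind(series_with_cor(-0.6, as.numeric(ref)),
             series_with_cor(-0.6, as.numeric(ref)),
             series_with_cor(0.6, as.numeric(ref)),
             series_with_cor(-0.6, as.numeric(ref)))
  cm <- correlate_reference(y, ref)
  cls <- classify_nbr_vs_inverted(cm, c(6.0, 3.0, 6.0, NA))
  expect_equal(as.character(cls),
               c("NBR", "inverted", "positive", "unclassifiable"))
  # noiseless patch: classification matches ground truth exactly
  sim <- small_sim_clean()
  patch <- small_patch_clean()
  cmp <- correlate_reference(sim$integrated$fullfield, ff_reference())
  cls2 <- classify_nbr_vs_inverted(cmp, patch$truth$eccentricity)
  expect_identical(as.character(cls2),
                   as.character(patch$truth$class_integrated))
})

test_that("NBRs are brighter and more strongly correlated than inverted voxels", {
  sim <- sim30()
  patch <- patch30()
  cm <- correlate_reference(sim$integrated$fullfield, ff_reference())
  m <- normalized_mean_map(sim$integrated$fullfield)
  cls <- classify_nbr_vs_inverted(cm, patch$truth$eccentricity)
  nbr <- cls == "NBR"; inv <- cls == "inverted"
  expect_gt(sum(nbr), 0)
  expect_gt(sum(inv), 0)
  expect_gt(mean(m[nbr]), mean(m[inv]))
  expect_gt(mean(abs(cm$r[nbr])), mean(abs(cm$r[inv])))
})

test_that("inverted-voxel fractions summarise regions and decay with depth", {
  ref <- ff_reference()
  y <- rbind(series_with_cor(0.5, as.numeric(ref)),
             series_with_cor(0.4, as.numeric(ref)),
             series_with_cor(-0.5, as.numeric(ref)))
  cm <- correlate_reference(y, ref)
  tab <- inverted_fraction_by_region(cm, list(pos = 1:2, neg = 3))
  expect_equal(tab$percent_inverted, c(0, 100))
  expect_error(inverted_fraction_by_region(cm, list(a = integer(0))),
               "empty region")
  # prevalence inside the eclipse decays toward the grey/white boundary
  sim <- sim30()
  patch <- patch30()
  fr <- vapply(c("d2.5mm", "d1mm", "grey_white"), function(ly) {
    cml <- correlate_reference(sim$series[[ly]]$fullfield, ff_reference())
    inverted_fraction_by_region(
      cml, list(ecl = patch$eclipse_voxels))$percent_inverted
  }, 1)
  expect_true(all(diff(fr) < 0))
})

test_that("mean-map intensity and correlation covary positively over visual areas", {
  sim <- sim30()
  patch <- patch30()
  cm <- correlate_reference(sim$integrated$fullfield, ff_reference())
  m <- normalized_mean_map(sim$integrated$fullfield)
  roi <- unlist(patch$areas[c("V1", "V2", "V3", "hV4")])
  expect_gt(stats::cor(as.numeric(m)[roi], cm$r[roi]), 0)
})
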