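test_that("patch geometry is retinotopically smooth and within bounds", {
  patch <- patch30()
  tr <- patch$truth
  # stimulated areas inside the display, NBR band wholly outside
  expect_true(all(tr$eccentricity[tr$area != "periphery"] <= 5.5))
  expect_true(all(tr$eccentricity[tr$area == "periphery"] > 5.5))
  # every inverted voxel lies within the stimulated field
  inv_any <- tr$inv_d2.5mm | tr$inv_d1mm | tr$inv_grey_white
  expect_true(all(tr$eccentricity[inv_any] <= 5.5))
  # neighbouring lattice voxels map neighbouring field angles
  for (ar in c("V1", "V2", "V3", "hV4")) {
    sub <- tr[tr$area == ar, ]
    for (cc in unique(sub$col)) {
      d <- sub$meridian_dist[sub$col == cc][order(sub$row[sub$col == cc])]
      expect_lt(max(abs(diff(d))), 10)
    }
  }
  # hV4 samples the full hemifield densely: every 5-degree angle bin hit
  hv4 <- tr[tr$area == "hV4", ]
  bins <- table(cut(hv4$meridian_dist, seq(0, 180, by = 5)))
  expect_true(all(bins >= 1))
})

test_that("inverted sets are nested quotas that thin toward the grey/white boundary", {
  patch <- patch30()
  tr <- patch$truth
  n_elig <- sum(tr$eclipse & !tr$nbr)
  expect_equal(sum(tr$inv_d2.5mm), round(0.8 * n_elig))
  expect_equal(sum(tr$inv_d1mm), round(0.5 * n_elig))
  expect_equal(sum(tr$inv_grey_white), round(0.2 * n_elig))
  expect_true(all(tr$inv_grey_white <= tr$inv_d1mm))
  expect_true(all(tr$inv_d1mm <= tr$inv_d2.5mm))
})

test_that("invalid patch specifications are rejected", {
  expect_error(patch_spec(lattice = c(10, 30)), "at least 20")
  expect_error(patch_spec(intensity_drop = c(0.1, 0.3, 0.45)),
               "non-increasing")
  expect_error(patch_spec(nbr_band = c(5.0, 6.0)), "outside")
  expect_error(make_retinotopic_patch(patch_spec(eclipse_rows = 40:42)),
               "outside the lattice")
})

test_that("simulation is bit-reproducible per seed with seed-free geometry", {
  s1 <- simulate_bold(make_retinotopic_patch(
    patch_spec(lattice = c(20, 20), seed = 7)), protocols = "fullfield")
  s2 <- simulate_bold(make_retinotopic_patch(
    patch_spec(lattice = c(20, 20), seed = 7)), protocols = "fullfield")
  expect_identical(s1$integrated$fullfield, s2$integrated$fullfield)
  s3 <- simulate_bold(make_retinotopic_patch(
    patch_spec(lattice = c(20, 20), seed = 8)), protocols = "fullfield")
  expect_false(identical(s1$integrated$fullfield,
                         s3$integrated$fullfield))
  geo <- c("row", "col", "area", "x0", "y0", "sigma", "eclipse")
  expect_identical(s1$patch$truth[, geo], s3$patch$truth[, geo])
})

test_that("class frequencies and labels behave under noise", {
  # noiseless: exact; default noise: high agreement with ground truth
  sim <- small_sim()
  patch <- small_patch()
  cm <- correlate_reference(sim$integrated$fullfield, ff_reference())
  truth_neg <- patch$truth$class_integrated != "positive"
  expect_gte(mean((cm$label == "inverted") == truth_neg), 0.95)
})

test_that("eclipse contrast weakens with depth and with depth-averaging", {
  sim <- sim30()
  patch <- patch30()
  gt <- patch$eclipse_voxels
  contrast <- function(s) {
    m <- normalized_mean_map(s)
    mean(m[-gt]) - mean(m[gt])
  }
  c25 <- contrast(sim$series$d2.5mm$fullfield)
  c1 <- contrast(sim$series$d1mm$fullfield)
  cgw <- contrast(sim$series$grey_white$fullfield)
  cint <- contrast(sim$integrated$fullfield)
  expect_gt(c25, c1)
  expect_gt(c1, cgw)
  expect_gt(cgw, 0)
  expect_lt(cint, c25)
})

test_that("the subject10 scenario inverts the whole lower hV4 wedge", {
  b <- memo("s10_small", scenario_subject10(seed = 3, lattice = c(20, 20)))
  tr <- b$patch$truth
  low <- tr$area == "hV4" & tr$meridian_dist >= 110
  expect_true(all(tr$inv_d2.5mm[low] & tr$inv_d1mm[low] &
                    tr$inv_grey_white[low]))
  expect_true(all(tr$class_integrated[low] == "inverted"))
  # ground truth still tiles the full hemifield
  bins <- table(cut(tr$meridian_dist[tr$area == "hV4"],
                    seq(0, 180, by = 15)))
  expect_true(all(bins >= 1))
})

test_that("fixture bundles are written, seeded, and geometry-stable", {
  out <- withr::local_tempdir()
  d1 <- generate_fixtures(file.path(out, "a"), seed = 1)
  expect_setequal(names(d1), c("default", "missing_lower", "subject10"))
  gt_file <- file.path(d1$default, "ground_truth.tsv")
  expect_true(file.exists(gt_file))
  expect_true(file.exists(file.path(d1$default,
                                    "series_integrated_fullfield.tsv")))
  d2 <- generate_fixtures(file.path(out, "b"), seed = 2)
  g1 <- utils::read.delim(gt_file)
  g2 <- utils::read.delim(file.path(d2$default, "ground_truth.tsv"))
  expect_equal(g1[, c("row", "col", "x0", "y0", "sigma")],
               g2[, c("row", "col", "x0", "y0", "sigma")])
  s1 <- utils::read.delim(file.path(d1$default,
                                    "series_integrated_fullfield.tsv"),
                          header = FALSE)
  s2 <- utils::read.delim(file.path(d2$default,
                                    "series_integrated_fullfield.tsv"),
                          header = FALSE)
  expect_false(isTRUE(all.equal(s1, s2)))
  expect_error(generate_fixtures(out, lattice = c(50, 50)), "test-scale")
})
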