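#' Normalised pRF density (visual field coverage) map
#'
#' Evaluates each usable pRF as a unit-height Gaussian profile over a square
#' visual-field lattice and combines them into a coverage map in `[0, 1]`.
#' Two constructions are available: `"max"` (default) takes the maximum
#' profile value at each field point — the field-standard coverage plot, so
#' a point is covered at 0.8 whenever it lies within ~0.67 sigma of some pRF
#' centre; `"sum"` adds the profiles and divides by the map's maximum.
#'
#' @param fits a [fit_prf()] object, or a data frame with columns `x0`,
#'   `y0`, `sigma` and optionally `variance_explained`.
#' @param field_extent half-width of the field lattice in degrees.
#' @param field_samples lattice samples per side (default 201).
#' @param mode `"max"` or `"sum"`.
#' @param ve_floor usable-fit floor on variance explained (defaults to the
#'   fit object's own, else 0.1).
#' @return an object of class `density_map`: list with matrix `value`
#'   (rows = y descending, cols = x ascending), sample coordinates `x`,
#'   `y`, the `mode` and the number of pRFs used.
#' @export
prf_density <- function(fits, field_extent = 5.5, field_samples = 201,
                        mode = c("max", "sum"), ve_floor = NULL) {
  mode <- match.arg(mode)
  if (inherits(fits, "prf_fit")) {
    if (is.null(ve_floor)) ve_floor <- fits$ve_floor
    f <- fits$fits
  } else {
    f <- as.data.frame(fits)
    if (is.null(ve_floor)) ve_floor <- 0.1
  }
  if (!is.null(f$variance_explained))
    f <- f[!is.na(f$variance_explained) &
             f$variance_explained >= ve_floor, , drop = FALSE]
  f <- f[!is.na(f$x0) & !is.na(f$sigma) & f$sigma > 0, , drop = FALSE]
  if (nrow(f) == 0) stop("no usable pRF fits above the variance floor")
  cc <- seq(-field_extent, field_extent, length.out = field_samples)
  X <- matrix(cc, field_samples, field_samples, byrow = TRUE)
  Y <- matrix(rev(cc), field_samples, field_samples)
  val <- matrix(0, field_samples, field_samples)
  for (i in seq_len(nrow(f))) {
    g <- exp(-((X - f$x0[i])^2 + (Y - f$y0[i])^2) / (2 * f$sigma[i]^2))
    val <- if (mode == "max") pmax(val, g) else val + g
  }
  if (mode == "sum") val <- val / max(val)
  structure(list(value = val, x = cc, y = rev(cc), mode = mode,
                 n_prf = nrow(f)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map>", x$mode, "mode,", x$n_prf, "pRFs on",
      length(x$x), "x", length(x$y), "field samples\n")
  invisible(x)
}

#' @export
plot.density_map <- function(x, threshold = NULL, ...) {
  graphics::image(x$x, rev(x$y), t(x$value[nrow(x$value):1, ]),
                  asp = 1, xlab = "x (deg)", ylab = "y (deg)",
                  col = grDevices::gray.colors(64, 0, 1), ...)
  if (!is.null(threshold))
    graphics::contour(x$x, rev(x$y), t(x$value[nrow(x$value):1, ]),
                      levels = threshold, add = TRUE, col = "red")
  invisible(x)
}

#' Hemifield quadrant specification
#'
#' A hemifield is divided into four contiguous 45-degree polar-angle
#' sectors, named (from the upper vertical meridian toward the lower
#' vertical meridian) `upper`, `middle-upper`, `middle-lower`, `lower`.
#'
#' @param hemifield `"left"` or `"right"`.
#' @return an object of class `quadrant_spec`.
#' @export
quadrant_spec <- function(hemifield = c("left", "right")) {
  hemifield <- match.arg(hemifield)
  structure(list(hemifield = hemifield,
                 sectors = c("upper", "middle-upper",
                             "middle-lower", "lower"),
                 breaks = c(0, 45, 90, 135, 180)),
            class = "quadrant_spec")
}

#' Percent visual-field coverage per hemifield quadrant
#'
#' Thresholds a coverage map at `threshold` and measures, for each of the
#' four 45-degree sectors of the hemifield, the percentage of the sector's
#' field-grid area (within `max_ecc`) whose density reaches the threshold.
#'
#' @param density a [prf_density()] map.
#' @param quad a [quadrant_spec()].
#' @param threshold density threshold in (0, 1); default 0.8.
#' @param max_ecc eccentricity cropping radius in degrees.
#' @return an object of class `coverage_report`: data frame with `sector`,
#'   `percent`, plus attributes recording the parameters. Use
#'   [classify_completeness()] to add complete/incomplete flags.
#' @export
quadrant_coverage <- function(density, quad, threshold = 0.8,
                              max_ecc = 5.5) {
  stopifnot(inherits(density, "density_map"),
            inherits(quad, "quadrant_spec"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  n <- length(density$x)
  X <- matrix(density$x, n, n, byrow = TRUE)
  Y <- matrix(density$y, n, n)
  ecc <- sqrt(X^2 + Y^2)
  d <- meridian_distance(field_angle(X, Y), quad$hemifield)
  pct <- numeric(4)
  for (s in 1:4) {
    in_sector <- ecc <= max_ecc & d >= quad$breaks[s] & d < quad$breaks[s + 1]
    if (s == 4) in_sector <- ecc <= max_ecc & d >= 135 & d <= 180
    if (!any(in_sector)) stop("empty sector grid: increase field_samples")
    pct[s] <- 100 * mean(density$value[in_sector] >= threshold)
  }
  rep <- data.frame(sector = quad$sectors, percent = pct)
  structure(rep, class = c("coverage_report", "data.frame"),
            hemifield = quad$hemifield, density_threshold = threshold,
            max_ecc = max_ecc)
}

#' Classify quadrant coverage as complete or incomplete
#'
#' Coverage percentages are rounded half-up to the nearest whole number and
#' flagged complete when the rounded value reaches the cutoff (default 20%),
#' so 19.4% is incomplete and 19.5% is complete.
#'
#' @param percents numeric coverage percentages in `[0, 100]`, or a
#'   [quadrant_coverage()] report.
#' @param cutoff completeness cutoff in percent.
#' @return logical vector of `complete` flags, or the report with a
#'   `complete` column appended.
#' @export
classify_completeness <- function(percents, cutoff = 20) {
  if (inherits(percents, "coverage_report")) {
    percents$complete <- classify_completeness(percents$percent, cutoff)
    attr(percents, "cutoff_percent") <- cutoff
    return(percents)
  }
  if (any(percents < 0 | percents > 100)) stop("percents must be in [0,100]")
  floor(percents + 0.5) >= cutoff
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report>", attr(x, "hemifield"), "hemifield, density >=",
      attr(x, "density_threshold"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Render a polar-angle map of an ROI as a grayscale image
#'
#' Maps fitted polar angles of ROI voxels on the cortical patch lattice to
#' luminance in `[0, 1]` (linear in angle across the ROI's angular range)
#' and rotates the lattice so that the principal spatial gradient of polar
#' angle runs along the image x-axis ("angles as horizontal as possible").
#' Non-ROI and unusable (below the variance floor) voxels are `NA` and are
#' excluded from downstream statistics.
#'
#' @param fits a [fit_prf()] object or data frame with `polar_angle` and
#'   optionally `variance_explained`.
#' @param lattice integer `c(rows, cols)`; voxel i sits at column-major
#'   position i.
#' @param roi voxel indices of the ROI (at least a 2 x 2 extent).
#' @param ve_floor usable-fit floor (defaults to the fit object's).
#' @return an object of class `angle_map`: list with matrix `image`
#'   (luminance with `NA` outside the ROI), the rotation `angle_deg`
#'   applied, and the luminance mapping range `angle_range`.
#' @export
render_angle_map <- function(fits, lattice, roi, ve_floor = NULL) {
  if (inherits(fits, "prf_fit")) {
    if (is.null(ve_floor)) ve_floor <- fits$ve_floor
    f <- fits$fits
  } else {
    f <- as.data.frame(fits)
    if (is.null(ve_floor)) ve_floor <- 0.1
  }
  ang <- rep(NA_real_, prod(lattice))
  usable <- roi
  if (!is.null(f$variance_explained))
    usable <- roi[!is.na(f$variance_explained[roi]) &
                    f$variance_explained[roi] >= ve_floor]
  ang[usable] <- f$polar_angle[usable]
  rows <- (usable - 1L) %% lattice[1] + 1L
  cols <- (usable - 1L) %/% lattice[1] + 1L
  if (length(unique(rows)) < 2 || length(unique(cols)) < 2)
    stop("ROI must span at least a 2 x 2 lattice extent")
  # principal gradient of angle over the lattice (least-squares plane)
  a <- ang[usable]
  fitpl <- stats::lm.fit(cbind(1, cols, rows), a)
  gx <- fitpl$coefficients[2]
  gy <- -fitpl$coefficients[3]          # lattice rows run downward
  theta <- atan2(gy, gx)                # rotate by -theta to align with +x
  rot <- -theta
  # rotate voxel positions about the ROI centroid and bin onto a lattice
  cr <- mean(rows); ccol <- mean(cols)
  xr <- (cols - ccol) * cos(rot) + (rows - cr) * sin(rot)
  yr <- -(cols - ccol) * sin(rot) + (rows - cr) * cos(rot)
  ix <- as.integer(round(xr - min(xr))) + 1L
  iy <- as.integer(round(yr - min(yr))) + 1L
  img <- matrix(NA_real_, max(iy), max(ix))
  rng <- range(a)
  lum <- if (diff(rng) > 0) (a - rng[1]) / diff(rng) else rep(0.5, length(a))
  # mean-aggregate voxels that fall in the same bin
  key <- paste(iy, ix)
  agg <- tapply(lum, key, mean)
  pos <- do.call(rbind, strsplit(names(agg), " "))
  img[cbind(as.integer(pos[, 1]), as.integer(pos[, 2]))] <- agg
  structure(list(image = img, angle_deg = rot * 180 / pi,
                 angle_range = rng, n_voxels = length(usable)),
            class = "angle_map")
}

#' Smoothness statistic of a polar-angle map image
#'
#' Summarises each image column by the mean luminance of its included
#' pixels, min-max normalises the column profile to `[0, 1]`, and reports
#' the total variation of the profile (the sum of absolute successive
#' differences — the discrete "absolute gradient of the plotted line"). An
#' ideal smooth map, whose profile is a clean monotone ramp spanning the
#' full range, scores exactly 1; disturbances add to the total variation,
#' so *larger values mean rougher maps*. A constant image has no angular
#' gradient; it scores 0 and is flagged degenerate.
#'
#' @param image an [render_angle_map()] result or a numeric matrix with
#'   `NA` for excluded pixels.
#' @return an object of class `smoothness_result`: list with
#'   `column_profile`, `smoothness` and `degenerate`.
#' @export
smoothness <- function(image) {
  img <- if (inherits(image, "angle_map")) image$image else image
  stopifnot(is.matrix(img))
  colv <- apply(img, 2, function(cl) {
    if (all(is.na(cl))) NA_real_ else mean(cl, na.rm = TRUE)
  })
  colv <- colv[!is.na(colv)]
  if (length(colv) < 3)
    stop("need at least 3 usable columns to measure smoothness")
  rng <- range(colv)
  if (diff(rng) == 0) {
    warning("degenerate: no angular gradient across columns")
    return(structure(list(column_profile = rep(0, length(colv)),
                          smoothness = 0, degenerate = TRUE),
                     class = "smoothness_result"))
  }
  prof <- (colv - rng[1]) / diff(rng)
  structure(list(column_profile = prof,
                 smoothness = sum(abs(diff(prof))), degenerate = FALSE),
            class = "smoothness_result")
}

#' @export
print.smoothness_result <- function(x, ...) {
  cat("<smoothness_result>", signif(x$smoothness, 4),
      "(1 = ideally smooth; larger = rougher)",
      if (x$degenerate) "[degenerate]" else "", "\n")
  invisible(x)
}

#' Percent smoothness change between two maps
#'
#' `100 * (s_A - s_B) / s_A`: positive when map B is smoother (smaller
#' statistic) than map A, e.g. `percent_smoother(original, corrected)`.
#'
#' @param a,b [smoothness()] results or bare statistics.
#' @return signed percent.
#' @export
percent_smoother <- function(a, b) {
  sa <- if (inherits(a, "smoothness_result")) a$smoothness else a
  sb <- if (inherits(b, "smoothness_result")) b$smoothness else b
  if (sa == 0) stop("reference map has zero smoothness statistic")
  100 * (sa - sb) / sa
}
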