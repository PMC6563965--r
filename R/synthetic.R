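#' Specification of a synthetic cortical patch
#'
#' Describes the study conditions emulated by the generator: a rows x cols
#' voxel lattice carved into retinotopically organised bands for V1, V2, V3
#' and hV4 plus a peripheral band just outside the stimulated field (the
#' negative-BOLD band), three cortical depth layers above the grey/white
#' boundary, and a spatially contiguous venous eclipse near the lower hV4
#' border whose intensity shadow and inverted-response prevalence decay with
#' cortical depth.
#'
#' Default amplitudes: signal baseline 100 with 5% voxel-to-voxel baseline
#' heterogeneity, response amplitude `beta = 2` (unit-range predictions),
#' Gaussian noise SD 1; NBR voxels respond negatively with amplitude 1.5
#' and noise SD 0.5 (stronger-correlated, brighter and less noisy than
#' inverted voxels). Eclipse layers (2.5 mm, 1 mm, grey/white) carry
#' fractional intensity drops (0.45, 0.30, 0.10) and inverted-voxel
#' probabilities (0.8, 0.5, 0.2), realised as nested quota samples so that
#' prevalence decays monotonically with depth; the shadow is tapered
#' (0.15..1) along the eclipse's length, as a vessel shadow fades at its
#' ends.
#'
#' @param lattice integer `c(rows, cols)`, at least 20 x 20.
#' @param hemifield hemifield mapped by the patch (`"right"` = left
#'   hemisphere analogue, the default).
#' @param scenario `"default"`, `"missing_lower"` (hV4 map compressed to
#'   polar angles < 120 deg from the upper vertical meridian, no eclipse),
#'   or `"subject10"` (full hV4 in ground truth, but all voxels beyond
#'   110 deg rendered inverted at every depth by a strong eclipse).
#' @param seed integer seed governing all randomness of the patch and its
#'   simulated series.
#' @param baseline,beta,noise_sd,baseline_jitter positive-voxel signal
#'   parameters (arbitrary EPI units).
#' @param nbr_beta,nbr_noise_sd negative-BOLD band parameters.
#' @param intensity_drop,inversion_prob length-3 vectors for layers
#'   (`d2.5mm`, `d1mm`, `grey_white`); must be non-increasing toward the
#'   grey/white boundary.
#' @param stim_max maximum stimulated eccentricity (degrees).
#' @param nbr_band eccentricity range of the NBR band, wholly beyond
#'   `stim_max`.
#' @param sigma_intercept,sigma_slope pRF size model
#'   `sigma = intercept + slope * eccentricity`.
#' @param eclipse_rows,eclipse_cols optional explicit eclipse placement
#'   (default scenario only); must lie within the lattice.
#' @param aperture_samples grid resolution used when this spec renders its
#'   aperture movies.
#' @return an object of class `patch_spec`.
#' @export
patch_spec <- function(lattice = c(30, 30), hemifield = c("right", "left"),
                       scenario = c("default", "missing_lower", "subject10"),
                       seed = 1L,
                       baseline = 100, beta = 2, noise_sd = 1,
                       baseline_jitter = 0.05,
                       nbr_beta = 1.5, nbr_noise_sd = 0.5,
                       intensity_drop = c(0.45, 0.30, 0.10),
                       inversion_prob = c(0.8, 0.5, 0.2),
                       stim_max = 5.5, nbr_band = c(5.7, 6.6),
                       sigma_intercept = 0.3, sigma_slope = 0.2,
                       eclipse_rows = NULL, eclipse_cols = NULL,
                       aperture_samples = 51) {
  hemifield <- match.arg(hemifield)
  scenario <- match.arg(scenario)
  if (scenario == "subject10" && missing(inversion_prob))
    inversion_prob <- c(1, 1, 1)   # the eclipse inverts at every depth
  if (any(lattice < 20)) stop("lattice must be at least 20 x 20")
  if (any(diff(intensity_drop) > 0) || any(diff(inversion_prob) > 0))
    stop("intensity_drop and inversion_prob must be non-increasing from ",
         "the 2.5 mm layer to the grey/white boundary")
  if (nbr_band[1] <= stim_max)
    stop("nbr_band must lie wholly outside the stimulated eccentricity")
  if (!is.null(eclipse_rows) &&
      (any(eclipse_rows < 1) || any(eclipse_rows > lattice[1])))
    stop("eclipse rows outside the lattice")
  if (!is.null(eclipse_cols) &&
      (any(eclipse_cols < 1) || any(eclipse_cols > lattice[2])))
    stop("eclipse columns outside the lattice")
  structure(list(lattice = as.integer(lattice), hemifield = hemifield,
                 scenario = scenario, seed = as.integer(seed),
                 baseline = baseline, beta = beta, noise_sd = noise_sd,
                 baseline_jitter = baseline_jitter,
                 nbr_beta = nbr_beta, nbr_noise_sd = nbr_noise_sd,
                 intensity_drop = intensity_drop,
                 inversion_prob = inversion_prob,
                 stim_max = stim_max, nbr_band = nbr_band,
                 sigma_intercept = sigma_intercept,
                 sigma_slope = sigma_slope,
                 eclipse_rows = eclipse_rows, eclipse_cols = eclipse_cols,
                 aperture_samples = aperture_samples,
                 layers = c("grey_white", "d1mm", "d2.5mm")),
            class = "patch_spec")
}

# internal: split the lattice columns into area bands, scaled from the
# 30-column reference layout (V1/V2/V3: 5 each, hV4: 11, periphery: 4)
area_bands <- function(ncols) {
  per <- max(2L, round(ncols * 4 / 30))
  hv4 <- max(4L, round(ncols * 11 / 30))
  rest <- ncols - per - hv4
  if (rest < 6L) stop("lattice too narrow for the area layout")
  w <- rep(rest %/% 3L, 3L)
  w[seq_len(rest %% 3L)] <- w[seq_len(rest %% 3L)] + 1L
  widths <- c(V1 = w[1], V2 = w[2], V3 = w[3], hV4 = hv4, periphery = per)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  data.frame(area = names(widths), start = starts, end = ends,
             row.names = NULL)
}

#' Generate a synthetic retinotopic cortical patch with ground truth
#'
#' Lays out smooth polar-angle and eccentricity gradients in each area band
#' (polar angle runs along lattice rows from the upper to the lower vertical
#' meridian, with small per-column offsets so that angles are sampled
#' densely; eccentricity runs along columns within each band), places the
#' venous eclipse, and draws the nested per-depth inverted-voxel sets.
#'
#' @param spec a [patch_spec()].
#' @return an object of class `cortical_patch`: list with the `spec`, the
#'   per-voxel ground-truth data frame `truth` (lattice position, area,
#'   pRF parameters, eccentricity and polar angle, eclipse membership and
#'   shadow taper, per-layer and depth-integrated response classes), the
#'   `areas` voxel-index list and `eclipse_voxels`.
#' @export
make_retinotopic_patch <- function(spec = patch_spec()) {
  stopifnot(inherits(spec, "patch_spec"))
  R <- spec$lattice[1]; C <- spec$lattice[2]
  bands <- area_bands(C)
  nvox <- R * C
  vox <- seq_len(nvox)
  row <- (vox - 1L) %% R + 1L
  col <- (vox - 1L) %/% R + 1L
  area <- character(nvox)
  ecc <- numeric(nvox)
  doff <- numeric(nvox)
  step <- 180 / (R - 1)
  for (b in seq_len(nrow(bands))) {
    in_b <- col >= bands$start[b] & col <= bands$end[b]
    area[in_b] <- bands$area[b]
    k <- col[in_b] - bands$start[b]
    wdt <- bands$end[b] - bands$start[b] + 1L
    erange <- if (bands$area[b] == "periphery") spec$nbr_band
              else c(0.5, spec$stim_max)
    ecc[in_b] <- erange[1] + (erange[2] - erange[1]) * k / max(wdt - 1L, 1L)
    doff[in_b] <- step * k / wdt      # sub-row angular offset per column
  }
  d <- pmin((row - 1L) * step + doff, 180)
  # scenario adjustments to the hV4 angular range
  hv4 <- area == "hV4"
  if (spec$scenario == "missing_lower") d[hv4] <- d[hv4] * 119 / 180
  theta <- if (spec$hemifield == "left") d else (360 - d) %% 360
  xy <- angle_to_xy(theta, ecc)
  sigma <- spec$sigma_intercept + spec$sigma_slope * ecc

  # eclipse placement
  if (spec$scenario == "subject10") {
    eclipse <- hv4 & d >= 110
    taper <- as.numeric(eclipse)
  } else if (spec$scenario == "missing_lower") {
    eclipse <- rep(FALSE, nvox)
    taper <- numeric(nvox)
  } else {
    er <- if (is.null(spec$eclipse_rows)) (R - 5L):(R - 3L)
          else spec$eclipse_rows
    h_start <- bands$start[bands$area == "hV4"]
    h_end <- bands$end[bands$area == "hV4"]
    ec <- if (is.null(spec$eclipse_cols))
      max(1L, h_start - 2L):min(C, h_end + 3L) else spec$eclipse_cols
    eclipse <- row %in% er & col %in% ec
    # vessel shadow fades linearly toward the ends of the band
    mid <- mean(range(ec))
    half <- max(diff(range(ec)) / 2, 1)
    taper <- ifelse(eclipse, 1 - 0.85 * abs(col - mid) / half, 0)
    taper <- pmax(taper, 0.15 * eclipse)
  }

  nbr <- area == "periphery"
  # nested per-depth inverted sets (quota sampling among eligible voxels)
  eligible <- which(eclipse & !nbr)
  pr <- spec$inversion_prob          # (d2.5mm, d1mm, grey_white)
  set.seed(spec$seed)
  n25 <- round(pr[1] * length(eligible))
  n1 <- round(pr[2] * length(eligible))
  ngw <- round(pr[3] * length(eligible))
  s25 <- if (length(eligible)) sample(eligible, n25) else integer(0)
  s1 <- if (n25) sample(s25, min(n1, n25)) else integer(0)
  sgw <- if (length(s1)) sample(s1, min(ngw, length(s1))) else integer(0)
  inv_d25 <- vox %in% s25
  inv_d1 <- vox %in% s1
  inv_gw <- vox %in% sgw

  cls <- function(inv) factor(ifelse(nbr, "NBR",
                              ifelse(inv, "inverted", "positive")),
                              levels = c("positive", "inverted", "NBR"))
  k <- inv_d25 + inv_d1 + inv_gw
  truth <- data.frame(
    voxel = vox, row = row, col = col, area = area,
    x0 = xy$x, y0 = xy$y, sigma = sigma,
    eccentricity = ecc, meridian_dist = d, polar_angle = theta,
    eclipse = eclipse, taper = taper, nbr = nbr,
    inv_grey_white = inv_gw, inv_d1mm = inv_d1, inv_d2.5mm = inv_d25,
    class_grey_white = cls(inv_gw), class_d1mm = cls(inv_d1),
    class_d2.5mm = cls(inv_d25),
    class_integrated = cls(k >= 2))
  areas <- split(vox, area)
  structure(list(spec = spec, truth = truth, areas = areas,
                 eclipse_voxels = which(eclipse),
                 layers = spec$layers, hemifield = spec$hemifield),
            class = "cortical_patch")
}

#' @export
print.cortical_patch <- function(x, ...) {
  cat("<cortical_patch>", x$spec$lattice[1], "x", x$spec$lattice[2],
      "voxels (", x$spec$scenario, "scenario,", x$hemifield,
      "hemifield, seed", x$spec$seed, ")\n")
  cat("  areas:", paste(names(x$areas), lengths(x$areas), collapse = ", "),
      "\n")
  cat("  eclipse:", length(x$eclipse_voxels), "voxels;",
      sum(x$truth$inv_d2.5mm), "/", sum(x$truth$inv_d1mm), "/",
      sum(x$truth$inv_grey_white),
      "inverted at 2.5mm / 1mm / grey-white\n")
  invisible(x)
}

#' Simulate BOLD time series for a cortical patch
#'
#' The generative model is the package's own pRF forward model: each
#' voxel's prediction is its ground-truth Gaussian receptive field
#' overlapped with the aperture movie and convolved with the HRF, scaled to
#' unit range. Per depth layer, a positive voxel is
#' `baseline + beta * prediction + noise`; an inverted voxel is
#' `baseline * (1 - drop) - beta * prediction + noise` (sign-inverted and
#' dimmed by the eclipse shadow); an NBR voxel is
#' `baseline - nbr_beta * prediction + low noise` (strongly negatively
#' correlated, bright, less noisy). Eclipse voxels are dimmed at every
#' layer whether or not they are inverted there. The depth-integrated
#' series is the unweighted mean over the three layers. All randomness
#' derives from `spec$seed`.
#'
#' @param patch a [make_retinotopic_patch()] result.
#' @param protocols character vector of stimulus names to simulate.
#' @param model an [hrf_model()].
#' @return an object of class `bold_sim`: list with `movies` (per
#'   protocol), `series` (`$layer$protocol` voxel x volume matrices),
#'   `integrated` (`$protocol`), and the originating `patch`.
#' @export
simulate_bold <- function(patch,
                          protocols = c("bowtie", "ring", "bar",
                                        "fullfield"),
                          model = hrf_model()) {
  stopifnot(inherits(patch, "cortical_patch"))
  spec <- patch$spec
  tr <- patch$truth
  missing_p <- setdiff(protocols, c("bowtie", "ring", "bar", "fullfield"))
  if (length(missing_p))
    stop("unknown protocol(s): ", paste(missing_p, collapse = ", "))
  movies <- lapply(protocols, function(p)
    render_apertures(make_protocol(p), grid_samples = spec$aperture_samples))
  names(movies) <- protocols

  set.seed(spec$seed)
  nvox <- nrow(tr)
  base_v <- spec$baseline *
    (1 + spec$baseline_jitter * stats::rnorm(nvox))

  # unit-range predictions per protocol (voxels x volumes)
  preds <- lapply(movies, function(mov) {
    prep <- prf_prepare(list(mov), model)
    G <- exp(-((outer(prep$xv[[1]], tr$x0, "-"))^2 +
                 (outer(prep$yv[[1]], tr$y0, "-"))^2) /
               matrix(2 * tr$sigma^2, length(prep$xv[[1]]), nvox,
                      byrow = TRUE))
    P <- prep$M[[1]] %*% (prep$F[[1]] %*% G)
    rng <- apply(P, 2, function(p) diff(range(p)))
    rng[rng == 0] <- 1
    t(sweep(P, 2, rng, "/"))
  })

  layer_amp <- function(layer) {
    inv <- tr[[paste0("inv_", sub("\\.", ".", layer))]]
    ifelse(tr$nbr, -spec$nbr_beta, ifelse(inv, -spec$beta, spec$beta))
  }
  drops <- stats::setNames(rev(spec$intensity_drop),
                           c("grey_white", "d1mm", "d2.5mm"))
  series <- list()
  for (layer in patch$layers) {
    amp <- layer_amp(layer)
    bl <- base_v * (1 - drops[[layer]] * tr$taper)
    series[[layer]] <- lapply(protocols, function(p) {
      Tn <- ncol(preds[[p]])
      sd_v <- ifelse(tr$nbr, spec$nbr_noise_sd, spec$noise_sd)
      noise <- matrix(stats::rnorm(nvox * Tn), nvox, Tn) * sd_v
      bl + amp * preds[[p]] + noise
    })
    names(series[[layer]]) <- protocols
  }
  integrated <- lapply(protocols, function(p)
    Reduce(`+`, lapply(series, `[[`, p)) / length(series))
  names(integrated) <- protocols

  structure(list(movies = movies, series = series,
                 integrated = integrated, patch = patch, model = model),
            class = "bold_sim")
}

#' @export
print.bold_sim <- function(x, ...) {
  cat("<bold_sim>", nrow(x$patch$truth), "voxels;",
      length(x$movies), "protocols (",
      paste(names(x$movies), collapse = ", "), ") x",
      length(x$series), "layers + integrated\n")
  invisible(x)
}

#' The "restored hemifield" demonstration scenario
#'
#' A patch whose hV4 lower-quadrant receptive fields exist in ground truth
#' but are rendered as inverted voxels by a strong venous eclipse at every
#' depth, so the measured lower quadrant classifies incomplete before the
#' flipping correction and complete after it.
#'
#' @param seed integer seed.
#' @param lattice lattice size (default 30 x 30).
#' @return list with `patch` and `sim` (a [simulate_bold()] result for all
#'   four protocols).
#' @export
scenario_subject10 <- function(seed = 1L, lattice = c(30, 30)) {
  patch <- make_retinotopic_patch(
    patch_spec(lattice = lattice, scenario = "subject10", seed = seed))
  list(patch = patch, sim = simulate_bold(patch))
}

#' Write the three standard synthetic scenarios as plain-text fixtures
#'
#' Emits, for each of `default`, `missing_lower` and `subject10`, the
#' ground-truth table (TSV), the spec echo (YAML) and the depth-integrated
#' series per protocol (TSV), at test scale.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed integer seed.
#' @param lattice lattice size for the fixtures (kept small; at most
#'   40 x 40).
#' @param protocols protocols to simulate for each scenario.
#' @return invisibly, the named list of per-scenario directories.
#' @export
generate_fixtures <- function(out_dir, seed = 1L, lattice = c(20, 20),
                              protocols = c("fullfield")) {
  if (any(lattice > 40)) stop("fixtures are test-scale: lattice <= 40 x 40")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  dirs <- list()
  for (sc in c("default", "missing_lower", "subject10")) {
    d <- file.path(out_dir, sc)
    dir.create(d, showWarnings = FALSE)
    spec <- patch_spec(lattice = lattice, scenario = sc, seed = seed)
    patch <- make_retinotopic_patch(spec)
    sim <- simulate_bold(patch, protocols = protocols)
    utils::write.table(patch$truth, file.path(d, "ground_truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    yaml::write_yaml(unclass(spec), file.path(d, "spec.yaml"))
    for (p in protocols)
      utils::write.table(sim$integrated[[p]],
                         file.path(d, paste0("series_integrated_", p,
                                             ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    dirs[[sc]] <- d
  }
  invisible(dirs)
}
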