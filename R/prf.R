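#' Predict a voxel time course from population receptive field parameters
#'
#' The forward pRF model: at every retained volume the binary stimulus
#' aperture is overlapped with an isotropic 2-D Gaussian receptive field
#' (centre `x0`, `y0`; width `sigma`, all in degrees), and the resulting
#' neuronal drive is convolved with the canonical HRF (at the kernel's fine
#' time step, then sampled at volume onsets), scaled by `beta` and offset by
#' `baseline`.
#'
#' @param params list or one-row data frame with `x0`, `y0`, `sigma` and
#'   optionally `beta` (default 1) and `baseline` (default 0).
#' @param movie an [render_apertures()] movie.
#' @param model an [hrf_model()].
#' @return numeric vector of predicted signal, one value per frame.
#' @export
predict_timecourse <- function(params, movie, model = hrf_model()) {
  stopifnot(inherits(movie, "aperture_movie"))
  if (is.null(params$sigma) || params$sigma <= 0)
    stop("sigma must be positive")
  prep <- prf_prepare(list(movie), model)
  g <- gaussian_column(prep, 1L, params$x0, params$y0, params$sigma)
  pred <- as.vector(prep$M[[1]] %*% (prep$F[[1]] %*% g))
  beta <- if (is.null(params$beta)) 1 else params$beta
  baseline <- if (is.null(params$baseline)) 0 else params$baseline
  baseline + beta * pred
}

#' Default coarse search grid for pRF fitting
#'
#' An 11 x 11 lattice of centres spanning +/- `extent` degrees crossed with
#' sigma in 0.25, 0.5, 1, 2, 4 degrees.
#'
#' @param extent half-width of the centre lattice in degrees.
#' @return data frame with columns `x0`, `y0`, `sigma`.
#' @export
default_prf_grid <- function(extent = 5.5) {
  expand.grid(x0 = seq(-extent, extent, length.out = 11),
              y0 = seq(-extent, extent, length.out = 11),
              sigma = c(0.25, 0.5, 1, 2, 4))
}

# ---- internal machinery -----------------------------------------------------

# Precompute, per movie, the flattened frame matrix F (volumes x pixels), the
# pixel coordinates, and the TR-grid HRF convolution operator M so that a
# candidate prediction is M %*% (F %*% gaussian).
prf_prepare <- function(movies, model) {
  if (inherits(movies, "aperture_movie")) movies <- list(movies)
  stopifnot(all(vapply(movies, inherits, TRUE, "aperture_movie")))
  Fs <- Ms <- xs <- ys <- vector("list", length(movies))
  for (m in seq_along(movies)) {
    mov <- movies[[m]]
    d <- dim(mov$frames)
    g <- d[2]
    Fs[[m]] <- matrix(as.numeric(mov$frames), nrow = d[1]) *
      mov$degrees_per_sample^2
    xs[[m]] <- rep(mov$x, each = g)
    ys[[m]] <- rep(mov$y, times = g)
    taps <- tr_response_taps(mov$protocol$tr, model)
    Tn <- d[1]
    M <- matrix(0, Tn, Tn)
    for (j in seq_len(Tn)) {
      i <- j:min(Tn, j + length(taps) - 1L)
      M[i, j] <- taps[seq_along(i)]
    }
    Ms[[m]] <- M
  }
  shared <- length(movies) == 1L ||
    all(vapply(movies[-1], function(mv)
      identical(mv$x, movies[[1]]$x) && identical(mv$y, movies[[1]]$y),
      TRUE))
  list(F = Fs, M = Ms, xv = xs, yv = ys, shared_grid = shared,
       nvol = vapply(Fs, nrow, 1L), movies = movies, model = model)
}

gaussian_column <- function(prep, m, x0, y0, sigma) {
  exp(-((prep$xv[[m]] - x0)^2 + (prep$yv[[m]] - y0)^2) / (2 * sigma^2))
}

# concatenated prediction for one candidate.  Each run's block is scaled to
# unit range so that runs of different stimuli contribute comparably to a
# joint fit and the fitted amplitude is in signal units per run; a
# constant-zero block (pRF outside the aperture path) is left as is.
prf_predict_raw <- function(prep, x0, y0, sigma) {
  g1 <- if (prep$shared_grid) gaussian_column(prep, 1L, x0, y0, sigma)
  unlist(lapply(seq_along(prep$F), function(m) {
    g <- if (prep$shared_grid) g1 else gaussian_column(prep, m, x0, y0, sigma)
    p <- as.vector(prep$M[[m]] %*% (prep$F[[m]] %*% g))
    rng <- diff(range(p))
    if (rng > 0) p / rng else p
  }), use.names = FALSE)
}

# candidate prediction matrix (total volumes x candidates), with the same
# per-run unit-range scaling as prf_predict_raw
prf_candidate_preds <- function(prep, grid) {
  blocks <- lapply(seq_along(prep$F), function(m) {
    G <- vapply(seq_len(nrow(grid)), function(i)
      gaussian_column(prep, if (prep$shared_grid) 1L else m,
                      grid$x0[i], grid$y0[i], grid$sigma[i]),
      numeric(length(prep$xv[[if (prep$shared_grid) 1L else m]])))
    P <- prep$M[[m]] %*% (prep$F[[m]] %*% G)
    rng <- apply(P, 2, function(p) diff(range(p)))
    rng[rng == 0] <- 1
    sweep(P, 2, rng, "/")
  })
  do.call(rbind, blocks)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run-block index list from per-movie volume counts
run_blocks <- function(nvol) {
  ends <- cumsum(nvol)
  starts <- ends - nvol + 1L
  Map(seq.int, starts, ends)
}

# remove each run block's mean (vector, or per row of a matrix)
center_runs <- function(x, blocks) {
  if (is.matrix(x)) {
    for (b in blocks) x[, b] <- x[, b] - rowMeans(x[, b, drop = FALSE])
  } else {
    for (b in blocks) x[b] <- x[b] - mean(x[b])
  }
  x
}

# ---- fitting ---------------------------------------------------------------

#' Fit population receptive fields by two-stage coarse-to-fine search
#'
#' The package's central estimator. Stage one evaluates every candidate of a
#' coarse grid of pRF parameters against each voxel time course, solving the
#' amplitude (`beta`) and baseline in closed form by least squares; stage
#' two refines the winning candidate per voxel by derivative-free local
#' minimisation of the residual sum of squares over (`x0`, `y0`, `sigma`),
#' with the linear parameters profiled out. Every run (scan) carries its own
#' baseline — scans have arbitrary DC offsets, and the flipping correction
#' reflects each run about its own mean — so the linear part is one shared
#' amplitude plus a per-run intercept. By default the response
#' amplitude is constrained to be non-negative (the positive-BOLD
#' assumption), which is what makes the inverted-voxel flipping correction
#' consequential: an exactly inverted time course cannot be absorbed by a
#' sign flip of `beta` and instead fits a mirrored or degenerate receptive
#' field.
#'
#' Multiple mapping runs (e.g. bowtie + ring + bar) are fitted jointly by
#' concatenating predictions and data in the order of `movies`; each run's
#' prediction is scaled to unit range before concatenation so that runs of
#' different stimuli contribute comparably and `beta` reads as the per-run
#' response amplitude in signal units.
#'
#' @param series numeric matrix (voxels x volumes) or vector; total volume
#'   count must equal the summed frame counts of `movies`.
#' @param movies an [render_apertures()] movie or list of movies.
#' @param model an [hrf_model()].
#' @param grid coarse candidate grid, as from [default_prf_grid()].
#' @param refine run the continuous refinement stage (default `TRUE`).
#' @param allow_negative permit negative response amplitudes (default
#'   `FALSE`).
#' @param ve_floor variance-explained floor below which downstream coverage
#'   and smoothness computations ignore a voxel (stored on the object).
#' @param control optimiser settings: `reltol` (default `1e-6`) and `maxit`
#'   (default 500) for the Nelder-Mead refinement.
#' @param corrected logical flag recording whether `series` had the
#'   inverted-voxel correction applied (carried into the result).
#' @return an object of class `prf_fit`; see [coef.prf_fit()],
#'   [predict.prf_fit()], [summary.prf_fit()]. The per-voxel table is in
#'   `$fits` with columns `voxel`, `x0`, `y0`, `sigma`, `polar_angle`,
#'   `eccentricity`, `beta`, `baseline`, `rss`, `variance_explained`,
#'   `converged`, `degenerate`.
#' @examples
#' mov <- render_apertures(make_protocol("fullfield"), grid_samples = 21)
#' y <- predict_timecourse(list(x0 = 1, y0 = 1, sigma = 1, beta = 2,
#'                              baseline = 100), mov)
#' fit <- fit_prf(rbind(y), mov, grid = default_prf_grid()[seq(1, 605, 40), ])
#' @export
fit_prf <- function(series, movies, model = hrf_model(),
                    grid = default_prf_grid(), refine = TRUE,
                    allow_negative = FALSE, ve_floor = 0.1,
                    control = list(), corrected = FALSE) {
  if (!is.matrix(series)) series <- matrix(series, nrow = 1)
  if (nrow(grid) == 0) stop("candidate grid is empty")
  ctrl <- utils::modifyList(list(reltol = 1e-6, maxit = 500), control)
  prep <- prf_prepare(movies, model)
  Tn <- sum(prep$nvol)
  if (ncol(series) != Tn)
    stop("series has ", ncol(series), " volumes but the movies supply ", Tn)

  blocks <- run_blocks(prep$nvol)
  P <- prf_candidate_preds(prep, grid)
  Pc <- center_runs(t(P), blocks)          # candidates x volumes, centred
  Pc <- t(Pc)
  Pn <- sqrt(colSums(Pc^2))
  ok_cand <- Pn > 0
  Yc <- center_runs(series, blocks)
  Yn <- sqrt(rowSums(Yc^2))
  degenerate <- Yn == 0

  R <- matrix(0, nrow(series), nrow(grid))
  if (any(!degenerate) && any(ok_cand)) {
    R[!degenerate, ok_cand] <-
      (Yc[!degenerate, , drop = FALSE] %*% Pc[, ok_cand, drop = FALSE]) /
      outer(Yn[!degenerate], Pn[ok_cand])
  }
  score <- if (allow_negative) abs(R) else R
  win <- max.col(score, ties.method = "first")

  E <- max(vapply(prep$movies, function(m) m$grid_extent, 1))
  nv <- nrow(series)
  out <- data.frame(voxel = seq_len(nv), x0 = NA_real_, y0 = NA_real_,
                    sigma = NA_real_, polar_angle = NA_real_,
                    eccentricity = NA_real_, beta = NA_real_,
                    baseline = NA_real_, rss = NA_real_,
                    variance_explained = NA_real_,
                    converged = NA, degenerate = degenerate)

  baseline_runs <- matrix(NA_real_, nv, length(blocks))
  for (v in seq_len(nv)) {
    if (degenerate[v]) next
    yc <- Yc[v, ]
    yn <- Yn[v]
    start <- c(grid$x0[win[v]], grid$y0[win[v]], log(grid$sigma[win[v]]))
    objective <- function(par) {
      x0 <- clamp(par[1], -2 * E, 2 * E)
      y0 <- clamp(par[2], -2 * E, 2 * E)
      sg <- clamp(exp(par[3]), 0.05, 4 * E)
      p <- prf_predict_raw(prep, x0, y0, sg)
      pc <- center_runs(p, blocks)
      pn <- sqrt(sum(pc^2))
      if (pn == 0) return(0)
      r <- sum(pc * yc) / (pn * yn)
      if (allow_negative) -abs(r) else -r
    }
    r_grid <- R[v, win[v]]
    score_grid <- if (allow_negative) abs(r_grid) else r_grid
    best <- c(start[1:2], exp(start[3]))
    conv <- TRUE
    if (refine) {
      opt <- stats::optim(start, objective, method = "Nelder-Mead",
                          control = list(reltol = ctrl$reltol,
                                         maxit = ctrl$maxit))
      if (-opt$value >= score_grid) {
        best <- c(clamp(opt$par[1], -2 * E, 2 * E),
                  clamp(opt$par[2], -2 * E, 2 * E),
                  clamp(exp(opt$par[3]), 0.05, 4 * E))
        conv <- opt$convergence == 0
      } else {
        conv <- FALSE   # refinement failed to improve; keep the grid start
      }
    }
    p <- prf_predict_raw(prep, best[1], best[2], best[3])
    fitv <- prf_linfit(series[v, ], p, blocks, allow_negative)
    out$x0[v] <- best[1]; out$y0[v] <- best[2]; out$sigma[v] <- best[3]
    out$beta[v] <- fitv$beta; out$baseline[v] <- fitv$baseline
    out$rss[v] <- fitv$rss
    out$variance_explained[v] <- fitv$ve
    out$converged[v] <- conv
    baseline_runs[v, ] <- fitv$baseline_runs
  }
  out$polar_angle <- field_angle(out$x0, out$y0)
  out$eccentricity <- field_ecc(out$x0, out$y0)

  structure(list(fits = out, model = model, grid = grid,
                 movies = prep$movies, series = series,
                 baseline_runs = baseline_runs,
                 allow_negative = allow_negative, ve_floor = ve_floor,
                 corrected = corrected),
            class = "prf_fit")
}

# closed-form amplitude and per-run baselines given a raw prediction;
# enforces the non-negative amplitude constraint when requested
prf_linfit <- function(y, p, blocks, allow_negative) {
  yc <- center_runs(y, blocks)
  pc <- center_runs(p, blocks)
  tss <- sum(yc^2)
  vp <- sum(pc^2)
  if (vp == 0) {
    b0r <- vapply(blocks, function(b) mean(y[b]), 1)
    return(list(beta = 0, baseline = mean(b0r), baseline_runs = b0r,
                rss = tss, ve = 0))
  }
  b1 <- sum(pc * yc) / vp
  if (!allow_negative && b1 < 0) b1 <- 0
  b0r <- vapply(blocks, function(b) mean(y[b]) - b1 * mean(p[b]), 1)
  rss <- sum((yc - b1 * pc)^2)
  ve <- if (tss > 0) clamp(1 - rss / tss, 0, 1) else 0
  list(beta = b1, baseline = mean(b0r), baseline_runs = b0r, rss = rss,
       ve = ve)
}

#' Coarse-grid pRF search for a single voxel
#'
#' Stage one of the coarse-to-fine search in isolation: evaluates every
#' candidate of `grid`, solving amplitude and baseline by least squares,
#' and returns the candidate minimising the residual sum of squares.
#'
#' @inheritParams fit_prf
#' @param series numeric vector, one voxel's time course.
#' @return list with `params` (x0, y0, sigma, beta, baseline), `rss`, and
#'   `degenerate` (`TRUE` for a zero-variance series, in which case no fit
#'   is attempted).
#' @export
fit_prf_grid <- function(series, movies, model = hrf_model(),
                         grid = default_prf_grid(),
                         allow_negative = FALSE) {
  if (stats::var(as.numeric(series)) == 0)
    return(list(params = NULL, rss = NA_real_, degenerate = TRUE))
  f <- fit_prf(matrix(series, nrow = 1), movies, model = model, grid = grid,
               refine = FALSE, allow_negative = allow_negative)
  r <- f$fits[1, ]
  list(params = list(x0 = r$x0, y0 = r$y0, sigma = r$sigma, beta = r$beta,
                     baseline = r$baseline),
       rss = r$rss, degenerate = FALSE)
}

#' Continuous pRF refinement for a single voxel
#'
#' Stage two of the coarse-to-fine search: local derivative-free
#' minimisation of the residual sum of squares over position and size
#' starting from a coarse-grid winner. The refined fit never has larger RSS
#' than its start; if the optimiser fails to improve, the start is returned
#' with `converged = FALSE`.
#'
#' @inheritParams fit_prf_grid
#' @param start list with `x0`, `y0`, `sigma` (e.g. `fit_prf_grid()$params`).
#' @return a one-voxel `prf_fit` object.
#' @export
fit_prf_refine <- function(series, movies, start, model = hrf_model(),
                           allow_negative = FALSE, control = list()) {
  grid1 <- data.frame(x0 = start$x0, y0 = start$y0, sigma = start$sigma)
  fit_prf(matrix(series, nrow = 1), movies, model = model, grid = grid1,
          refine = TRUE, allow_negative = allow_negative, control = control)
}

# ---- prf_fit methods --------------------------------------------------------

#' @export
print.prf_fit <- function(x, ...) {
  n <- nrow(x$fits)
  usable <- sum(x$fits$variance_explained >= x$ve_floor, na.rm = TRUE)
  cat("<prf_fit> ", n, " voxels (", usable, " with variance explained >= ",
      x$ve_floor, ")", if (x$corrected) ", corrected series" else "",
      "\n", sep = "")
  cat("  runs:", paste(vapply(x$movies, function(m) m$protocol$name, ""),
                       collapse = " + "), "\n")
  cat("  median variance explained:",
      signif(stats::median(x$fits$variance_explained, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Summarise a pRF fit
#'
#' @param object a [fit_prf()] result.
#' @param ... unused.
#' @return a list with voxel counts, variance-explained quartiles and
#'   eccentricity/size summaries, printed compactly.
#' @export
summary.prf_fit <- function(object, ...) {
  f <- object$fits
  res <- list(
    n_voxels = nrow(f),
    n_degenerate = sum(f$degenerate),
    n_usable = sum(f$variance_explained >= object$ve_floor, na.rm = TRUE),
    ve = stats::quantile(f$variance_explained, c(0.25, 0.5, 0.75),
                         na.rm = TRUE),
    sigma = stats::quantile(f$sigma, c(0.25, 0.5, 0.75), na.rm = TRUE),
    eccentricity = stats::quantile(f$eccentricity, c(0.25, 0.5, 0.75),
                                   na.rm = TRUE),
    corrected = object$corrected)
  class(res) <- "summary.prf_fit"
  res
}

#' @export
print.summary.prf_fit <- function(x, ...) {
  cat("pRF fit of", x$n_voxels, "voxels",
      if (x$corrected) "(corrected series)" else "", "\n")
  cat("  degenerate:", x$n_degenerate, "; usable:", x$n_usable, "\n")
  cat("  variance explained (quartiles):",
      paste(signif(x$ve, 3), collapse = " / "), "\n")
  cat("  sigma (deg):", paste(signif(x$sigma, 3), collapse = " / "), "\n")
  cat("  eccentricity (deg):",
      paste(signif(x$eccentricity, 3), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.prf_fit <- function(object, ...) {
  as.matrix(object$fits[, c("x0", "y0", "sigma", "beta", "baseline")])
}

#' Predicted time courses from a pRF fit
#'
#' @param object a [fit_prf()] result.
#' @param voxels voxel indices (default all).
#' @param ... unused.
#' @return matrix (voxels x volumes) of model predictions.
#' @export
predict.prf_fit <- function(object, voxels = NULL, ...) {
  if (is.null(voxels)) voxels <- seq_len(nrow(object$fits))
  prep <- prf_prepare(object$movies, object$model)
  blocks <- run_blocks(prep$nvol)
  out <- matrix(NA_real_, length(voxels), sum(prep$nvol))
  for (i in seq_along(voxels)) {
    r <- object$fits[voxels[i], ]
    if (r$degenerate || is.na(r$x0)) next
    p <- prf_predict_raw(prep, r$x0, r$y0, r$sigma)
    pr <- r$beta * p
    for (b in seq_along(blocks))
      pr[blocks[[b]]] <- pr[blocks[[b]]] +
        object$baseline_runs[voxels[i], b]
    out[i, ] <- pr
  }
  out
}

#' @export
fitted.prf_fit <- function(object, ...) predict(object)

#' @export
residuals.prf_fit <- function(object, ...) object$series - predict(object)

#' Plot fitted pRF centres in the visual field
#'
#' Centres of voxels at or above the variance-explained floor, sized by
#' sigma, on the stimulated field disc.
#'
#' @param x a [fit_prf()] result.
#' @param ve_floor override the stored usability floor.
#' @param ... passed to [graphics::symbols()].
#' @export
plot.prf_fit <- function(x, ve_floor = x$ve_floor, ...) {
  f <- x$fits[!x$fits$degenerate &
                x$fits$variance_explained >= ve_floor, ]
  E <- max(vapply(x$movies, function(m) m$grid_extent, 1))
  graphics::plot(NA, xlim = c(-2 * E, 2 * E), ylim = c(-2 * E, 2 * E),
                 asp = 1, xlab = "x (deg)", ylab = "y (deg)")
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(E * cos(th), E * sin(th), lty = 2)
  if (nrow(f))
    graphics::symbols(f$x0, f$y0, circles = f$sigma, inches = FALSE,
                      add = TRUE, fg = grDevices::grey(0.3, 0.5), ...)
  invisible(x)
}

# ---- Fourier travelling-wave analysis ---------------------------------------

#' Fourier travelling-wave phase and coherence maps
#'
#' Discrete Fourier transform of each voxel time course; phase and coherence
#' are read at the stimulus frequency bin (`n_cycles` cycles per scan).
#' Coherence is the amplitude at the stimulus frequency divided by the
#' root-sum-square amplitude over all non-DC frequencies up to the Nyquist
#' bin. Phase follows the convention that a voxel responding as
#' `cos(2*pi*f*t - phi)` has phase `phi`, so later responses have larger
#' phase in `[0, 2*pi)`.
#'
#' For bowtie (double-wedge) runs the aperture stimulates each polar angle
#' twice per revolution, so the response frequency is *twice* the rotation
#' cycle count; pass `n_cycles = 2 * protocol$n_cycles` for those runs.
#'
#' @param series numeric matrix (voxels x volumes) or vector.
#' @param n_cycles stimulus frequency in cycles per scan; must be at least 1
#'   and below the Nyquist bin.
#' @return an object of class `phase_map`: list with numeric vectors `phase`
#'   (radians in `[0, 2*pi)`), `coherence` (in `[0, 1]`), `amplitude`, and
#'   the `stimulus_frequency`.
#' @export
fft_phase_map <- function(series, n_cycles) {
  if (!is.matrix(series)) series <- matrix(series, nrow = 1)
  Tn <- ncol(series)
  nyq <- floor(Tn / 2)
  if (n_cycles < 1 || n_cycles >= nyq)
    stop("n_cycles must lie in [1, ", nyq - 1, "] for ", Tn, " volumes")
  X <- stats::mvfft(t(series))
  bins <- 2:(nyq + 1)                 # non-DC up to Nyquist
  amps <- Mod(X[bins, , drop = FALSE])
  tot <- sqrt(colSums(amps^2))
  at <- X[n_cycles + 1, ]
  coh <- ifelse(tot > 0, Mod(at) / tot, 0)
  phase <- (-Arg(at)) %% (2 * pi)
  structure(list(phase = as.numeric(phase), coherence = as.numeric(coh),
                 amplitude = as.numeric(Mod(at)) / Tn * 2,
                 stimulus_frequency = n_cycles),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat("<phase_map>", length(x$phase), "voxels at",
      x$stimulus_frequency, "cycles/scan; median coherence",
      signif(stats::median(x$coherence), 3), "\n")
  invisible(x)
}
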