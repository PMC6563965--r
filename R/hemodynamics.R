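#' Canonical haemodynamic response model
#'
#' A double-gamma impulse response: a positive lobe peaking at `peak_delay`
#' seconds minus an undershoot lobe peaking at `undershoot_delay` seconds,
#' scaled by `undershoot_ratio`, sampled at `dt` over `kernel_length` seconds
#' and normalised to unit peak. Each lobe is the unit-peak gamma shape
#' `(t/p)^p * exp(p - t)`, which is zero at `t = 0` and peaks exactly at `p`.
#' The defaults (peak 5 s, undershoot 15 s, ratio 1/6, 32 s kernel, 0.1 s
#' sampling) reproduce the canonical 8 s on-grid peak of the block response
#' to a 4 s stimulus sampled at TR = 2 s.
#'
#' @param peak_delay time-to-peak of the positive lobe, seconds.
#' @param undershoot_delay time-to-peak of the undershoot lobe, seconds;
#'   must exceed `peak_delay`.
#' @param undershoot_ratio undershoot amplitude relative to the peak.
#' @param kernel_length kernel support in seconds.
#' @param dt sampling interval in seconds.
#' @return an object of class `hrf_model`.
#' @export
hrf_model <- function(peak_delay = 5, undershoot_delay = 15,
                      undershoot_ratio = 1 / 6, kernel_length = 32,
                      dt = 0.1) {
  if (dt <= 0) stop("dt must be positive")
  if (peak_delay <= 0 || undershoot_delay <= 0)
    stop("delays must be positive")
  if (peak_delay >= undershoot_delay)
    stop("peak_delay must be smaller than undershoot_delay")
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 undershoot_ratio = undershoot_ratio,
                 kernel_length = kernel_length, dt = dt),
            class = "hrf_model")
}

#' @export
print.hrf_model <- function(x, ...) {
  cat("<hrf_model> double-gamma: peak", x$peak_delay, "s, undershoot",
      x$undershoot_delay, "s (ratio", signif(x$undershoot_ratio, 3),
      "),", x$kernel_length, "s kernel @", x$dt, "s\n")
  invisible(x)
}

# internal: unit-peak gamma lobe, zero at and before t = 0
gamma_lobe <- function(t, p) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(p * log(t[pos] / p) + p - t[pos])
  out
}

#' Sample the HRF kernel
#'
#' @param model an [hrf_model()].
#' @return numeric vector: the kernel sampled at `model$dt` from 0 to
#'   `model$kernel_length`, normalised to unit peak, with the sampling grid
#'   in attribute `"time"`.
#' @export
hrf_kernel <- function(model = hrf_model()) {
  stopifnot(inherits(model, "hrf_model"))
  t <- seq(0, model$kernel_length, by = model$dt)
  k <- gamma_lobe(t, model$peak_delay) -
    model$undershoot_ratio * gamma_lobe(t, model$undershoot_delay)
  k <- k / max(k)
  attr(k, "time") <- t
  attr(k, "dt") <- model$dt
  k
}

#' Causal convolution of a stimulus boxcar with a sampled kernel
#'
#' Discrete causal linear convolution truncated to the boxcar length; both
#' inputs must share the sampling interval `dt`.
#'
#' @param boxcar 0/1 stimulus indicator sampled at `dt`.
#' @param kernel sampled kernel, e.g. from [hrf_kernel()].
#' @param dt sampling interval of `boxcar`; defaults to the kernel's own.
#' @return numeric vector, `length(boxcar)`.
#' @export
convolve_design <- function(boxcar, kernel, dt = attr(kernel, "dt")) {
  if (!all(boxcar %in% c(0, 1))) stop("boxcar must be 0/1")
  kdt <- attr(kernel, "dt")
  if (!is.null(kdt) && !is.null(dt) && !isTRUE(all.equal(dt, kdt)))
    stop("dt mismatch between boxcar (", dt, ") and kernel (", kdt, ")")
  n <- length(boxcar)
  full <- stats::convolve(boxcar, rev(as.numeric(kernel)), type = "open")
  full[seq_len(n)]
}

# internal: TR-grid block-response operator.  A series defined on the TR grid
# is implicitly a step function; convolving it with the kernel at fine dt and
# reading off the values at volume onsets is a causal Toeplitz filter whose
# taps are the response to a single TR-long block.  Convolving at TR
# resolution instead would shift block-response peaks earlier (6 s rather
# than the correct 8 s for the full-field timing), so all TR-grid
# convolutions in the package go through this operator.
tr_response_taps <- function(tr, model) {
  up <- tr / model$dt
  if (abs(up - round(up)) > 1e-8)
    stop("hrf dt (", model$dt, ") must divide the TR (", tr, ")")
  up <- as.integer(round(up))
  k <- as.numeric(hrf_kernel(model))
  x <- c(rep(1, up), numeric(length(k)))     # one TR of stimulation, padded
  full <- stats::convolve(x, rev(k), type = "open")[seq_along(x)]
  full[seq(1, length(x), by = up)]
}

# internal: convolve a TR-grid series (vector or voxel x volume matrix rows)
# with the HRF via the block-response taps
convolve_tr <- function(x, tr, model) {
  taps <- tr_response_taps(tr, model)
  one <- function(v) {
    n <- length(v)
    full <- stats::convolve(v, rev(taps), type = "open")
    full[seq_len(n)]
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

#' Reference haemodynamic waveform for the full-field control stimulus
#'
#' Convolves the 4 s ON / 16 s OFF full-field boxcar (on the retained-volume
#' TR grid) with the canonical HRF and removes the mean. Voxel time courses
#' are correlated against this waveform to classify positive versus inverted
#' responses; Pearson correlation is invariant to the zero-meaning, which is
#' kept for the stability of regression-style diagnostics.
#'
#' @param protocol a full-field [make_protocol()] object.
#' @param model an [hrf_model()].
#' @param zero_mean subtract the mean (default `TRUE`).
#' @return an object of class `reference_waveform`: numeric vector of length
#'   `n_retained(protocol)` with attributes `protocol_name`, `timestamps`
#'   and `zero_meaned`.
#' @export
reference_waveform <- function(protocol, model = hrf_model(),
                               zero_mean = TRUE) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (protocol$name != "fullfield")
    stop("the reference waveform is defined for the full-field control ",
         "stimulus only, not '", protocol$name, "'")
  nr <- n_retained(protocol)
  ts <- (seq_len(nr) - 1) * protocol$tr
  box <- as.numeric((ts %% protocol$cycle_period) < protocol$on_duration)
  w <- convolve_tr(box, protocol$tr, model)
  if (zero_mean) w <- w - mean(w)
  structure(w, protocol_name = protocol$name, timestamps = ts,
            zero_meaned = zero_mean, class = "reference_waveform")
}

#' Event-averaged impulse/block response of a voxel group
#'
#' Cuts each voxel's full-field time course into per-cycle epochs aligned to
#' stimulus (ON) onsets, converts to percent signal change about the voxel's
#' own run mean, and averages over cycles and then voxels. The standard error
#' is taken over voxels. `time_to_peak` is the argmax of the group mean on
#' the TR grid (meaningful for groups whose mean response is predominantly
#' positive; for inverted groups read the trough instead).
#'
#' @param series voxel x volume numeric matrix of retained volumes.
#' @param protocol the full-field [make_protocol()] object.
#' @param group voxel (row) indices to average; must be non-empty.
#' @param window epoch length in seconds; defaults to, and must not exceed,
#'   the cycle period.
#' @return an object of class `irf_estimate`: list with `time` (seconds from
#'   stimulus onset), `mean_response` and `sem` (percent signal change),
#'   `time_to_peak` (seconds) and `n_voxels`.
#' @export
event_average_irf <- function(series, protocol, group,
                              window = protocol$cycle_period) {
  stopifnot(is.matrix(series), inherits(protocol, "stim_protocol"))
  if (length(group) == 0) stop("voxel group is empty")
  if (protocol$name != "fullfield")
    stop("IRFs are extracted from the full-field control stimulus")
  if (window > protocol$cycle_period)
    stop("window (", window, " s) exceeds the cycle period (",
         protocol$cycle_period, " s)")
  nr <- ncol(series)
  per <- protocol$cycle_period / protocol$tr
  nw <- floor(window / protocol$tr)
  onsets <- seq(1, nr, by = per)
  onsets <- onsets[onsets + nw - 1 <= nr]
  sub <- series[group, , drop = FALSE]
  mu <- rowMeans(sub)
  if (any(mu == 0)) stop("voxel with zero mean signal: percent signal ",
                         "change undefined")
  psc <- 100 * sweep(sweep(sub, 1, mu, "-"), 1, mu, "/")
  # cycle-average per voxel
  epochs <- vapply(onsets, function(o) {
    psc[, o:(o + nw - 1), drop = FALSE]
  }, matrix(0, nrow(sub), nw))
  per_voxel <- apply(epochs, c(1, 2), mean)
  m <- colMeans(per_voxel)
  sem <- if (nrow(per_voxel) > 1)
    apply(per_voxel, 2, stats::sd) / sqrt(nrow(per_voxel))
  else rep(0, nw)
  tt <- (seq_len(nw) - 1) * protocol$tr
  structure(list(time = tt, mean_response = m, sem = sem,
                 time_to_peak = tt[which.max(m)],
                 n_voxels = length(group)),
            class = "irf_estimate")
}

#' @export
print.irf_estimate <- function(x, ...) {
  cat("<irf_estimate>", x$n_voxels, "voxels; time-to-peak",
      x$time_to_peak, "s; peak", signif(max(x$mean_response), 3),
      "% signal change\n")
  invisible(x)
}

#' @export
plot.irf_estimate <- function(x, ...) {
  graphics::plot(x$time, x$mean_response, type = "b", pch = 16,
                 xlab = "time from stimulus onset (s)",
                 ylab = "response (% signal change)", ...)
  graphics::arrows(x$time, x$mean_response - x$sem,
                   x$time, x$mean_response + x$sem,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
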