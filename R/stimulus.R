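#' Stimulus protocols for retinotopic mapping
#'
#' Constructs the timing of one of the four mapping stimuli used throughout
#' the package: a rotating double-wedge ("bowtie"), an expanding ring, an
#' eight-direction drifting bar with interleaved blanks, and a full-field
#' flash used as the haemodynamic control. All protocols run at TR = 2 s and
#' a maximum stimulus eccentricity of 5.5 degrees:
#'
#' * `bowtie`: 186 acquired volumes, first 6 discarded, 15 cycles (one full
#'   revolution per 24 s cycle).
#' * `ring`: 174 acquired volumes, first 6 discarded, 12 cycles (28 s cycle).
#' * `bar`: 200 acquired volumes, none discarded; 8 sweeps of 40 s (four
#'   orientations, 0/45/90/115 degrees, two directions each) with four 20 s
#'   blank blocks inserted after every second sweep.
#' * `fullfield`: 124 acquired volumes, first 4 discarded, 12 cycles of
#'   4 s ON / 16 s OFF.
#'
#' @param name one of `"bowtie"`, `"ring"`, `"bar"`, `"fullfield"`.
#' @return an object of class `stim_protocol`: a list with fields `name`,
#'   `tr`, `n_volumes_acquired`, `n_discard`, `n_cycles`, `cycle_period`,
#'   `max_eccentricity` and, where applicable, `on_duration`, `off_duration`,
#'   `bar_sweep_duration`, `bar_orientations`, `n_blanks`, `blank_duration`.
#' @seealso [render_apertures()], [discard_initial()]
#' @examples
#' p <- make_protocol("fullfield")
#' n_retained(p)  # 120
#' @export
make_protocol <- function(name) {
  valid <- c("bowtie", "ring", "bar", "fullfield")
  if (length(name) != 1L || !name %in% valid) {
    stop("unknown stimulus name ", deparse(name), "; valid names are: ",
         paste(valid, collapse = ", "))
  }
  tr <- 2
  p <- switch(name,
    bowtie = list(
      name = "bowtie", tr = tr, n_volumes_acquired = 186L, n_discard = 6L,
      n_cycles = 15L, cycle_period = 24
    ),
    ring = list(
      name = "ring", tr = tr, n_volumes_acquired = 174L, n_discard = 6L,
      n_cycles = 12L, cycle_period = 28
    ),
    bar = list(
      name = "bar", tr = tr, n_volumes_acquired = 200L, n_discard = 0L,
      n_cycles = NA_integer_, cycle_period = NA_real_,
      bar_sweep_duration = 40, bar_orientations = c(0, 45, 90, 115),
      n_blanks = 4L, blank_duration = 20
    ),
    fullfield = list(
      name = "fullfield", tr = tr, n_volumes_acquired = 124L, n_discard = 4L,
      n_cycles = 12L, cycle_period = 20, on_duration = 4, off_duration = 16
    )
  )
  p$max_eccentricity <- 5.5
  class(p) <- "stim_protocol"
  validate_protocol(p)
  p
}

#' Number of retained volumes of a protocol
#'
#' @param protocol a [make_protocol()] object.
#' @return integer count of volumes after discarding initial volumes.
#' @export
n_retained <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  protocol$n_volumes_acquired - protocol$n_discard
}

# internal: integer-arithmetic consistency of the published timing
validate_protocol <- function(p) {
  nr <- p$n_volumes_acquired - p$n_discard
  if (nr <= 0) stop("protocol retains no volumes")
  dur <- nr * p$tr
  if (p$name == "fullfield") {
    if (dur != p$n_cycles * (p$on_duration + p$off_duration))
      stop("fullfield timing inconsistent: ", dur, " s retained vs cycles")
  } else if (p$name == "bar") {
    sched <- 8 * p$bar_sweep_duration + p$n_blanks * p$blank_duration
    if (dur != sched) stop("bar timing inconsistent: ", dur, " vs ", sched)
  } else {
    if (dur != p$n_cycles * p$cycle_period)
      stop(p$name, " timing inconsistent: ", dur, " s vs ",
           p$n_cycles * p$cycle_period)
  }
  invisible(p)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>", x$name, "\n")
  cat("  TR:", x$tr, "s;", x$n_volumes_acquired, "volumes acquired,",
      x$n_discard, "discarded ->", n_retained(x), "retained\n")
  if (!is.na(x$cycle_period))
    cat("  cycles:", x$n_cycles, "x", x$cycle_period, "s\n")
  if (x$name == "bar")
    cat("  bar: 8 sweeps x", x$bar_sweep_duration,
        "s (orientations", paste(x$bar_orientations, collapse = "/"),
        "deg), 4 x", x$blank_duration, "s blanks\n")
  if (x$name == "fullfield")
    cat("  ON", x$on_duration, "s / OFF", x$off_duration, "s\n")
  cat("  max eccentricity:", x$max_eccentricity, "deg\n")
  invisible(x)
}

#' Render the binary aperture movie of a stimulus protocol
#'
#' Produces one binary visual-field frame per *retained* volume of the
#' protocol, on a square grid of pixel-centred samples spanning
#' +/- `max_eccentricity` degrees. Apertures are:
#' double 45-degree wedge rotating one full revolution per cycle (bowtie,
#' clockwise); annulus of width `duty * max_eccentricity` expanding from the
#' centre each cycle (ring); a bar of width 1/8 of the display sweeping each
#' of the eight directions in 40 s with blanks after every second sweep (bar);
#' and the full 5.5-degree disc during ON volumes (fullfield).
#'
#' @param protocol a [make_protocol()] object.
#' @param grid_samples number of samples per grid side (>= 16); default 101.
#' @param wedge_width bowtie wedge angular width in degrees (per wedge).
#' @param ring_duty ring annulus width as a fraction of max eccentricity.
#' @param bar_width_frac bar width as a fraction of the full display width.
#' @return an object of class `aperture_movie`: list with `frames` (a 3-D
#'   0/1 array `[volume, y, x]`), `degrees_per_sample`, `grid_extent`, `x`,
#'   `y` (sample-centre coordinates), `timestamps` (seconds, re-zeroed to the
#'   first retained volume) and the originating `protocol`.
#' @examples
#' mov <- render_apertures(make_protocol("fullfield"), grid_samples = 21)
#' sum(apply(mov$frames, 1, any))  # 24 ON frames
#' @export
render_apertures <- function(protocol, grid_samples = 101,
                             wedge_width = 45, ring_duty = 0.25,
                             bar_width_frac = 1 / 8) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (grid_samples < 16) stop("grid_samples must be at least 16")
  E <- protocol$max_eccentricity
  dps <- 2 * E / grid_samples
  thinnest <- switch(protocol$name,
    bar = bar_width_frac * 2 * E,
    ring = ring_duty * E,
    Inf)
  if (dps > thinnest / 2)
    stop("grid too coarse: ", signif(dps, 3), " deg/sample cannot represent ",
         "the thinnest aperture feature (", signif(thinnest, 3), " deg)")
  # pixel centres on a half-open extent
  cc <- -E + dps * (seq_len(grid_samples) - 0.5)
  X <- matrix(cc, grid_samples, grid_samples, byrow = TRUE)   # x along columns
  Y <- matrix(rev(cc), grid_samples, grid_samples)            # y up along rows
  ecc <- sqrt(X^2 + Y^2)
  ang <- field_angle(X, Y)
  disc <- ecc <= E

  nr <- n_retained(protocol)
  ts <- (seq_len(nr) - 1) * protocol$tr
  frames <- array(0L, dim = c(nr, grid_samples, grid_samples))

  if (protocol$name == "fullfield") {
    on <- (ts %% protocol$cycle_period) < protocol$on_duration
    for (i in which(on)) frames[i, , ] <- disc
  } else if (protocol$name == "bowtie") {
    for (i in seq_len(nr)) {
      phase <- (ts[i] %% protocol$cycle_period) / protocol$cycle_period
      centre <- (-360 * phase) %% 360   # clockwise rotation
      m <- disc & (ang_dist(ang, centre) <= wedge_width / 2 |
                   ang_dist(ang, (centre + 180) %% 360) <= wedge_width / 2)
      frames[i, , ] <- m
    }
  } else if (protocol$name == "ring") {
    w <- ring_duty * E
    for (i in seq_len(nr)) {
      phase <- (ts[i] %% protocol$cycle_period) / protocol$cycle_period
      inner <- phase * E
      frames[i, , ] <- disc & ecc >= inner & ecc <= inner + w
    }
  } else { # bar
    w <- bar_width_frac * 2 * E
    sweep_vols <- protocol$bar_sweep_duration / protocol$tr   # 20
    blank_vols <- protocol$blank_duration / protocol$tr       # 10
    # segment schedule: sweeps 1,2, blank, 3,4, blank, 5,6, blank, 7,8, blank
    seg_type <- c("s", "s", "b", "s", "s", "b", "s", "s", "b", "s", "s", "b")
    seg_len <- ifelse(seg_type == "s", sweep_vols, blank_vols)
    seg_end <- cumsum(seg_len)
    sweep_id <- 0L
    i <- 1L
    for (s in seq_along(seg_type)) {
      idx <- i:seg_end[s]
      if (seg_type[s] == "s") {
        sweep_id <- sweep_id + 1L
        ori <- protocol$bar_orientations[ceiling(sweep_id / 2)]
        dir <- if (sweep_id %% 2L == 1L) 1 else -1
        mu <- ori * pi / 180                       # motion axis from +x
        proj <- X * cos(mu) + Y * sin(mu)
        for (k in seq_along(idx)) {
          cpos <- dir * (-E + (k - 0.5) / sweep_vols * 2 * E)
          frames[idx[k], , ] <- disc & abs(proj - cpos) <= w / 2
        }
      }
      i <- seg_end[s] + 1L
    }
  }

  structure(list(
    frames = frames, degrees_per_sample = dps, grid_extent = E,
    x = cc, y = rev(cc), timestamps = ts, protocol = protocol
  ), class = "aperture_movie")
}

#' @export
print.aperture_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat("<aperture_movie>", x$protocol$name, ":", d[1], "frames of",
      d[2], "x", d[3], "samples (", signif(x$degrees_per_sample, 3),
      "deg/sample )\n")
  invisible(x)
}

#' Discard initial volumes from a time-indexed series
#'
#' Removes the first `n` time points of a vector (time along its length) or
#' matrix (voxels in rows, time in columns) and re-zeroes any `timestamps`
#' attribute to the first retained volume.
#'
#' @param series numeric vector or matrix with time as the last index.
#' @param n number of initial time points to drop (`0 <= n <` series length).
#' @return the trimmed series, same type as the input.
#' @examples
#' discard_initial(1:10, 4)
#' @export
discard_initial <- function(series, n) {
  len <- if (is.matrix(series)) ncol(series) else length(series)
  if (n < 0) stop("n must be non-negative")
  if (n >= len) stop("cannot discard ", n, " of ", len,
                     " volumes: nothing would remain")
  ts <- attr(series, "timestamps")
  out <- if (is.matrix(series)) series[, seq.int(n + 1L, len), drop = FALSE]
         else series[seq.int(n + 1L, len)]
  if (!is.null(ts)) {
    ts <- ts[seq.int(n + 1L, length(ts))]
    attr(out, "timestamps") <- ts - ts[1L]
  }
  out
}

#' Serialise / restore a stimulus protocol as a key-value text config
#'
#' @param protocol a [make_protocol()] object.
#' @param path file path to write to / read from.
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns a `stim_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  p <- yaml::read_yaml(path)
  ref <- make_protocol(p$name)
  for (f in names(p)) ref[[f]] <- p[[f]]
  validate_protocol(ref)
  ref
}
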