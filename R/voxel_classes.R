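#' Normalised mean (EPI brightness) map
#'
#' Voxel-wise time-average of the signal, divided by the maximum average, so
#' the brightest voxel is exactly 1. Venous eclipses appear as contiguous
#' low-intensity regions on this map.
#'
#' @param series numeric matrix, voxels x volumes, all finite.
#' @return an object of class `mean_map`: numeric vector of per-voxel values
#'   in `(0, 1]` with the normalising maximum in attribute
#'   `"normalising_max"`.
#' @export
normalized_mean_map <- function(series) {
  if (!is.matrix(series)) series <- matrix(series, nrow = 1)
  if (ncol(series) < 1) stop("series has no volumes")
  if (!all(is.finite(series))) stop("series contains non-finite values")
  m <- rowMeans(series)
  mx <- max(m)
  if (mx <= 0) stop("non-positive maximum mean intensity: not physical data")
  structure(m / mx, normalising_max = mx, class = "mean_map")
}

#' @export
print.mean_map <- function(x, ...) {
  cat("<mean_map>", length(x), "voxels; min",
      signif(min(x), 3), "of the maximum intensity (",
      signif(attr(x, "normalising_max"), 4), ")\n")
  invisible(x)
}

#' Correlate voxel time courses with the reference waveform
#'
#' Pearson correlation of each voxel against the HRF-convolved full-field
#' reference; voxels are labelled `positive` when `r >= 0` and `inverted`
#' when `r < 0` (the paper's sign-of-correlation rule; an exact zero — which
#' includes constant voxels — counts as positive and is flagged).
#'
#' @param series numeric matrix, voxels x volumes.
#' @param reference a [reference_waveform()] (or numeric vector of equal
#'   length).
#' @return an object of class `correlation_map`: list with numeric `r`,
#'   factor `label` (`positive`/`inverted`) and logical `flagged` for
#'   zero-variance voxels.
#' @export
correlate_reference <- function(series, reference) {
  if (!is.matrix(series)) series <- matrix(series, nrow = 1)
  ref <- as.numeric(reference)
  if (ncol(series) != length(ref))
    stop("series (", ncol(series), " volumes) and reference (",
         length(ref), ") lengths differ")
  sds <- apply(series, 1, stats::sd)
  flagged <- sds == 0
  r <- numeric(nrow(series))
  if (any(!flagged))
    r[!flagged] <- as.numeric(stats::cor(t(series[!flagged, , drop = FALSE]),
                                         ref))
  label <- factor(ifelse(r < 0, "inverted", "positive"),
                  levels = c("positive", "inverted"))
  structure(list(r = r, label = label, flagged = flagged),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("<correlation_map>", length(x$r), "voxels;",
      sum(x$label == "inverted"), "inverted (",
      signif(100 * mean(x$label == "inverted"), 3), "% )\n")
  invisible(x)
}

#' Flip negatively correlated time courses
#'
#' The inverted-voxel correction: every voxel whose correlation with the
#' reference is below `-threshold` has its time course reflected about its
#' own temporal mean (`y' = 2 * mean(y) - y`). This is the unique pointwise
#' correction that exactly negates the Pearson correlation while leaving the
#' voxel's mean — and hence the normalised mean map — untouched; applying it
#' twice restores the original series. With the default `threshold = 0`
#' every negatively correlated voxel is flipped; a threshold of 0.1
#' reproduces the conservative variant that only corrects correlations
#' stronger than -0.1.
#'
#' @param series numeric matrix, voxels x volumes.
#' @param cmap a [correlate_reference()] map for `series`.
#' @param threshold non-negative correlation magnitude; voxels with
#'   `r < -threshold` (strict) are flipped.
#' @return the corrected series, with the flipped voxel indices in
#'   attribute `"flipped"`.
#' @export
flip_timecourses <- function(series, cmap, threshold = 0) {
  if (!is.matrix(series)) series <- matrix(series, nrow = 1)
  stopifnot(inherits(cmap, "correlation_map"))
  if (threshold < 0) stop("threshold must be non-negative")
  if (length(cmap$r) != nrow(series))
    stop("correlation map does not match the series")
  idx <- which(cmap$r < -threshold)
  out <- series
  if (length(idx)) {
    mu <- rowMeans(series[idx, , drop = FALSE])
    out[idx, ] <- 2 * mu - series[idx, , drop = FALSE]
  }
  attr(out, "flipped") <- idx
  out
}

#' Detect venous-eclipse candidates on a mean map
#'
#' An automated surrogate for hand-drawn eclipse ROIs: voxels below the
#' given intensity quantile are grouped into 4-connected components on the
#' patch lattice, and components that are both large enough and elongated
#' enough (venous shadows are vessel-shaped) are returned as the ROI. An
#' empty ROI is a valid "absent" outcome.
#'
#' @param mmap a [normalized_mean_map()].
#' @param lattice integer `c(rows, cols)` of the patch lattice; voxels are
#'   taken in column-major order.
#' @param intensity_quantile quantile in (0, 1) defining "dark" voxels.
#' @param min_size minimum component size in voxels.
#' @param min_elongation minimum major/minor axis ratio (square root of the
#'   component coordinate covariance eigenvalue ratio; a straight line is
#'   infinitely elongated).
#' @param layer label recorded on the ROI (e.g. `"d2.5mm"`,
#'   `"integrated"`).
#' @return an object of class `eclipse_roi`: list with integer `voxels`,
#'   `provenance = "detected"`, `layer`, and the per-component table in
#'   `$components`.
#' @export
detect_eclipse <- function(mmap, lattice, intensity_quantile = 0.15,
                           min_size = 20, min_elongation = 2,
                           layer = "integrated") {
  if (intensity_quantile <= 0 || intensity_quantile >= 1)
    stop("intensity_quantile must lie in (0, 1)")
  v <- as.numeric(mmap)
  stopifnot(length(v) == prod(lattice))
  thr <- stats::quantile(v, intensity_quantile)
  dark <- v < thr
  lab <- label_components(dark, lattice[1], lattice[2])
  comps <- split(which(lab > 0), lab[lab > 0])
  keep <- integer(0)
  tab <- data.frame(size = integer(0), elongation = numeric(0),
                    kept = logical(0))
  for (cmp in comps) {
    rows <- (cmp - 1L) %% lattice[1] + 1L
    cols <- (cmp - 1L) %/% lattice[1] + 1L
    el <- component_elongation(rows, cols)
    kept <- length(cmp) >= min_size && el >= min_elongation
    tab <- rbind(tab, data.frame(size = length(cmp), elongation = el,
                                 kept = kept))
    if (kept) keep <- c(keep, cmp)
  }
  eclipse_roi(sort(keep), provenance = "detected", layer = layer,
              components = tab)
}

#' Construct a venous-eclipse region of interest
#'
#' @param voxels integer voxel indices (unique).
#' @param provenance `"manual"` (hand-drawn) or `"detected"`.
#' @param layer depth label: `"integrated"`, `"d2.5mm"`, `"d1mm"` or
#'   `"grey_white"`.
#' @param components optional per-component diagnostics table.
#' @return an object of class `eclipse_roi`.
#' @export
eclipse_roi <- function(voxels, provenance = c("manual", "detected"),
                        layer = "integrated", components = NULL) {
  provenance <- match.arg(provenance)
  voxels <- as.integer(voxels)
  if (anyDuplicated(voxels)) stop("ROI voxel indices must be unique")
  structure(list(voxels = voxels, provenance = provenance, layer = layer,
                 components = components),
            class = "eclipse_roi")
}

#' @export
print.eclipse_roi <- function(x, ...) {
  cat("<eclipse_roi>", if (length(x$voxels) == 0) "absent:" else "",
      length(x$voxels), "voxels (", x$provenance, ", layer", x$layer, ")\n")
  invisible(x)
}

# internal: 4-connected component labelling on a rows x cols lattice
label_components <- function(mask, nrow, ncol) {
  lab <- integer(length(mask))
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      r <- (cur - 1L) %% nrow + 1L
      cc <- (cur - 1L) %/% nrow + 1L
      nb <- c(if (r > 1L) cur - 1L, if (r < nrow) cur + 1L,
              if (cc > 1L) cur - nrow, if (cc < ncol) cur + nrow)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  lab
}

# internal: sqrt eigenvalue ratio of the component coordinate covariance
component_elongation <- function(rows, cols) {
  if (length(rows) < 2) return(1)
  cv <- stats::cov(cbind(rows, cols))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0) return(Inf)
  sqrt(ev[1] / ev[2])
}

#' Read / write an eclipse ROI as a plain text index list
#'
#' The format is a plain file of voxel indices, one per line, preceded by
#' `# provenance:` and `# layer:` header comments — hand-editable, and
#' stable for exchanging hand-drawn ROIs.
#'
#' @param roi an [eclipse_roi()].
#' @param path file path.
#' @return `write_eclipse_roi()` returns `path` invisibly;
#'   `read_eclipse_roi()` returns an `eclipse_roi`.
#' @export
write_eclipse_roi <- function(roi, path) {
  stopifnot(inherits(roi, "eclipse_roi"))
  writeLines(c(paste("# provenance:", roi$provenance),
               paste("# layer:", roi$layer),
               as.character(roi$voxels)), path)
  invisible(path)
}

#' @rdname write_eclipse_roi
#' @export
read_eclipse_roi <- function(path) {
  ln <- readLines(path)
  hdr <- grep("^#", ln, value = TRUE)
  val <- function(key, default) {
    h <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(h)) trimws(sub(".*:", "", h[1])) else default
  }
  eclipse_roi(as.integer(ln[!grepl("^#", ln) & nzchar(ln)]),
              provenance = val("provenance", "manual"),
              layer = val("layer", "integrated"))
}

#' Discriminate inverted voxels from negative BOLD responses
#'
#' Negatively correlated voxels *within* the stimulated eccentricity range
#' are inverted voxels (venous artefact); negatively correlated voxels
#' *beyond* it are negative BOLD responses (NBRs, neuronal suppression just
#' outside the stimulus). Positively correlated voxels are `positive`.
#'
#' @param cmap a [correlate_reference()] map.
#' @param eccentricity per-voxel eccentricity in degrees (ground truth or
#'   pRF fits); `NA` for a negatively correlated voxel makes it
#'   `unclassifiable`.
#' @param stim_max maximum stimulated eccentricity in degrees.
#' @return factor with levels `positive`, `inverted`, `NBR`,
#'   `unclassifiable`.
#' @export
classify_nbr_vs_inverted <- function(cmap, eccentricity, stim_max = 5.5) {
  stopifnot(inherits(cmap, "correlation_map"))
  if (length(eccentricity) != length(cmap$r))
    stop("eccentricity must be supplied for every voxel")
  neg <- cmap$r < 0
  out <- rep("positive", length(cmap$r))
  out[neg & !is.na(eccentricity) & eccentricity > stim_max] <- "NBR"
  out[neg & !is.na(eccentricity) & eccentricity <= stim_max] <- "inverted"
  out[neg & is.na(eccentricity)] <- "unclassifiable"
  factor(out, levels = c("positive", "inverted", "NBR", "unclassifiable"))
}

#' Percentage of inverted voxels per region
#'
#' @param cmap a [correlate_reference()] map.
#' @param regions named list of voxel index vectors (e.g. visual areas, or
#'   eclipse ROI vs. the rest, per depth layer).
#' @return data frame with `region`, `n_voxels`, `n_inverted`,
#'   `percent_inverted`.
#' @export
inverted_fraction_by_region <- function(cmap, regions) {
  stopifnot(inherits(cmap, "correlation_map"), is.list(regions))
  if (length(regions) == 0) stop("no regions supplied")
  if (any(lengths(regions) == 0)) stop("empty region: ",
    paste(names(regions)[lengths(regions) == 0], collapse = ", "))
  inv <- cmap$label == "inverted"
  data.frame(
    region = names(regions),
    n_voxels = lengths(regions),
    n_inverted = vapply(regions, function(i) sum(inv[i]), 1L),
    percent_inverted = vapply(regions, function(i) 100 * mean(inv[i]), 1),
    row.names = NULL)
}
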