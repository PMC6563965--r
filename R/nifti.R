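#' Load a masked 4-D NIfTI time series
#'
#' Extracts masked voxels from a 4-D functional image into a voxel x volume
#' matrix. Voxels are ordered by ascending linear index of the 3-D volume
#' with the first (x) dimension fastest — a stable, documented ordering, so
#' repeated loads and round-trips are reproducible. The repetition time is
#' read from the header; when it is absent or non-positive the `tr`
#' argument is used and a warning is raised.
#'
#' @param path path to a 4-D NIfTI image (or an array/`niftiImage`).
#' @param mask path to a 3-D mask image, or a logical/numeric array whose
#'   dimensions match the spatial dimensions of the series; at least one
#'   voxel must be selected.
#' @param tr fallback repetition time in seconds.
#' @return list with `series` (voxels x volumes matrix), `voxels` (linear
#'   indices into the volume), `dim` (spatial dimensions) and `tr`.
#' @export
load_nifti_series <- function(path, mask, tr = 2) {
  img <- if (is.character(path)) RNifti::readNifti(path) else path
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4-D image, got ", length(d), "-D")
  m <- if (is.character(mask)) RNifti::readNifti(mask) else mask
  m <- array(as.logical(m), dim = dim(m))
  if (!identical(as.integer(dim(m)), as.integer(d[1:3])))
    stop("mask dimensions (", paste(dim(m), collapse = "x"),
         ") do not match the series (", paste(d[1:3], collapse = "x"), ")")
  idx <- which(m)
  if (length(idx) == 0) stop("mask selects no voxels")
  hdr_tr <- if (inherits(img, "niftiImage"))
    tryCatch(RNifti::pixdim(img)[4], error = function(e) NA_real_)
  else NA_real_   # a bare array carries no header

  if (is.na(hdr_tr) || hdr_tr <= 0) {
    warning("TR absent from header; using configured TR = ", tr, " s")
  } else {
    tr <- hdr_tr
  }
  vol <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  list(series = vol[idx, , drop = FALSE], voxels = idx, dim = d[1:3],
       tr = tr)
}

#' Write a voxel x volume series back into a 4-D NIfTI image
#'
#' Inverse of [load_nifti_series()] for synthetic data: places the rows of
#' `series` at `voxels` linear indices of a `dim` volume (zero elsewhere)
#' and writes a 4-D image with the given TR.
#'
#' @param series voxels x volumes matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param dim spatial dimensions, e.g. `c(30, 30, 1)`.
#' @param voxels linear indices; default all voxels in order.
#' @param tr repetition time in seconds.
#' @return `path`, invisibly.
#' @export
write_nifti_series <- function(series, path, dim, voxels = NULL, tr = 2) {
  if (is.null(voxels)) voxels <- seq_len(prod(dim))
  stopifnot(length(voxels) == nrow(series))
  vol <- array(0, c(prod(dim), ncol(series)))
  vol[voxels, ] <- series
  arr <- array(vol, c(dim, ncol(series)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}
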