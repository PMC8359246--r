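#' Create a volume: a 3D numeric array with voxel spacing in mm
#'
#' Volumes are plain 3D arrays carrying a `spacing` attribute (mm per voxel
#' along each axis). The centre of voxel `[i, j, k]` sits at physical
#' coordinate `((i-1)*s1, (j-1)*s2, (k-1)*s3)` mm.
#'
#' @param data numeric array or vector of length `prod(dim)`
#' @param dim integer length-3 dimensions (taken from `data` if an array)
#' @param spacing numeric length-3 voxel spacing in mm
#' @return a 3D array of class `knee_volume`
#' @export
as_volume <- function(data, dim = base::dim(data), spacing = c(1, 1, 1)) {
  if (is.null(dim) || length(dim) != 3L)
    stop("volume must be three-dimensional")
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  v <- array(as.numeric(data), dim = dim)
  attr(v, "spacing") <- as.numeric(spacing)
  class(v) <- c("knee_volume", class(v))
  v
}

#' Voxel spacing of a volume (mm)
#' @param v a volume
#' @return numeric length-3 spacing
#' @export
spacing <- function(v) {
  s <- attr(v, "spacing")
  if (is.null(s)) rep(1, 3) else s
}

#' @export
print.knee_volume <- function(x, ...) {
  cat(sprintf("<knee_volume> %d x %d x %d, spacing %s mm, range [%g, %g]\n",
              dim(x)[1], dim(x)[2], dim(x)[3],
              paste(signif(spacing(x), 4), collapse = " x "),
              min(x), max(x)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(dim(a), dim(b)) && all(abs(spacing(a) - spacing(b)) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid: %s/%s vs %s/%s", what,
                 paste(dim(a), collapse = "x"),
                 paste(signif(spacing(a), 4), collapse = "x"),
                 paste(dim(b), collapse = "x"),
                 paste(signif(spacing(b), 4), collapse = "x")))
  invisible(TRUE)
}

#' Physical coordinates (mm) of all voxels, or of a logical mask's voxels
#' @param v a volume (used for dim and spacing)
#' @param mask optional logical array; if given, only TRUE voxels are returned
#' @return matrix with columns x, y, z in mm
#' @export
voxel_coordinates <- function(v, mask = NULL) {
  d <- dim(v); s <- spacing(v)
  if (is.null(mask)) {
    idx <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
                 rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                 rep(seq_len(d[3]), each = d[1] * d[2]))
  } else {
    idx <- which(array(mask, d), arr.ind = TRUE)
  }
  cbind(x = (idx[, 1] - 1) * s[1],
        y = (idx[, 2] - 1) * s[2],
        z = (idx[, 3] - 1) * s[3])
}

#' Euclidean distance transform (mm) to the nearest TRUE voxel
#'
#' Anisotropy-aware: distances are computed in physical mm using the volume's
#' spacing, so thick-slice acquisitions are handled correctly.
#'
#' @param mask logical 3D array (with optional spacing attribute)
#' @param spacing voxel spacing in mm
#' @return volume of distances (mm); `Inf`-like large values if mask is empty
#' @export
distance_transform <- function(mask, spacing = attr(mask, "spacing")) {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  d2 <- edt_sq_cpp(as.logical(mask), dim(mask), spacing)
  as_volume(sqrt(d2), dim(mask), spacing)
}

#' Gaussian smoothing of a volume
#' @param v volume
#' @param sigma_mm standard deviation in mm (scalar or length 3)
#' @return smoothed volume
#' @export
smooth_volume <- function(v, sigma_mm) {
  s <- spacing(v)
  sigma_vox <- rep(sigma_mm, length.out = 3) / s
  as_volume(gauss_smooth_cpp(as.numeric(v), dim(v), sigma_vox), dim(v), s)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving the spacing attribute.
#' @param path file path (.nii or .nii.gz)
#' @return `read_volume`: a volume; `write_volume`: the path, invisibly
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  as_volume(as.array(img), spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param v volume to write
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(array(as.numeric(v), dim(v)))
  RNifti::pixdim(img) <- spacing(v)
  RNifti::writeNifti(img, path)
  invisible(path)
}
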