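#' SUV volume container
#'
#' A 3-D grid of standardised-uptake-value (SUV) voxels with physical voxel
#' spacing, the basic image object consumed by every delineation method.
#' Axis order is fixed as (x, y, z); the centre of voxel `(i, j, k)` (1-based
#' array indices) sits at `origin + (c(i, j, k) - 0.5) * spacing` in mm.
#'
#' @param values numeric 3-D array of SUV values; must be finite and >= 0.
#' @param spacing numeric length-3 voxel spacing (dx, dy, dz) in mm, all > 0.
#' @param origin numeric length-3 physical coordinate (mm) of the grid corner.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(values, spacing = c(5.3, 5.3, 2.0), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (any(!is.finite(values)) || any(values < 0))
    stop("SUV values must be finite and non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<suv_volume> %d x %d x %d voxels, spacing (%.2f, %.2f, %.2f) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  SUV range [%.3f, %.3f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.suv_volume <- function(x) dim(x$values)

#' Physical coordinates of voxel centres along one axis
#' @param vol an `suv_volume`
#' @param axis axis index 1..3
#' @return numeric vector of centre coordinates in mm
#' @keywords internal
voxel_centers <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$values)[axis]) - 0.5) * vol$spacing[axis]
}

#' Voxel volume in cm^3
#' @param spacing length-3 spacing in mm
#' @keywords internal
voxel_cm3 <- function(spacing) prod(spacing) / 1000

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Separable 3-D Gaussian smoothing
#'
#' Convolves a 3-D array with an isotropic (in mm) Gaussian point-spread
#' function, applied as three separable 1-D passes with a normalised discrete
#' kernel and replicated (clamped) edges, so the filter never increases the
#' array maximum.
#'
#' @param values numeric 3-D array.
#' @param fwhm_mm full width at half maximum of the PSF in mm; 0 is a no-op.
#' @param spacing voxel spacing (mm) per axis.
#' @return smoothed array of the same dimensions.
#' @export
gaussian_blur3d <- function(values, fwhm_mm, spacing) {
  if (fwhm_mm < 0) stop("PSF FWHM must be >= 0")
  if (fwhm_mm == 0) return(values)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / spacing
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    values <- convolve_axis(values, w, axis)
  }
  values
}

# 1-D convolution along `axis` with clamped (replicate) boundary handling,
# implemented as a banded-matrix product so the inner loop runs in BLAS.
# Kernel w has odd length 2r+1 centred at r+1.
convolve_axis <- function(a, w, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(w) - 1L) / 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in seq_along(w)) {
    j <- pmin(pmax(i + (k - r - 1L), 1L), n)
    ij <- cbind(i, j)
    K[ij] <- K[ij] + w[k]
  }
  if (axis == 1L) {
    out <- K %*% matrix(a, n, prod(d[-1]))
    dim(out) <- d
    return(out)
  }
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(a, perm)
  out <- K %*% matrix(x, n, prod(d[-axis]))
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

#' Convert a voxel count or lesion mask to a volume in cm^3
#'
#' @param mask a `lesion_mask`, a logical/numeric array, or a voxel count.
#' @param spacing voxel spacing (mm); taken from the mask if it carries one.
#' @return volume in cm^3 (`count * dx*dy*dz / 1000`).
#' @export
mask_volume_cm3 <- function(mask, spacing = NULL) {
  if (inherits(mask, "lesion_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    n <- mask$n_voxels
  } else if (is.array(mask) || is.logical(mask)) {
    n <- sum(mask != 0)
  } else {
    n <- as.numeric(mask)
  }
  if (is.null(spacing)) stop("voxel `spacing` required")
  n * voxel_cm3(spacing)
}

#' Write / read an SUV volume as NIfTI-1
#'
#' Spacing is carried in the NIfTI `pixdim` header; the origin in the
#' sform/qform offset.
#'
#' @param vol an `suv_volume`
#' @param path output `.nii` or `.nii.gz` path
#' @return `write_suv_nifti` returns `path` invisibly; `read_suv_nifti`
#'   returns an `suv_volume`.
#' @export
write_suv_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_suv_nifti
#' @param path path of a NIfTI file written by [write_suv_nifti()]
#' @export
read_suv_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  suv_volume(array(as.numeric(img), dim = dim(img)),
             spacing = RNifti::pixdim(img)[1:3])
}

# run expr under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic child seeds below 2^31 derived from a master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
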