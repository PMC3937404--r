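# Separable filtering and the scale-normalized LoG scale-space.

# Convolve an n-D array along one axis with an odd-length kernel,
# half-sample symmetric (mirror) boundaries. Axis 1 is the fastest path;
# other axes are brought to the front with aperm.
convolveAxis <- function(a, kernel, axis) {
  d <- dim(a)
  nd <- length(d)
  if (axis < 1 || axis > nd) stop("bad axis")
  perm <- c(axis, setdiff(seq_len(nd), axis))
  ap <- if (axis == 1) a else aperm(a, perm)
  m <- conv_axis1_reflect(matrix(ap, d[axis], prod(d[-axis])), kernel)
  dim(m) <- d[perm]
  if (axis == 1) m else aperm(m, order(perm))
}

# Sampled Gaussian kernel, truncated at 4 sigma, normalized to sum 1.
gaussianKernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-h):h
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable Gaussian smoothing with per-axis std. dev. in voxel units.
# A zero entry skips that axis.
gaussianSmoothArray <- function(a, sigma_vox) {
  for (ax in seq_along(sigma_vox)) {
    if (sigma_vox[ax] > 0)
      a <- convolveAxis(a, gaussianKernel(sigma_vox[ax]), ax)
  }
  a
}

#' Build the discrete LoG scale set
#'
#' Arithmetic progression `sigma_min, sigma_min + step, ...` up to
#' `sigma_max`; `sigma_max` is appended if the progression does not hit it
#' exactly. The triplet notation matches the usual parameter tables, e.g.
#' `(8, 11, 1)` gives `{8, 9, 10, 11}` and `(6, 9, 3)` gives `{6, 9}`.
#'
#' @param sigma_min,sigma_max,sigma_step scale range and step (physical
#'   units), `0 < sigma_min <= sigma_max`, `sigma_step > 0`.
#' @return Strictly increasing numeric vector of scales.
#' @examples
#' buildScales(8, 11, 1)
#' buildScales(6, 9, 3)
#' @export
buildScales <- function(sigma_min, sigma_max, sigma_step) {
  stopifnot(sigma_min > 0, sigma_min <= sigma_max, sigma_step > 0)
  s <- seq(sigma_min, sigma_max, by = sigma_step)
  if (sigma_max - s[length(s)] > 1e-9) s <- c(s, sigma_max)
  s
}

#' Physical blob radius corresponding to a LoG scale
#'
#' The scale-normalized LoG response at the centre of a solid bright blob of
#' radius `r` peaks at `sigma = r / sqrt(ndim)`, so the radius estimate for a
#' selected scale is `sigma * sqrt(ndim)` (`sigma * sqrt(2)` in 2D,
#' `sigma * sqrt(3)` in 3D).
#'
#' @param sigma scale (physical units), > 0.
#' @param ndim image dimensionality, 2 or 3.
#' @return Physical radius estimate.
#' @examples
#' radiusFromScale(3, 2)  # 3 * sqrt(2)
#' radiusFromScale(3, 3)  # 3 * sqrt(3)
#' @export
radiusFromScale <- function(sigma, ndim) {
  stopifnot(all(sigma > 0), ndim %in% c(2, 3))
  sigma * sqrt(ndim)
}

#' Scale-normalized Laplacian-of-Gaussian filter
#'
#' Smooths the image with an isotropic-in-physical-space Gaussian of std.
#' dev. `sigma` (per-axis voxel std. dev. `sigma / spacing`), applies the
#' discrete Laplacian (central second differences scaled by `1/spacing^2`),
#' negates, and multiplies by `sigma^2` so responses are comparable across
#' scales. Bright blobs therefore produce positive maxima. Boundaries are
#' mirrored; Gaussian kernels are truncated at 4 sigma.
#'
#' @param volume a [Volume-class].
#' @param sigma scale in physical units; the effective voxel-space std. dev.
#'   `sigma / spacing` must be at least 0.3 on every axis.
#' @return A [Volume-class] of LoG responses (same shape and spacing).
#' @examples
#' v <- Volume(matrix(5, 16, 16))
#' range(imageData(logFilter(v, 2)))  # exactly 0 on a constant image
#' @export
logFilter <- function(volume, sigma) {
  stopifnot(is(volume, "Volume"), length(sigma) == 1, sigma > 0)
  sp <- volume@spacing
  s_vox <- sigma / sp
  if (any(s_vox < 0.3))
    stop(sprintf(
      "sigma %g gives voxel-space std. dev. below 0.3 on axis %d; filter unresolvable",
      sigma, which.min(s_vox)))
  sm <- gaussianSmoothArray(volume@data, s_vox)
  lap <- 0
  for (ax in seq_along(sp))
    lap <- lap + convolveAxis(sm, c(1, -2, 1) / sp[ax]^2, ax)
  Volume(-sigma^2 * lap, sp)
}

#' LoG scale-space maximum intensity projection
#'
#' Computes [logFilter()] responses for each scale in turn and keeps, per
#' voxel, the maximum response and the scale that attained it (the first
#' scale wins ties). The scan is iterative, so at most the running maximum
#' and one response volume are resident at a time.
#'
#' @param volume a [Volume-class].
#' @param scales strictly increasing numeric vector of scales (see
#'   [buildScales()]).
#' @return A [ScaleSpaceResult-class].
#' @export
scaleSpaceMIP <- function(volume, scales) {
  stopifnot(is(volume, "Volume"), length(scales) >= 1)
  if (is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly increasing")
  mip <- imageData(logFilter(volume, scales[1]))
  smap <- array(scales[1], dim(mip))
  for (s in scales[-1]) {
    r <- imageData(logFilter(volume, s))
    upd <- r > mip          # strict: earlier scale wins ties
    mip[upd] <- r[upd]
    smap[upd] <- s
  }
  new("ScaleSpaceResult", mip = Volume(mip, volume@spacing),
      scaleMap = Volume(smap, volume@spacing), scales = as.numeric(scales))
}
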