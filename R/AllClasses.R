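#' @useDynLib twangseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Volume: an n-dimensional intensity image with physical voxel spacing
#'
#' The universal image container of the package. `data` is a 2D or 3D numeric
#' array (axis order `(y, x)` in 2D and `(z, y, x)` in 3D); `spacing` gives the
#' physical size of one voxel along each axis, in the same order, e.g.
#' micrometres per voxel. Intensities are held as doubles regardless of the
#' bit depth they were read from, because all downstream transforms are
#' real-valued. Non-finite intensities are rejected.
#'
#' Voxel indices are 1-based throughout the package (R convention); the
#' physical coordinate of voxel `i` along an axis is `(i - 1) * spacing`.
#'
#' @slot data numeric array of intensities.
#' @slot spacing numeric vector, one strictly positive entry per axis.
#' @aliases Volume-class
#' @exportClass Volume
setClass("Volume", representation(data = "array", spacing = "numeric"))

setValidity("Volume", function(object) {
  d <- dim(object@data)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    return("data must be a 2D or 3D array")
  if (length(object@spacing) != length(d))
    return("spacing must have one entry per image axis")
  if (!all(is.finite(object@spacing)) || any(object@spacing <= 0))
    return("spacing entries must be finite and > 0")
  if (anyNA(object@data) || !all(is.finite(object@data)))
    return("image data contains non-finite values (NaN/Inf rejected)")
  TRUE
})

#' Construct a Volume
#'
#' @param data 2D or 3D numeric array (a matrix counts as 2D).
#' @param spacing per-axis physical voxel size; defaults to unit spacing.
#' @return A [Volume-class] object.
#' @examples
#' v <- Volume(matrix(0, 8, 8), spacing = c(0.5, 0.5))
#' spacing(v)
#' @export
Volume <- function(data, spacing = rep(1, length(dim(data)))) {
  if (is.null(dim(data))) stop("data must be an array or matrix")
  storage.mode(data) <- "double"
  new("Volume", data = data, spacing = as.numeric(spacing))
}

#' LabelImage: an integer label map with physical voxel spacing
#'
#' Holds a segmentation or ground-truth labeling. Value 0 is background; each
#' positive integer denotes one segment. Axis conventions match
#' [Volume-class].
#'
#' @slot labels integer array, non-negative.
#' @slot spacing numeric vector as in [Volume-class].
#' @aliases LabelImage-class
#' @exportClass LabelImage
setClass("LabelImage", representation(labels = "array", spacing = "numeric"))

setValidity("LabelImage", function(object) {
  d <- dim(object@labels)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    return("labels must be a 2D or 3D array")
  if (length(object@spacing) != length(d))
    return("spacing must have one entry per axis")
  if (!all(is.finite(object@spacing)) || any(object@spacing <= 0))
    return("spacing entries must be finite and > 0")
  if (anyNA(object@labels) || any(object@labels < 0))
    return("labels must be non-negative and finite")
  TRUE
})

#' Construct a LabelImage
#'
#' @param labels 2D/3D array of non-negative integer labels (0 = background).
#' @param spacing per-axis physical voxel size; defaults to unit spacing.
#' @return A [LabelImage-class] object.
#' @export
LabelImage <- function(labels, spacing = rep(1, length(dim(labels)))) {
  if (is.null(dim(labels))) stop("labels must be an array or matrix")
  storage.mode(labels) <- "integer"
  new("LabelImage", labels = labels, spacing = as.numeric(spacing))
}

#' ScaleSpaceResult: LoG scale-space maximum intensity projection
#'
#' Result of [scaleSpaceMIP()]: per-voxel maximum of the scale-normalized LoG
#' responses over a discrete scale set (`mip`), the scale attaining that
#' maximum at each voxel (`scaleMap`, first scale wins ties) and the ordered
#' scale set used.
#'
#' @slot mip [Volume-class] of maximum LoG responses.
#' @slot scaleMap [Volume-class] whose values are elements of `scales`.
#' @slot scales numeric, strictly increasing.
#' @aliases ScaleSpaceResult-class
#' @exportClass ScaleSpaceResult
setClass("ScaleSpaceResult",
         representation(mip = "Volume", scaleMap = "Volume",
                        scales = "numeric"))

setValidity("ScaleSpaceResult", function(object) {
  if (!identical(dim(object@mip@data), dim(object@scaleMap@data)))
    return("mip and scaleMap must have identical shape")
  if (length(object@scales) < 1 || is.unsorted(object@scales, strictly = TRUE))
    return("scales must be non-empty and strictly increasing")
  if (!all(object@scaleMap@data %in% object@scales))
    return("every scaleMap value must be an element of scales")
  TRUE
})

#' TwangParams: algorithm parameters
#'
#' Bundles the tunable parameters of seed detection and per-seed
#' segmentation. Defaults correspond to the 3D light-sheet setting
#' (`sigma` 6 to 9 in steps of 3, gradient smoothing 3.0, kernel multiplier
#' 1.5, kernel standard deviation 3.0). All sigma-like values are physical
#' units (equal to voxels under unit spacing).
#'
#' @slot sigma_min,sigma_max,sigma_step LoG scale range and step.
#' @slot gradient_sigma std. dev. of the Gaussian used before the gradient.
#' @slot kernel_multiplier plateau scaling `m` of the distance kernel.
#' @slot kernel_sigma std. dev. of the Gaussian tail of the distance kernel.
#' @slot seed_intensity_threshold minimum MIP response for a seed.
#' @slot fusion_distance maximum separation (physical) below which two seed
#'   candidates are fused; `NA` means `radiusFromScale(sigma_min, ndim)`.
#' @slot connectivity neighborhood size for maxima/labeling (8 or 26);
#'   `NA` selects 8 for 2D and 26 for 3D input.
#' @aliases TwangParams-class
#' @exportClass TwangParams
setClass("TwangParams",
         representation(sigma_min = "numeric", sigma_max = "numeric",
                        sigma_step = "numeric", gradient_sigma = "numeric",
                        kernel_multiplier = "numeric", kernel_sigma = "numeric",
                        seed_intensity_threshold = "numeric",
                        fusion_distance = "numeric",
                        connectivity = "integer"))

setValidity("TwangParams", function(object) {
  if (object@sigma_min <= 0 || object@sigma_max <= 0 ||
      object@sigma_min > object@sigma_max)
    return("need 0 < sigma_min <= sigma_max")
  if (object@sigma_step <= 0) return("sigma_step must be > 0")
  if (object@gradient_sigma <= 0) return("gradient_sigma must be > 0")
  if (object@kernel_multiplier <= 0) return("kernel_multiplier must be > 0")
  if (object@kernel_sigma <= 0) return("kernel_sigma must be > 0")
  if (!is.na(object@fusion_distance) && object@fusion_distance < 0)
    return("fusion_distance must be >= 0")
  if (!is.na(object@connectivity) && !(object@connectivity %in% c(8L, 26L)))
    return("connectivity must be 8 or 26")
  TRUE
})

#' Construct TwangParams
#'
#' @param sigma_min,sigma_max,sigma_step LoG scale range (physical units).
#' @param gradient_sigma Gaussian std. dev. for gradient smoothing.
#' @param kernel_multiplier plateau multiplier `m` of the distance kernel.
#' @param kernel_sigma Gaussian std. dev. of the distance-kernel tail.
#' @param seed_intensity_threshold minimum MIP response for a seed.
#' @param fusion_distance physical fusion distance for close maxima
#'   (`NA` = radius at `sigma_min`).
#' @param connectivity 8 or 26; `NA` = full connectivity for the input ndim.
#' @return A [TwangParams-class] object.
#' @examples
#' twangParams()                       # 3D light-sheet defaults
#' twangParams(sigma_min = 8, sigma_max = 11, sigma_step = 1)  # 2D benchmark
#' @export
twangParams <- function(sigma_min = 6, sigma_max = 9, sigma_step = 3,
                        gradient_sigma = 3.0, kernel_multiplier = 1.5,
                        kernel_sigma = 3.0, seed_intensity_threshold = 0,
                        fusion_distance = NA_real_,
                        connectivity = NA_integer_) {
  new("TwangParams", sigma_min = as.numeric(sigma_min),
      sigma_max = as.numeric(sigma_max), sigma_step = as.numeric(sigma_step),
      gradient_sigma = as.numeric(gradient_sigma),
      kernel_multiplier = as.numeric(kernel_multiplier),
      kernel_sigma = as.numeric(kernel_sigma),
      seed_intensity_threshold = as.numeric(seed_intensity_threshold),
      fusion_distance = as.numeric(fusion_distance),
      connectivity = as.integer(connectivity))
}

#' CropRegion: a per-seed sub-volume
#'
#' Cropped raw intensities around one seed. `offset` is the 1-based voxel
#' index of the crop origin in the full image; `seed_local` the seed position
#' in crop coordinates, so `offset + seed_local - 1` is the seed in the full
#' frame.
#'
#' @slot data numeric sub-array of raw intensities.
#' @slot offset integer crop origin (1-based, full-image frame).
#' @slot seed_local integer seed position within the crop (1-based).
#' @slot spacing inherited per-axis physical spacing.
#' @aliases CropRegion-class
#' @exportClass CropRegion
setClass("CropRegion",
         representation(data = "array", offset = "integer",
                        seed_local = "integer", spacing = "numeric"))

setValidity("CropRegion", function(object) {
  d <- dim(object@data)
  if (length(object@offset) != length(d) ||
      length(object@seed_local) != length(d) ||
      length(object@spacing) != length(d))
    return("offset, seed_local and spacing must have one entry per axis")
  if (any(object@seed_local < 1) || any(object@seed_local > d))
    return("seed_local must lie inside the crop")
  if (any(object@offset < 1)) return("offset must be >= 1")
  TRUE
})

#' SegmentCandidate: one seed's segmentation result
#'
#' Binary mask and region properties extracted for a single seed. The mask is
#' a connected component containing (or nearest to) the seed; properties are
#' computed from the raw intensities under the mask. Coordinates are reported
#' both as voxel indices (1-based, full-image frame, `bbox`) and physical
#' units (`centroid`, `(index - 1) * spacing`).
#'
#' @slot seed_id integer seed identifier.
#' @slot seed_pos integer seed position (1-based, full-image frame).
#' @slot offset integer crop origin (1-based, full-image frame).
#' @slot mask logical sub-array, a single connected component.
#' @slot otsu_threshold numeric threshold applied to the combined image.
#' @slot centroid numeric physical centroid.
#' @slot volume_voxels integer voxel count of the mask.
#' @slot volume_physical numeric, `volume_voxels * prod(spacing)`.
#' @slot mean_intensity numeric mean raw intensity over the mask.
#' @slot bbox 2 x ndim matrix of min/max voxel indices (full-image frame).
#' @aliases SegmentCandidate-class
#' @exportClass SegmentCandidate
setClass("SegmentCandidate",
         representation(seed_id = "integer", seed_pos = "integer",
                        offset = "integer", mask = "array",
                        otsu_threshold = "numeric", centroid = "numeric",
                        volume_voxels = "integer", volume_physical = "numeric",
                        mean_intensity = "numeric", bbox = "matrix"))

#' PhantomSpec: synthetic nuclei phantom parameters
#'
#' Describes a clustered-nuclei phantom. Defaults emulate the character of
#' the simulated 3D HL60 benchmark (roundish nuclei, clustering probability
#' 0.75, low signal-to-noise ratio) at desk scale.
#'
#' @slot shape integer image dimensions (`(z, y, x)` in 3D, `(y, x)` in 2D).
#' @slot spacing per-axis physical voxel size.
#' @slot n_nuclei number of nuclei to place.
#' @slot radius_range min/max physical nucleus radius.
#' @slot clustering_probability fraction of nuclei placed touching/nearly
#'   touching an existing nucleus (centre distance 0.8 to 1.2 times the sum of
#'   radii); the rest are isolated (distance > 1.5 times the sum of radii).
#' @slot intensity_fg,intensity_bg peak foreground and background intensity.
#' @slot intensity_falloff fraction by which a nucleus dims from centre to
#'   rim (quadratic radial profile, `1 - falloff * (d/r)^2`); nuclei are
#'   brighter centrally, which is what makes the seam between touching
#'   nuclei visible. 0 gives uniformly filled spheres.
#' @slot psf_sigma Gaussian blur std. dev. (physical units) emulating the PSF.
#' @slot noise_sigma additive Gaussian noise std. dev.
#' @slot poisson_scale if > 0, Poisson resampling `rpois(x*scale)/scale`
#'   applied after blurring (shot noise); 0 disables it.
#' @slot rng_seed integer seed; phantoms are bit-reproducible from it.
#' @slot max_attempts placement attempts per nucleus before giving up.
#' @aliases PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(shape = "integer", spacing = "numeric",
                        n_nuclei = "integer", radius_range = "numeric",
                        clustering_probability = "numeric",
                        intensity_fg = "numeric", intensity_bg = "numeric",
                        intensity_falloff = "numeric",
                        psf_sigma = "numeric", noise_sigma = "numeric",
                        poisson_scale = "numeric", rng_seed = "integer",
                        max_attempts = "integer"))

setValidity("PhantomSpec", function(object) {
  if (!(length(object@shape) %in% c(2L, 3L)) || any(object@shape < 1))
    return("shape must be 2 or 3 positive extents")
  if (length(object@spacing) != length(object@shape) ||
      any(object@spacing <= 0))
    return("spacing must match shape and be > 0")
  if (object@n_nuclei < 0) return("n_nuclei must be >= 0")
  if (length(object@radius_range) != 2 ||
      object@radius_range[1] > object@radius_range[2] ||
      object@radius_range[1] <= 0)
    return("radius_range must be positive with min <= max")
  if (object@clustering_probability < 0 || object@clustering_probability > 1)
    return("clustering_probability must be in [0, 1]")
  if (object@intensity_fg <= object@intensity_bg || object@intensity_bg < 0)
    return("need intensity_fg > intensity_bg >= 0")
  if (object@intensity_falloff < 0 || object@intensity_falloff >= 1)
    return("intensity_falloff must be in [0, 1)")
  if (object@psf_sigma < 0 || object@noise_sigma < 0 ||
      object@poisson_scale < 0)
    return("psf_sigma, noise_sigma and poisson_scale must be >= 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param shape,spacing,n_nuclei,radius_range,clustering_probability,intensity_fg,intensity_bg,intensity_falloff,psf_sigma,noise_sigma,poisson_scale,rng_seed,max_attempts
#'   see [PhantomSpec-class].
#' @return A [PhantomSpec-class] object.
#' @examples
#' phantomSpec(shape = c(32, 64, 64), n_nuclei = 5, rng_seed = 1)
#' @export
phantomSpec <- function(shape = c(64L, 128L, 128L), spacing = rep(1, length(shape)),
                        n_nuclei = 30, radius_range = c(5, 8),
                        clustering_probability = 0.75,
                        intensity_fg = 200, intensity_bg = 20,
                        intensity_falloff = 0.25,
                        psf_sigma = 1.5, noise_sigma = 15,
                        poisson_scale = 0, rng_seed = 42L,
                        max_attempts = 10000L) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      n_nuclei = as.integer(n_nuclei), radius_range = as.numeric(radius_range),
      clustering_probability = as.numeric(clustering_probability),
      intensity_fg = as.numeric(intensity_fg),
      intensity_bg = as.numeric(intensity_bg),
      intensity_falloff = as.numeric(intensity_falloff),
      psf_sigma = as.numeric(psf_sigma), noise_sigma = as.numeric(noise_sigma),
      poisson_scale = as.numeric(poisson_scale),
      rng_seed = as.integer(rng_seed), max_attempts = as.integer(max_attempts))
}

#' PhantomTruth: ground truth accompanying a phantom
#'
#' @slot labels [LabelImage-class] of pre-blur nucleus geometry.
#' @slot centroids n x ndim matrix of physical nucleus centres.
#' @slot radii numeric physical radii.
#' @slot snr measured signal-to-noise ratio of the generated image:
#'   (mean in-object intensity - mean background) / background std. dev.
#' @aliases PhantomTruth-class
#' @exportClass PhantomTruth
setClass("PhantomTruth",
         representation(labels = "LabelImage", centroids = "matrix",
                        radii = "numeric", snr = "numeric"))

#' EvaluationReport: segmentation quality criteria for one image pair
#'
#' Per-image summary of the comparison between a reference and a candidate
#' label image: Rand index (percent), pair-based Jaccard index (ratio, not
#' upper-bounded), Hausdorff metric (physical distance, mean over matched
#' object pairs), normalized sum of distances (ratio between 0 and 1, also reported
#' times 10), and object-level error counts.
#'
#' @slot rand_index percentage between 0 and 100.
#' @slot jaccard_index agreeing/disagreeing pair ratio; `Inf` when the two
#'   labelings agree on every pair.
#' @slot hausdorff mean symmetric Hausdorff distance over matched pairs.
#' @slot nsd normalized sum of distances between 0 and 1; `nsd_x10` is 10 * nsd.
#' @slot nsd_x10 see `nsd`.
#' @slot n_split,n_merged,n_added,n_missing object-level error counts.
#' @slot n_reference,n_segmented object counts in the two inputs.
#' @aliases EvaluationReport-class
#' @exportClass EvaluationReport
setClass("EvaluationReport",
         representation(rand_index = "numeric", jaccard_index = "numeric",
                        hausdorff = "numeric", nsd = "numeric",
                        nsd_x10 = "numeric", n_split = "integer",
                        n_merged = "integer", n_added = "integer",
                        n_missing = "integer", n_reference = "integer",
                        n_segmented = "integer"))
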