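#' Accessors for image containers
#'
#' `imageData()` returns the raw array of a [Volume-class], the label array of
#' a [LabelImage-class] or the data of a [CropRegion-class]; `spacing()`
#' returns the per-axis physical voxel size.
#'
#' @param object a container object.
#' @return An array (`imageData`) or numeric vector (`spacing`).
#' @examples
#' v <- Volume(matrix(1:9, 3, 3), spacing = c(2, 1))
#' dim(imageData(v)); spacing(v)
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname imageData
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname imageData
#' @export
setMethod("imageData", "Volume", function(object) object@data)

#' @rdname imageData
#' @export
setMethod("imageData", "LabelImage", function(object) object@labels)

#' @rdname imageData
#' @export
setMethod("imageData", "CropRegion", function(object) object@data)

#' @rdname imageData
#' @export
setMethod("spacing", "Volume", function(object) object@spacing)

#' @rdname imageData
#' @export
setMethod("spacing", "LabelImage", function(object) object@spacing)

#' @rdname imageData
#' @export
setMethod("spacing", "CropRegion", function(object) object@spacing)

setMethod("show", "Volume", function(object) {
  cat(sprintf("Volume: %s voxels, spacing (%s)\n",
              paste(dim(object@data), collapse = " x "),
              paste(format(object@spacing), collapse = ", ")))
  r <- range(object@data)
  cat(sprintf("  intensity range [%g, %g]\n", r[1], r[2]))
})

setMethod("show", "LabelImage", function(object) {
  labs <- unique(as.vector(object@labels))
  cat(sprintf("LabelImage: %s voxels, %d segment(s), spacing (%s)\n",
              paste(dim(object@labels), collapse = " x "),
              sum(labs > 0),
              paste(format(object@spacing), collapse = ", ")))
})

setMethod("show", "ScaleSpaceResult", function(object) {
  cat(sprintf("ScaleSpaceResult: %s voxels, scales {%s}\n",
              paste(dim(object@mip@data), collapse = " x "),
              paste(format(object@scales), collapse = ", ")))
})

setMethod("show", "TwangParams", function(object) {
  cat("TwangParams:\n")
  cat(sprintf("  LoG scales: %g to %g, step %g\n",
              object@sigma_min, object@sigma_max, object@sigma_step))
  cat(sprintf("  gradient_sigma %g, kernel_multiplier %g, kernel_sigma %g\n",
              object@gradient_sigma, object@kernel_multiplier,
              object@kernel_sigma))
  cat(sprintf("  seed_intensity_threshold %g, fusion_distance %s, connectivity %s\n",
              object@seed_intensity_threshold,
              ifelse(is.na(object@fusion_distance), "auto",
                     format(object@fusion_distance)),
              ifelse(is.na(object@connectivity), "auto",
                     format(object@connectivity))))
})

setMethod("show", "SegmentCandidate", function(object) {
  cat(sprintf("SegmentCandidate: seed %d, %d voxels, mean intensity %.2f, Otsu %.3f\n",
              object@seed_id, object@volume_voxels, object@mean_intensity,
              object@otsu_threshold))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d nuclei, measured SNR %.2f\n",
              nrow(object@centroids), object@snr))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:\n")
  cat(sprintf("  Rand index       %8.3f %%\n", object@rand_index))
  cat(sprintf("  Jaccard index    %8.3f\n", object@jaccard_index))
  cat(sprintf("  Hausdorff        %8.3f\n", object@hausdorff))
  cat(sprintf("  NSD (x10)        %8.4f (%.4f)\n", object@nsd, object@nsd_x10))
  cat(sprintf("  split %d  merged %d  added %d  missing %d  (reference %d, segmented %d)\n",
              object@n_split, object@n_merged, object@n_added,
              object@n_missing, object@n_reference, object@n_segmented))
})

#' Convert an EvaluationReport to a one-row data.frame
#'
#' @param x an [EvaluationReport-class].
#' @param row.names,optional,... passed for generic compatibility; unused.
#' @return A one-row `data.frame` with the report columns.
#' @export
as.data.frame.EvaluationReport <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(rand_index = x@rand_index, jaccard_index = x@jaccard_index,
             hausdorff = x@hausdorff, nsd = x@nsd, nsd_x10 = x@nsd_x10,
             n_split = x@n_split, n_merged = x@n_merged, n_added = x@n_added,
             n_missing = x@n_missing, n_reference = x@n_reference,
             n_segmented = x@n_segmented)
}
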