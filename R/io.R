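# TIFF and CSV input/output.
#
# Axis conventions (used verbatim by every reader/writer here): arrays are
# (y, x) in 2D and (z, y, x) in 3D, voxel indices are 1-based, physical
# coordinates are (index - 1) * spacing.

#' Read a volume from a single- or multi-page TIFF
#'
#' Pages become z-slices of a 3D array in `(z, y, x)` order; a single page
#' yields a 2D `(y, x)` volume. Integer data (8/16-bit) are read at native
#' intensity range, float TIFFs as stored. Spacing precedence: explicit
#' `spacing_override`, then TIFF x/y resolution metadata (z falls back to 1),
#' then unit spacing with a warning. Images containing NaN or Inf are
#' rejected.
#'
#' @param path TIFF file path.
#' @param spacing_override optional per-axis physical spacing (axis order as
#'   above).
#' @return A [Volume-class].
#' @export
readVolume <- function(path, spacing_override = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e) stop("cannot read TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits > 16) {
    # float samples: as.is reinterprets the bit pattern, so use the plain read
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p   # collapse RGB-ish channels
  })
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent page shapes in '", path, "'")
  if (length(pages) == 1) {
    data <- pages[[1]]
  } else {
    data <- aperm(array(unlist(pages), c(shp, length(pages))), c(3, 1, 2))
  }
  nd <- length(dim(data))
  if (anyNA(data) || !all(is.finite(data)))
    stop("image '", path, "' contains non-finite values")
  sp <- NULL
  if (!is.null(spacing_override)) {
    sp <- as.numeric(spacing_override)
    if (length(sp) != nd) stop("spacing_override must have ", nd, " entries")
  } else {
    xres <- attr(pages[[1]], "x.resolution")
    yres <- attr(pages[[1]], "y.resolution")
    if (!is.null(xres) && !is.null(yres) && xres > 0 && yres > 0) {
      sp <- if (nd == 3) c(1, 1 / yres, 1 / xres) else c(1 / yres, 1 / xres)
    } else {
      sp <- rep(1, nd)
      warning("no spacing metadata in '", path, "'; assuming unit spacing")
    }
  }
  Volume(data, sp)
}

#' Write a label image as a 16-bit multi-page TIFF
#'
#' @param labels a [LabelImage-class]; at most 65535 labels.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeLabelImage <- function(labels, path) {
  stopifnot(is(labels, "LabelImage"))
  mx <- max(labels@labels)
  if (mx > 65535) stop("label overflow: ", mx, " labels exceed 16-bit range")
  a <- labels@labels / 65535
  nd <- length(dim(a))
  pages <- if (nd == 2) list(a) else lapply(seq_len(dim(a)[1]),
                                            function(z) a[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a volume as a 16-bit unsigned TIFF
#'
#' Intensities are rounded to the nearest integer and must fall into the
#' 16-bit range 0..65535 (the standard dynamic range of microscopy
#' acquisitions); 3D volumes become multi-page TIFFs, one page per z-slice.
#' Integer-valued volumes round-trip bit-exactly through
#' [readVolume()].
#'
#' @param volume a [Volume-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "Volume"))
  a <- round(volume@data)
  if (min(a) < 0 || max(a) > 65535)
    stop("intensities outside the 16-bit range 0..65535 cannot be written")
  a <- a / 65535
  nd <- length(dim(a))
  pages <- if (nd == 2) list(a) else lapply(seq_len(dim(a)[1]),
                                            function(z) a[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write and read seed tables
#'
#' Seed CSVs have one header row and columns `id`, one voxel-index column per
#' axis (1-based), `scale`, `radius`, `response`.
#'
#' @param seeds seed `data.frame` from [detectSeeds()].
#' @param path CSV path.
#' @return `writeSeedsCSV` invisibly returns `path`; `readSeedsCSV` returns
#'   the seed `data.frame`.
#' @export
writeSeedsCSV <- function(seeds, path) {
  utils::write.csv(seeds, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSeedsCSV
#' @export
readSeedsCSV <- function(path) {
  utils::read.csv(path)
}

#' Write region properties of segments
#'
#' One row per surviving segment: `id`, physical centroid per axis, voxel and
#' physical volume, mean raw intensity, bounding box min/max per axis
#' (1-based voxel indices) and the per-crop Otsu threshold.
#'
#' @param segments list from [segmentAll()] (`NULL` entries are skipped).
#' @param path CSV path.
#' @param ndim image dimensionality (used to name axis columns when the
#'   segment list is empty); inferred from the first segment otherwise.
#' @return Invisibly, `path`.
#' @export
writeRegionpropsCSV <- function(segments, path, ndim = 3) {
  segs <- Filter(Negate(is.null), segments)
  if (length(segs) > 0) ndim <- length(segs[[1]]@centroid)
  ax <- axisNames(ndim)
  cols <- c("id", paste0("centroid_", ax), "volume_voxels", "volume_physical",
            "mean_intensity", paste0("bbox_min_", ax), paste0("bbox_max_", ax),
            "otsu_threshold")
  rows <- lapply(segs, function(s) {
    as.data.frame(as.list(stats::setNames(
      c(s@seed_id, s@centroid, s@volume_voxels, s@volume_physical,
        s@mean_intensity, s@bbox["min", ], s@bbox["max", ], s@otsu_threshold),
      cols)))
  })
  df <- if (length(rows) == 0) {
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  } else {
    do.call(rbind, rows)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a label image from TIFF
#'
#' Inverse of [writeLabelImage()]: 16-bit pages are mapped back to integer
#' labels.
#'
#' @param path TIFF path.
#' @param spacing_override optional per-axis spacing.
#' @return A [LabelImage-class].
#' @export
readLabelImage <- function(path, spacing_override = NULL) {
  v <- suppressWarnings(readVolume(path, spacing_override))
  LabelImage(round(imageData(v)), spacing(v))
}
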