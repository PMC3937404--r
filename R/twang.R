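# Per-seed segmentation: crop, smoothed gradient, seed-normal field,
# gradient/normal dot-product transform, plateau-Gaussian weighting,
# combination with raw intensities, Otsu threshold, property extraction.

#' Crop a region around a seed
#'
#' The crop half-width along axis `a` is `ceiling(2 * radius / spacing[a])`
#' voxels, i.e. a cuboid with side length four times the seed's radius in
#' physical units, clamped to the image bounds. This guarantees the Gaussian
#' tail of the distance kernel (plateau multiplier up to 1.5) lies materially
#' inside the crop.
#'
#' @param volume a [Volume-class].
#' @param seed a one-row seed `data.frame` (see [detectSeeds()]) or a list
#'   with voxel-index entries per axis and a `radius`.
#' @return A [CropRegion-class].
#' @export
cropRegion <- function(volume, seed) {
  stopifnot(is(volume, "Volume"))
  d <- dim(volume@data)
  nd <- length(d)
  pos <- as.integer(unlist(seed[axisNames(nd)]))
  if (any(pos < 1) || any(pos > d)) stop("seed lies outside the image")
  hw <- as.integer(ceiling(2 * seed$radius / volume@spacing))
  lo <- pmax(1L, pos - hw)
  hi <- pmin(d, pos + hw)
  idx <- lapply(seq_len(nd), function(a) lo[a]:hi[a])
  sub <- do.call(`[`, c(list(volume@data), idx, list(drop = FALSE)))
  new("CropRegion", data = sub, offset = lo,
      seed_local = pos - lo + 1L, spacing = volume@spacing)
}

#' Gaussian-smoothed intensity gradient of a crop
#'
#' Smooths the crop with a physically isotropic Gaussian of std. dev.
#' `gradient_sigma` and takes central differences scaled by `1/spacing` per
#' axis, so the gradient vectors live in physical space (intensity per
#' physical unit). One-sided differences are used at the crop faces.
#'
#' @param crop a [CropRegion-class].
#' @param gradient_sigma Gaussian std. dev. in physical units (default 3.0).
#' @return A list with one numeric array per axis, the gradient components.
#' @export
smoothedGradient <- function(crop, gradient_sigma = 3.0) {
  stopifnot(is(crop, "CropRegion"), gradient_sigma > 0)
  sm <- gaussianSmoothArray(crop@data, gradient_sigma / crop@spacing)
  lapply(seq_along(crop@spacing), function(ax)
    centralDifference(sm, ax, crop@spacing[ax]))
}

# Central difference along one axis, one-sided at the ends, physical scaling.
centralDifference <- function(a, axis, spacing) {
  d <- dim(a)
  n <- d[axis]
  fwd <- shiftArray(a, replace(rep(0L, length(d)), axis, 1L), fill = NA)
  bwd <- shiftArray(a, replace(rep(0L, length(d)), axis, -1L), fill = NA)
  g <- (fwd - bwd) / (2 * spacing)
  if (n >= 2) {
    idxEdge <- function(i, val) {
      idx <- lapply(d, seq_len)
      idx[[axis]] <- i
      do.call(`[<-`, c(list(g), idx, list(value = val)))
    }
    first <- slice(a, axis, 1L); second <- slice(a, axis, 2L)
    last <- slice(a, axis, n); prev <- slice(a, axis, n - 1L)
    g <- idxEdge(1L, (second - first) / spacing)
    g <- idxEdge(n, (last - prev) / spacing)
  } else {
    g[] <- 0
  }
  g
}

# Extract a slab at index i along an axis (kept as an array slab).
slice <- function(a, axis, i) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- i
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Seed-normal field of a crop
#'
#' For each voxel `x` the displacement from the seed is the Hadamard product
#' of the voxel offset with the spacing, `d(x) = (x - s) * spacing`; the
#' normal is the unit vector `d(x)/||d(x)||`, pointing from the seed to the
#' voxel. At the seed voxel itself the normal is undefined and stored as the
#' zero vector (it lies inside the copy-through radius and never influences
#' the result).
#'
#' @param crop a [CropRegion-class].
#' @return A list with `normals` (list of per-axis arrays) and `dist` (array
#'   of physical distances `||d(x)||`).
#' @export
seedNormalField <- function(crop) {
  stopifnot(is(crop, "CropRegion"))
  d <- dim(crop@data)
  nd <- length(d)
  comp <- vector("list", nd)
  dist2 <- 0
  for (ax in seq_len(nd)) {
    idx <- seq_len(d[ax]) - crop@seed_local[ax]
    profile <- idx * crop@spacing[ax]
    comp[[ax]] <- array(profile[broadcastIndex(d, ax)], d)
    dist2 <- dist2 + comp[[ax]]^2
  }
  dist <- sqrt(dist2)
  normals <- lapply(comp, function(cc) {
    n <- cc / dist
    n[dist == 0] <- 0
    n
  })
  list(normals = normals, dist = dist)
}

# Index vector replicating a 1-D profile along `axis` across an array of
# dims d (column-major broadcasting).
broadcastIndex <- function(d, axis) {
  nd <- length(d)
  reps_inner <- prod(d[seq_len(axis - 1)])
  reps_outer <- prod(d[seq_len(nd) > axis])
  rep(rep(seq_len(d[axis]), each = reps_inner), times = reps_outer)
}

#' Gradient/seed-normal dot-product transform
#'
#' Computes `psi(x) = (1 - <n(x), g(x)/||g(x)||>) / 2`, mapping gradients
#' anti-parallel to the outward seed normal (the boundary of the seed's own
#' bright nucleus, where gradients point back toward the seed) to 1,
#' perpendicular configurations to 0.5, and parallel gradients (the near edge
#' of a neighbouring nucleus) to 0. The measure is contrast invariant:
#' rescaling intensities by any positive gain leaves it unchanged. Voxels
#' with zero gradient or zero normal score the neutral value 0.5.
#'
#' @param normals the `normals` list from [seedNormalField()].
#' @param gradients the gradient list from [smoothedGradient()].
#' @return A numeric array with values in `[0, 1]`.
#' @export
dotProductTransform <- function(normals, gradients) {
  stopifnot(length(normals) == length(gradients))
  gnorm2 <- 0
  for (g in gradients) gnorm2 <- gnorm2 + g^2
  gnorm <- sqrt(gnorm2)
  dotp <- 0
  for (ax in seq_along(normals)) dotp <- dotp + normals[[ax]] * gradients[[ax]]
  cosv <- dotp / gnorm
  psi <- (1 - cosv) / 2
  psi[gnorm == 0] <- 0.5
  # zero normals (the seed voxel) give dotp 0, hence psi 0.5 already
  psi
}

#' Plateau-Gaussian distance weighting kernel
#'
#' `w(x) = 1` for `||d(x)|| <= m * radius` and
#' `exp(-(||d(x)|| - m*radius)^2 / (2*kernel_sigma^2))` beyond, so the
#' region likely to belong to the nucleus of interest keeps full weight and
#' remote intensities are attenuated smoothly.
#'
#' @param dist array of physical distances to the seed (see
#'   [seedNormalField()]).
#' @param radius seed radius estimate (physical units).
#' @param kernel_multiplier plateau multiplier `m` (default 1.5).
#' @param kernel_sigma Gaussian std. dev. of the tail (default 3.0).
#' @return A numeric array with values in `(0, 1]`.
#' @export
weightingKernel <- function(dist, radius, kernel_multiplier = 1.5,
                            kernel_sigma = 3.0) {
  stopifnot(radius > 0, kernel_multiplier > 0, kernel_sigma > 0)
  excess <- pmax(dist - kernel_multiplier * radius, 0)
  exp(-excess^2 / (2 * kernel_sigma^2))
}

#' Combine raw intensities with the weighted dot-product image
#'
#' Inside the seed radius the raw intensities are copied through unchanged;
#' outside, they are multiplied by the weighted dot product `w * psi`. The
#' result is the image handed to Otsu's method.
#'
#' @param crop a [CropRegion-class].
#' @param psi array from [dotProductTransform()].
#' @param w array from [weightingKernel()].
#' @param seed_radius copy-through radius (physical units).
#' @return A numeric array, same shape as the crop.
#' @export
combineImages <- function(crop, psi, w, seed_radius) {
  stopifnot(is(crop, "CropRegion"))
  dist <- seedNormalField(crop)$dist
  out <- crop@data * w * psi
  inside <- dist <= seed_radius
  out[inside] <- crop@data[inside]
  out
}

#' Otsu's threshold on a 256-bin histogram
#'
#' Bins the values into 256 equal-width bins spanning their range and returns
#' the bin boundary maximizing the between-class variance (the first boundary
#' in case of ties). Foreground is defined as `values > threshold`. A
#' constant input is degenerate: the threshold equals that value and the
#' foreground is empty.
#'
#' @param values numeric array or vector, non-empty.
#' @return A list with `threshold` (numeric) and `degenerate` (logical).
#' @export
otsuThreshold <- function(values) {
  x <- as.vector(values)
  stopifnot(length(x) > 0)
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(list(threshold = lo, degenerate = TRUE))
  nb <- 256L
  bin <- pmin(nb - 1L, as.integer(floor((x - lo) / (hi - lo) * nb)))
  counts <- tabulate(bin + 1L, nb)
  edges <- seq(lo, hi, length.out = nb + 1)
  mids <- (edges[-1] + edges[-(nb + 1)]) / 2
  n <- length(x)
  cw <- cumsum(counts)
  cmu <- cumsum(counts * mids)
  mu <- cmu[nb]
  w0 <- cw[-nb] / n
  w1 <- 1 - w0
  m0 <- cmu[-nb] / cw[-nb]
  m1 <- (mu - cmu[-nb]) / (n - cw[-nb])
  bcv <- w0 * w1 * (m0 - m1)^2
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)                      # first maximum wins
  list(threshold = edges[k + 1], degenerate = FALSE)
}

#' Extract the segment of one seed
#'
#' Binarizes the combined image at its Otsu threshold and keeps the connected
#' component (full connectivity) containing the seed voxel; if the seed voxel
#' itself falls below the threshold, the nearest foreground voxel within the
#' seed radius is used as the component anchor. Region properties are
#' computed from the raw intensities under the mask and mapped to the
#' full-image frame.
#'
#' @param combined array from [combineImages()].
#' @param crop the [CropRegion-class] the combined image was derived from.
#' @param seed one-row seed `data.frame` (needs `id`, position, `radius`).
#' @param params a [TwangParams-class] (connectivity is always full).
#' @return A [SegmentCandidate-class], or a lightweight `"twangDiscarded"`
#'   marker (a list with element `reason`: `"degenerate"`,
#'   `"empty-foreground"` or `"off-component"`) when no segment can be
#'   anchored at this seed.
#' @export
extractSegment <- function(combined, crop, seed, params = twangParams()) {
  stopifnot(is(crop, "CropRegion"))
  ot <- otsuThreshold(combined)
  if (ot$degenerate) return(discarded("degenerate"))
  fg <- combined > ot$threshold
  if (!any(fg)) return(discarded("empty-foreground"))
  nd <- length(dim(fg))
  anchor <- crop@seed_local
  if (!fg[matrix(anchor, 1)]) {
    dist <- seedNormalField(crop)$dist
    cand <- which(fg & dist <= seed$radius)
    if (length(cand) == 0) return(discarded("off-component"))
    dists <- dist[cand]
    cc <- arrayInd(cand, dim(fg))
    ord <- do.call(order, c(list(dists),
                            lapply(seq_len(nd), function(a) cc[, a])))
    anchor <- cc[ord[1], ]
  }
  mask <- floodFillComponent(fg, anchor)
  vox <- which(mask)
  coords <- arrayInd(vox, dim(mask))
  global <- sweep(coords, 2, crop@offset - 1L, `+`)
  phys <- physCoords(global, crop@spacing)
  raw <- crop@data[vox]
  new("SegmentCandidate",
      seed_id = as.integer(seed$id),
      seed_pos = as.integer(crop@offset + crop@seed_local - 1L),
      offset = crop@offset, mask = mask,
      otsu_threshold = ot$threshold,
      centroid = colMeans(phys),
      volume_voxels = length(vox),
      volume_physical = length(vox) * prod(crop@spacing),
      mean_intensity = mean(raw),
      bbox = rbind(min = apply(global, 2, min), max = apply(global, 2, max)))
}

discarded <- function(reason) {
  structure(list(reason = reason), class = "twangDiscarded")
}

#' Segment all seeds of an image
#'
#' Runs the per-seed pipeline (crop, smoothed gradient, seed-normal field,
#' dot-product transform, distance weighting, combination, Otsu threshold,
#' component extraction) independently for every seed. Seeds are distributed
#' over `workers` processes with `parallel::mclapply`; because each seed's
#' computation is deterministic and isolated, the result is bit-identical for
#' any worker count. A failing seed yields `NULL` (with a reason) and does
#' not abort the batch.
#'
#' @param volume a [Volume-class].
#' @param seeds seed `data.frame` from [detectSeeds()] (or user-supplied with
#'   the same columns).
#' @param params a [TwangParams-class].
#' @param workers number of worker processes (forked; serial on Windows).
#' @return A list with one [SegmentCandidate-class] or `NULL` per seed, in
#'   seed order; the attribute `discarded` is a `data.frame` of seed ids and
#'   reason codes for the `NULL` entries.
#' @export
segmentAll <- function(volume, seeds, params = twangParams(), workers = 1L) {
  stopifnot(is(volume, "Volume"), is.data.frame(seeds))
  one <- function(i) {
    seed <- seeds[i, , drop = FALSE]
    tryCatch({
      crop <- cropRegion(volume, seed)
      grad <- smoothedGradient(crop, params@gradient_sigma)
      nf <- seedNormalField(crop)
      psi <- dotProductTransform(nf$normals, grad)
      w <- weightingKernel(nf$dist, seed$radius, params@kernel_multiplier,
                           params@kernel_sigma)
      combined <- combineImages(crop, psi, w, seed$radius)
      extractSegment(combined, crop, seed, params)
    }, error = function(e) discarded(conditionMessage(e)))
  }
  n <- nrow(seeds)
  res <- if (workers > 1 && .Platform$OS.type != "windows") {
    parallel::mclapply(seq_len(n), one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n), one)
  }
  bad <- vapply(res, inherits, logical(1), what = "twangDiscarded")
  reasons <- data.frame(
    id = seeds$id[bad],
    reason = vapply(res[bad], function(r) r$reason, character(1)))
  res[bad] <- list(NULL)
  attr(res, "discarded") <- reasons
  res
}


#' Assemble a label image from per-seed segments
#'
#' Paints each segment's mask with its seed id. Where two masks overlap, the
#' voxel is assigned to the seed with the smaller physical distance to that
#' voxel (ties to the smaller seed id), so every labeled region maps to
#' exactly one seed and no merged segments can arise by construction.
#'
#' @param segments list from [segmentAll()] (`NULL` entries are skipped).
#' @param shape integer dimensions of the full image.
#' @param spacing per-axis physical voxel size.
#' @return A [LabelImage-class].
#' @export
assembleLabelImage <- function(segments, shape, spacing) {
  lab <- array(0L, shape)
  best <- array(Inf, shape)
  segs <- Filter(Negate(is.null), segments)
  ord <- order(vapply(segs, function(s) s@seed_id, integer(1)))
  for (s in segs[ord]) {
    vox <- which(s@mask)
    coords <- sweep(arrayInd(vox, dim(s@mask)), 2, s@offset - 1L, `+`)
    lin <- coordsToLinear(coords, shape)
    dd <- sqrt(rowSums(sweep(coords, 2, s@seed_pos, `-`)^2 %*%
                         diag(spacing^2, length(spacing))))
    win <- dd < best[lin]           # strict: earlier (smaller) id keeps ties
    lab[lin[win]] <- s@seed_id
    best[lin[win]] <- dd[win]
  }
  LabelImage(lab, spacing)
}
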