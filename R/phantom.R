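# Synthetic clustered-nuclei phantoms with ground truth.

#' Generate a synthetic nuclei phantom
#'
#' Places `n_nuclei` spheres (disks in 2D) with radii drawn uniformly from
#' `radius_range` by rejection sampling. With probability
#' `clustering_probability` a nucleus is placed touching/nearly touching a
#' randomly chosen existing nucleus (centre distance uniform in 0.8 to 1.2
#' times the sum of the two radii); otherwise it is placed isolated, at
#' distance greater than 1.5 times the sum of radii from every existing
#' nucleus. Ground-truth labels are rasterized from the sharp pre-blur
#' geometry (overlapping voxels go to the nucleus with the smallest
#' `distance/radius`); the intensity image paints each nucleus with a
#' quadratic radial profile (peak `intensity_fg` at the centre, dimming by
#' `intensity_falloff` toward the rim, so the seam between touching nuclei
#' shows a dip as in stained chromatin), blurs with a Gaussian of std. dev.
#' `psf_sigma` (physical units),
#' optionally applies Poisson resampling, and adds Gaussian read noise. The
#' whole construction is reproducible bit-for-bit from `rng_seed`; the
#' caller's RNG state is left untouched.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with `volume` (a [Volume-class]) and `truth` (a
#'   [PhantomTruth-class]: pre-blur labels, physical centroids, radii and the
#'   measured SNR `(mean in-object - mean background)/sd(background)`).
#' @examples
#' p <- generatePhantom(phantomSpec(shape = c(48, 48), n_nuclei = 3,
#'                                  rng_seed = 1))
#' p$truth
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldseed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldseed, envir = globalenv())
  })
  set.seed(spec@rng_seed)

  d <- spec@shape
  nd <- length(d)
  sp <- spec@spacing
  extent <- (d - 1) * sp               # physical image extent

  centers <- matrix(numeric(0), 0, nd)
  radii <- numeric(0)
  for (i in seq_len(spec@n_nuclei)) {
    placed <- FALSE
    for (att in seq_len(spec@max_attempts)) {
      r <- stats::runif(1, spec@radius_range[1], spec@radius_range[2])
      clustered <- nrow(centers) > 0 &&
        stats::runif(1) < spec@clustering_probability
      if (clustered) {
        k <- sample.int(nrow(centers), 1)
        dir <- stats::rnorm(nd)
        dir <- dir / sqrt(sum(dir^2))
        u <- stats::runif(1, 0.8, 1.2) * (r + radii[k])
        cand <- centers[k, ] + u * dir
      } else {
        cand <- vapply(seq_len(nd), function(a)
          stats::runif(1, r, extent[a] - r), numeric(1))
      }
      if (any(cand < r) || any(cand > extent - r)) next
      if (nrow(centers) > 0) {
        dd <- sqrt(rowSums(sweep(centers, 2, cand)^2))
        if (clustered) {
          # near the chosen partner, but not engulfing anyone else
          if (any(dd < 0.8 * (r + radii))) next
        } else {
          if (any(dd <= 1.5 * (r + radii))) next
        }
      }
      centers <- rbind(centers, cand)
      radii <- c(radii, r)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place nucleus %d of %d within %d attempts (placed %d)",
                   i, spec@n_nuclei, spec@max_attempts, nrow(centers)))
  }

  lab <- array(0L, d)
  score <- array(Inf, d)
  prof <- array(0, d)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    lo <- pmax(1L, as.integer(floor((centers[i, ] - r) / sp)) + 1L)
    hi <- pmin(d, as.integer(ceiling((centers[i, ] + r) / sp)) + 1L)
    idx <- lapply(seq_len(nd), function(a) lo[a]:hi[a])
    grid <- as.matrix(expand.grid(idx))
    dist <- sqrt(rowSums(sweep(physCoords(grid, sp), 2, centers[i, ])^2))
    inside <- dist <= r
    if (!any(inside)) next
    lin <- coordsToLinear(grid[inside, , drop = FALSE], d)
    s <- dist[inside] / r
    win <- s < score[lin]
    lab[lin[win]] <- i
    score[lin[win]] <- s[win]
    prof[lin] <- pmax(prof[lin], 1 - spec@intensity_falloff * s^2)
  }

  img <- spec@intensity_bg + (spec@intensity_fg - spec@intensity_bg) * prof
  if (spec@psf_sigma > 0)
    img <- gaussianSmoothArray(img, spec@psf_sigma / sp)
  if (spec@poisson_scale > 0)
    img <- stats::rpois(length(img), pmax(img, 0) * spec@poisson_scale) /
      spec@poisson_scale
  if (spec@noise_sigma > 0)
    img <- img + stats::rnorm(length(img), sd = spec@noise_sigma)
  dim(img) <- d
  img <- pmax(img, 0)
  dim(img) <- d

  fgMask <- lab > 0L
  bg <- img[!fgMask]
  snr <- if (any(fgMask) && stats::sd(bg) > 0)
    (mean(img[fgMask]) - mean(bg)) / stats::sd(bg) else NA_real_

  list(volume = Volume(img, sp),
       truth = new("PhantomTruth", labels = LabelImage(lab, sp),
                   centroids = centers, radii = radii, snr = snr))
}

#' Deterministic two-nucleus walkthrough fixture
#'
#' A 2D crop with one central nucleus and one partially overlapping
#' neighbour, plus a seed on the central nucleus, mirroring the per-seed
#' processing walkthrough (cropped raw image, smoothed gradient, dot-product
#' transform, weighting, combination, threshold). Deterministic: repeated
#' calls return identical output.
#'
#' @return A list with `volume` (2D [Volume-class]), `seed` (one-row seed
#'   `data.frame`), `truth` (a [LabelImage-class] with label 1 = central
#'   nucleus, label 2 = neighbour) and `params` (the 2D benchmark
#'   [TwangParams-class]: scales 8 to 11 step 1, gradient sigma 3, kernel
#'   multiplier 1.5, kernel sigma 3).
#' @export
twoNucleusFixture <- function() {
  spec <- phantomSpec(shape = c(128L, 128L), spacing = c(1, 1), n_nuclei = 0,
                      rng_seed = 7L)
  d <- spec@shape
  centers <- rbind(c(63, 55), c(63, 55 + 0.95 * (13 + 11)))
  radii <- c(13, 11)
  lab <- array(0L, d)
  score <- array(Inf, d)
  prof <- array(0, d)
  grid <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2])))
  for (i in 1:2) {
    dist <- sqrt(rowSums(sweep(physCoords(grid, spec@spacing), 2, centers[i, ])^2))
    inside <- dist <= radii[i]
    lin <- coordsToLinear(grid[inside, , drop = FALSE], d)
    s <- dist[inside] / radii[i]
    win <- s < score[lin]
    lab[lin[win]] <- i
    score[lin[win]] <- s[win]
    prof[lin] <- pmax(prof[lin], 1 - spec@intensity_falloff * s^2)
  }
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldseed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldseed, envir = globalenv())
  })
  set.seed(spec@rng_seed)
  img <- spec@intensity_bg + (spec@intensity_fg - spec@intensity_bg) * prof
  img <- gaussianSmoothArray(img, c(1.5, 1.5))
  img <- img + stats::rnorm(length(img), sd = 5)
  dim(img) <- d
  img <- pmax(img, 0)
  dim(img) <- d
  seed <- data.frame(id = 1L, y = 64L, x = 56L, scale = 9,
                     radius = radiusFromScale(9, 2), response = 1)
  list(volume = Volume(img, spec@spacing), seed = seed,
       truth = LabelImage(lab, spec@spacing),
       params = twangParams(sigma_min = 8, sigma_max = 11, sigma_step = 1))
}
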