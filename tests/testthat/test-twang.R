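test_that("crop geometry follows the 4r side-length rule and clamps at borders", {
  v <- Volume(array(0, c(60, 60, 60)))
  seed <- data.frame(id = 1L, z = 30L, y = 30L, x = 30L, radius = 5)
  crop <- cropRegion(v, seed)
  expect_equal(dim(imageData(crop)), c(21L, 21L, 21L))
  expect_equal(crop@seed_local, c(11L, 11L, 11L))

  corner <- data.frame(id = 1L, z = 1L, y = 1L, x = 1L, radius = 5)
  cc <- cropRegion(v, corner)
  expect_equal(cc@offset, c(1L, 1L, 1L))
  expect_equal(cc@seed_local, c(1L, 1L, 1L))
  expect_equal(dim(imageData(cc)), c(11L, 11L, 11L))

  va <- Volume(array(0, c(60, 60, 30)), spacing = c(1, 1, 2))
  ca <- cropRegion(va, data.frame(id = 1L, z = 30L, y = 30L, x = 15L, radius = 6))
  expect_equal(dim(imageData(ca)), c(25L, 25L, 13L))   # half-widths 12,12,6
})

test_that("smoothed gradient is zero on constants and recovers ramp slopes", {
  v <- Volume(array(4, c(31, 31)))
  crop <- cropRegion(v, data.frame(id = 1L, y = 16L, x = 16L, radius = 7))
  g <- smoothedGradient(crop, 3)
  expect_true(all(abs(g[[1]]) < 1e-12) && all(abs(g[[2]]) < 1e-12))

  ramp <- Volume(outer(1:41, 1:41, function(a, b) 2 * a))
  crop <- cropRegion(ramp, data.frame(id = 1L, y = 21L, x = 21L, radius = 9))
  g <- smoothedGradient(crop, 3)
  interior <- g[[1]][15:23, 15:23]     # > 4*sigma + 1 from every crop face
  expect_lt(max(abs(interior - 2)), 1e-3)
  expect_lt(max(abs(g[[2]][15:23, 15:23])), 1e-3)

  # physical scaling: same voxel data, coarser spacing halves the derivative
  ramp2 <- Volume(outer(1:41, 1:41, function(a, b) 2 * a), spacing = c(2, 1))
  crop2 <- cropRegion(ramp2, data.frame(id = 1L, y = 21L, x = 21L, radius = 9))
  g2 <- smoothedGradient(crop2, 3)
  expect_lt(max(abs(g2[[1]][8:13, 15:23] - 1)), 1e-3)
})

test_that("seed-normal field obeys the Hadamard spacing product", {
  v <- Volume(array(0, c(31, 31, 31)), spacing = c(1, 1, 2))
  crop <- cropRegion(v, data.frame(id = 1L, z = 16L, y = 16L, x = 16L, radius = 5))
  nf <- seedNormalField(crop)
  at <- function(arr, off) arr[matrix(crop@seed_local + off, 1)]
  # +5 voxels along x with spacing 2 -> distance 10, unit normal (0,0,1)
  expect_equal(at(nf$dist, c(0, 0, 5)), 10)
  expect_equal(vapply(nf$normals, at, numeric(1), off = c(0, 0, 5)), c(0, 0, 1))
  # 3-4-5 triangle in the unit-spaced plane
  expect_equal(at(nf$dist, c(3, 4, 0)), 5)
  expect_equal(vapply(nf$normals, at, numeric(1), off = c(3, 4, 0)),
               c(0.6, 0.8, 0))
  # seed voxel: zero normal, zero distance
  expect_equal(at(nf$dist, c(0, 0, 0)), 0)
  expect_equal(vapply(nf$normals, at, numeric(1), off = c(0, 0, 0)), c(0, 0, 0))
})

test_that("dot-product transform maps gradient orientation onto [0,1]", {
  n <- list(array(1, c(3, 3)), array(0, c(3, 3)))
  gAnti <- list(array(-2, c(3, 3)), array(0, c(3, 3)))
  gPerp <- list(array(0, c(3, 3)), array(5, c(3, 3)))
  gPar <- list(array(0.4, c(3, 3)), array(0, c(3, 3)))
  expect_equal(dotProductTransform(n, gAnti), array(1, c(3, 3)),
               tolerance = 1e-12)
  expect_equal(dotProductTransform(n, gPerp), array(0.5, c(3, 3)),
               tolerance = 1e-12)
  expect_equal(dotProductTransform(n, gPar), array(0, c(3, 3)),
               tolerance = 1e-12)
  gZero <- list(array(0, c(3, 3)), array(0, c(3, 3)))
  expect_equal(dotProductTransform(n, gZero), array(0.5, c(3, 3)))
})

test_that("the transform is contrast invariant on a real crop", {
  set.seed(31)
  img <- renderSpot2D(41, 6, amplitude = 90) + matrix(runif(41^2), 41, 41)
  v <- Volume(img)
  seed <- data.frame(id = 1L, y = 21L, x = 21L, radius = 8)
  psiOf <- function(gain) {
    crop <- cropRegion(Volume(gain * img), seed)
    dotProductTransform(seedNormalField(crop)$normals,
                        smoothedGradient(crop, 3))
  }
  p1 <- psiOf(1); p2 <- psiOf(7.3)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(p2, p1, tolerance = 1e-9)
})

test_that("the plateau-Gaussian kernel matches its closed form", {
  d <- array(c(0, 3, 7.5, 7.5 + 3, 20), c(5, 1))
  w <- weightingKernel(d, radius = 5, kernel_multiplier = 1.5, kernel_sigma = 3)
  expect_equal(w[1:3], rep(1, 3))                       # plateau: up to m*r
  expect_equal(w[4], exp(-1 / 2), tolerance = 1e-12)    # one sigma beyond
  expect_true(all(w > 0 & w <= 1))
})

test_that("combination copies through inside the seed radius and scales outside", {
  v <- Volume(matrix(117, 21, 21))
  crop <- cropRegion(v, data.frame(id = 1L, y = 11L, x = 11L, radius = 5))
  nf <- seedNormalField(crop)
  psi <- array(0, dim(imageData(crop)))
  w <- array(0.5, dim(imageData(crop)))
  comb <- combineImages(crop, psi, w, 5)
  expect_equal(comb[11, 11], 117)
  expect_equal(comb[11, 13], 117)      # distance 2 < radius
  expect_equal(comb[1, 1], 0)          # outside: I * w * psi = 0

  set.seed(33)
  img <- matrix(runif(21 * 21, 10, 200), 21, 21)
  cropOf <- function(gain) cropRegion(Volume(gain * img),
                                      data.frame(id = 1L, y = 11L, x = 11L,
                                                 radius = 5))
  psi <- array(runif(21 * 21), c(21, 21))
  w <- array(runif(21 * 21, 0.1, 1), c(21, 21))
  expect_equal(combineImages(cropOf(3), psi, w, 5),
               3 * combineImages(cropOf(1), psi, w, 5), tolerance = 1e-12)
})

test_that("Otsu threshold separates bimodal data and matches exhaustive search", {
  field <- c(rep(0, 100), rep(100, 100))
  ot <- otsuThreshold(field)
  expect_false(ot$degenerate)
  expect_gt(ot$threshold, 0)
  expect_lt(ot$threshold, 100)
  expect_true(all(field[field > ot$threshold] == 100))

  set.seed(41)
  for (i in 1:10) {
    x <- c(rnorm(80, 30, 8), rnorm(60, 120, 15))
    expect_equal(otsuThreshold(x)$threshold, otsuBrute(x), tolerance = 1e-12)
  }
  ot <- otsuThreshold(rep(4, 50))
  expect_true(ot$degenerate)
  expect_equal(ot$threshold, 4)
})

test_that("an isolated sphere is recovered with accurate volume", {
  p <- generatePhantom(phantomSpec(shape = c(48L, 48L, 48L), n_nuclei = 1,
                                   radius_range = c(6, 6),
                                   clustering_probability = 0, psf_sigma = 1,
                                   noise_sigma = 2, rng_seed = 3L))
  params <- twangParams(sigma_min = 3, sigma_max = 4, sigma_step = 0.25,
                        seed_intensity_threshold = 45)
  seeds <- detectSeeds(scaleSpaceMIP(p$volume, buildScales(3, 4, 0.25)), params)
  expect_equal(nrow(seeds), 1L)
  seg <- segmentOneSeed(p$volume, seeds[1, ], params)
  expect_s4_class(seg, "SegmentCandidate")
  expect_lt(abs(seg@volume_voxels - 4 / 3 * pi * 6^3) / (4 / 3 * pi * 6^3), 0.2)
  loc <- as.integer(seeds[1, c("z", "y", "x")]) - seg@offset + 1L
  expect_true(seg@mask[matrix(loc, 1)])
})

test_that("an all-zero background crop yields no segment with a degenerate flag", {
  v <- Volume(matrix(0, 31, 31))
  seed <- data.frame(id = 1L, y = 16L, x = 16L, radius = 5)
  seg <- segmentOneSeed(v, seed)
  expect_s3_class(seg, "twangDiscarded")
  expect_equal(seg$reason, "degenerate")
})

test_that("segmentAll is deterministic across worker counts and accounts for every seed", {
  p <- generatePhantom(phantomSpec(shape = c(96L, 96L), n_nuclei = 6,
                                   radius_range = c(6, 9),
                                   clustering_probability = 0, psf_sigma = 1,
                                   noise_sigma = 8, rng_seed = 17L))
  params <- twangParams(sigma_min = 4, sigma_max = 6.5, sigma_step = 0.5,
                        seed_intensity_threshold = 45)
  seeds <- detectSeeds(scaleSpaceMIP(p$volume, buildScales(4, 6.5, 0.5)), params)
  expect_equal(nrow(seeds), 6L)
  s1 <- segmentAll(p$volume, seeds, params, workers = 1L)
  s2 <- segmentAll(p$volume, seeds, params, workers = 2L)
  expect_equal(length(s1), nrow(seeds))
  attributes(s1) <- NULL; attributes(s2) <- NULL
  expect_equal(s1, s2)

  empty <- segmentAll(p$volume, seeds[0, ], params)
  expect_length(empty, 0)
})

test_that("label assembly resolves overlaps by distance with ties to the smaller id", {
  mk <- function(id, pos, maskIdx) {
    mask <- array(FALSE, c(1, 5))
    mask[maskIdx] <- TRUE
    new("SegmentCandidate", seed_id = id, seed_pos = pos,
        offset = c(1L, 1L), mask = mask, otsu_threshold = 0,
        centroid = c(0, 0), volume_voxels = sum(mask),
        volume_physical = sum(mask), mean_intensity = 1,
        bbox = rbind(min = c(1, 1), max = c(1, 5)))
  }
  # seeds at x=2 and x=4; masks overlap on x=3 (equidistant) and x=2/x=4
  a <- mk(1L, c(1L, 2L), c(1, 2, 3))
  b <- mk(2L, c(1L, 4L), c(3, 4, 5))
  lab <- assembleLabelImage(list(a, b), c(1L, 5L), c(1, 1))
  expect_equal(as.vector(imageData(lab)), c(1L, 1L, 1L, 2L, 2L))

  # disjoint masks are painted verbatim; label count never exceeds seed count
  c2 <- mk(3L, c(1L, 5L), 5)
  lab2 <- assembleLabelImage(list(a, c2), c(1L, 5L), c(1, 1))
  expect_equal(as.vector(imageData(lab2)), c(1L, 1L, 1L, 0L, 3L))
  expect_lte(length(setdiff(unique(as.vector(imageData(lab2))), 0L)), 2)
})
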