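spotScaleSpace <- function(img, scales = seq(2, 4, by = 0.5)) {
  scaleSpaceMIP(Volume(img), scales)
}

test_that("a constant image yields no seeds", {
  ss <- spotScaleSpace(matrix(5, 32, 32))
  expect_equal(nrow(detectSeeds(ss)), 0L)
})

test_that("a single rendered spot yields one seed at its centre", {
  img <- renderSpot2D(49, 3, centre = c(25, 25))
  ss <- spotScaleSpace(img)
  seeds <- detectSeeds(ss, twangParams(sigma_min = 2, sigma_max = 4,
                                       sigma_step = 0.5,
                                       seed_intensity_threshold = 0.05))
  expect_equal(nrow(seeds), 1L)
  expect_lte(max(abs(c(seeds$y, seeds$x) - c(25, 25))), 1)
  expect_equal(seeds$scale, 3)
  expect_equal(seeds$radius, radiusFromScale(3, 2))
})

test_that("seed fusion keeps both distant spots and collapses close maxima", {
  far <- renderSpot2D(81, 3, centre = c(25, 25)) +
    renderSpot2D(81, 3, centre = c(60, 60)) * 0.9
  ss <- spotScaleSpace(far)
  p <- twangParams(sigma_min = 2, sigma_max = 4, sigma_step = 0.5,
                   seed_intensity_threshold = 0.05, fusion_distance = 6)
  expect_equal(nrow(detectSeeds(ss, p)), 2L)

  near <- renderSpot2D(81, 3, centre = c(40, 38)) +
    renderSpot2D(81, 3, centre = c(40, 43)) * 0.9
  seeds <- detectSeeds(spotScaleSpace(near), p)
  expect_equal(nrow(seeds), 1L)
  # strongest-response candidate survives
  expect_lte(abs(seeds$x - 40), 2)
})

test_that("seed count is monotonically non-increasing in the intensity threshold", {
  set.seed(13)
  img <- matrix(runif(48 * 48), 48, 48)
  ss <- spotScaleSpace(img, seq(1.5, 2.5, by = 0.5))
  thresholds <- c(0, 0.001, 0.005, 0.01, 0.05)
  counts <- vapply(thresholds, function(t)
    nrow(detectSeeds(ss, twangParams(sigma_min = 1.5, sigma_max = 2.5,
                                     sigma_step = 0.5,
                                     seed_intensity_threshold = t,
                                     fusion_distance = 0))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("seed positions are invariant under positive intensity gain", {
  set.seed(14)
  img <- renderSpot2D(49, 3) + matrix(runif(49^2), 49, 49) * 0.02
  a <- 7.3
  p1 <- twangParams(sigma_min = 2, sigma_max = 4, sigma_step = 0.5,
                    seed_intensity_threshold = 0.05)
  p2 <- twangParams(sigma_min = 2, sigma_max = 4, sigma_step = 0.5,
                    seed_intensity_threshold = 0.05 * a)
  s1 <- detectSeeds(spotScaleSpace(img), p1)
  s2 <- detectSeeds(spotScaleSpace(a * img), p2)
  expect_equal(s1[c("y", "x", "scale")], s2[c("y", "x", "scale")])
  expect_equal(s2$response, a * s1$response, tolerance = 1e-9)
})

test_that("plateaus of equal maxima reduce to the lexicographically first voxel", {
  m <- matrix(0, 12, 12)
  m[5:6, 7:8] <- 5    # 2x2 flat plateau
  ss <- new("ScaleSpaceResult", mip = Volume(m),
            scaleMap = Volume(array(2, dim(m))), scales = 2)
  seeds <- detectSeeds(ss, twangParams(sigma_min = 2, sigma_max = 2,
                                       sigma_step = 1, fusion_distance = 0))
  expect_equal(nrow(seeds), 1L)
  expect_equal(c(seeds$y, seeds$x), c(5, 7))
})

test_that("anisotropic spacing still recovers an isotropic physical sphere's scale", {
  r <- 6
  iso <- renderSphere(c(41, 41, 41), c(1, 1, 1), c(20, 20, 20), r)
  aniso <- renderSphere(c(21, 41, 41), c(2, 1, 1), c(20, 20, 20), r)
  p <- twangParams(sigma_min = 2.5, sigma_max = 4.5, sigma_step = 0.5,
                   seed_intensity_threshold = 20)
  sIso <- detectSeeds(scaleSpaceMIP(Volume(iso), buildScales(2.5, 4.5, 0.5)), p)
  sAniso <- detectSeeds(scaleSpaceMIP(Volume(aniso, c(2, 1, 1)),
                                      buildScales(2.5, 4.5, 0.5)), p)
  expect_equal(nrow(sIso), 1L)
  expect_equal(nrow(sAniso), 1L)
  expect_lte(abs(sIso$scale - sAniso$scale), 0.5 + 1e-9)
})
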