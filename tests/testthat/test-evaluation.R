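li <- function(m, spacing = rep(1, length(dim(m)))) LabelImage(m, spacing)

test_that("identical labelings give perfect scores and an identity assignment", {
  set.seed(51)
  m <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  a <- li(m)
  rep <- evaluateSegmentation(a, a)
  expect_equal(rep@rand_index, 100)
  expect_true(is.infinite(rep@jaccard_index))
  expect_equal(rep@hausdorff, 0)
  expect_equal(rep@nsd, 0)
  expect_equal(c(rep@n_split, rep@n_merged, rep@n_added, rep@n_missing),
               rep(0L, 4))

  mo <- matchObjects(a, a)
  expect_equal(unname(mo$seg_to_ref), as.integer(names(mo$seg_to_ref)))
  off <- mo$overlap[setdiff(rownames(mo$overlap), "0"),
                    setdiff(colnames(mo$overlap), "0"), drop = FALSE]
  expect_true(all(off[row(off) != col(off)] == 0))
})

test_that("the 2x2 worked example gives RI 66.667 and JI 2.0", {
  ref <- li(matrix(c(0L, 0L, 1L, 1L), 2, 2))
  seg <- li(matrix(c(0L, 1L, 0L, 1L), 2, 2))
  expect_equal(randIndex(ref, seg), 100 * 4 / 6, tolerance = 1e-9)
  expect_equal(jaccardIndex(ref, seg), 2.0, tolerance = 1e-9)
})

test_that("contingency-table pair counts equal O(n^2) enumeration on random images", {
  set.seed(52)
  for (i in 1:8) {
    ref <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    seg <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    oracle <- pairEnumeration(ref, seg)
    expect_equal(randIndex(li(ref), li(seg)), oracle$ri, tolerance = 1e-12)
    expect_equal(jaccardIndex(li(ref), li(seg)), oracle$ji, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under consistent label permutation", {
  set.seed(53)
  ref <- matrix(sample(0:3, 49, replace = TRUE), 7, 7)
  seg <- matrix(sample(0:3, 49, replace = TRUE), 7, 7)
  perm <- c(0L, 3L, 1L, 2L)   # relabel 1->3, 2->1, 3->2
  segP <- matrix(perm[seg + 1L], 7, 7)
  expect_equal(randIndex(li(ref), li(seg)), randIndex(li(ref), li(segP)))
  expect_equal(jaccardIndex(li(ref), li(seg)), jaccardIndex(li(ref), li(segP)))
  n1 <- normalizedSumDistances(li(ref), li(seg))
  refP <- matrix(perm[ref + 1L], 7, 7)
  n2 <- normalizedSumDistances(li(refP), li(seg))
  expect_equal(n1$nsd, n2$nsd)
})

test_that("Hausdorff matches the single-point case and the all-pairs oracle", {
  forced <- list(seg_to_ref = stats::setNames(1L, "1"))
  ref <- matrix(0L, 6, 6); ref[1, 1] <- 1L
  seg <- matrix(0L, 6, 6); seg[4, 5] <- 1L
  expect_equal(hausdorffMetric(li(ref), li(seg), forced), 5)

  set.seed(54)
  for (i in 1:6) {
    ref <- matrix(0L, 8, 8); seg <- matrix(0L, 8, 8)
    ref[sample(64, 12)] <- 1L
    seg[sample(64, 12)] <- 1L
    sp <- c(1, 2)
    got <- hausdorffMetric(li(ref, sp), li(seg, sp), forced)
    want <- hausdorffBrute(arrayInd(which(ref == 1L), dim(ref)),
                           arrayInd(which(seg == 1L), dim(seg)), sp)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("NSD matches a hand tally on the 7x7 dilation fixture", {
  ref <- matrix(0L, 9, 9)
  ref[3:7, 3:7] <- 1L           # 5x5 square object
  seg <- matrix(0L, 9, 9)
  seg[2:8, 2:8] <- 1L           # dilated by a one-voxel ring (7x7)
  got <- normalizedSumDistances(li(ref), li(seg))$nsd

  # independent tally: distances to the reference border (the 16 ring voxels
  # of the 5x5 square; the interior 3x3 block is not border)
  border <- arrayInd(which(ref == 1L), dim(ref))
  interior <- border[, 1] >= 4 & border[, 1] <= 6 &
    border[, 2] >= 4 & border[, 2] <= 6
  border <- border[!interior, ]
  dTo <- function(p) min(sqrt(rowSums(sweep(border, 2, p)^2)))
  U <- arrayInd(which(ref == 1L | seg == 1L), dim(ref))
  D <- arrayInd(which(xor(ref == 1L, seg == 1L)), dim(ref))
  want <- sum(apply(D, 1, dTo)) / sum(apply(U, 1, dTo))
  expect_equal(got, want, tolerance = 1e-12)
  expect_gt(got, 0)
  expect_lte(got, 1)
})

test_that("object-level error counts identify splits, merges, additions, misses", {
  # one reference object covered by two half segments -> split = 1
  ref <- matrix(0L, 6, 6); ref[2:5, 2:5] <- 1L
  seg <- matrix(0L, 6, 6); seg[2:5, 2:3] <- 1L; seg[2:5, 4:5] <- 2L
  err <- countErrors(matchObjects(li(ref), li(seg)))
  expect_equal(err[["n_split"]], 1L)
  expect_equal(err[["n_merged"]], 0L)

  # two reference objects covered by one segment -> merged = 1
  ref2 <- matrix(0L, 6, 6); ref2[2:5, 2:3] <- 1L; ref2[2:5, 4:5] <- 2L
  seg2 <- matrix(0L, 6, 6); seg2[2:5, 2:5] <- 1L
  err2 <- countErrors(matchObjects(li(ref2), li(seg2)))
  expect_equal(err2[["n_merged"]], 1L)
  expect_equal(err2[["n_split"]], 0L)
  expect_equal(err2[["n_missing"]], 0L)

  # a segment on pure background -> added; an uncovered reference -> missing
  ref3 <- matrix(0L, 8, 8); ref3[2:3, 2:3] <- 1L
  seg3 <- matrix(0L, 8, 8); seg3[6:7, 6:7] <- 1L
  err3 <- countErrors(matchObjects(li(ref3), li(seg3)))
  expect_equal(err3[["n_added"]], 1L)
  expect_equal(err3[["n_missing"]], 1L)
})

test_that("shape mismatch is rejected", {
  expect_error(matchObjects(li(matrix(0L, 4, 4)), li(matrix(0L, 5, 5))),
               "same shape")
})
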