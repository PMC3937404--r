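# Segmentation quality criteria: object matching, pair-counting indices,
# Hausdorff metric, normalized sum of distances, object-level error counts.

#' Match objects between a reference and a segmentation
#'
#' Builds the full overlap (contingency) matrix between reference and
#' segmented objects, including the background (label 0) row and column, and
#' derives two assignments: each segmented object is assigned to the
#' reference object it overlaps most (or to background when more than half of
#' its voxels lie on reference background), and symmetrically each reference
#' object claims the segmented object it overlaps most (or none when more
#' than half of its voxels lie on segmentation background). Ties go to the
#' smaller label.
#'
#' @param reference,segmentation [LabelImage-class] objects of identical
#'   shape and spacing.
#' @return A list with `overlap` (matrix, dimnames are label values incl.
#'   `"0"`), `seg_to_ref` (named integer vector, 0 = background) and
#'   `ref_to_seg` (named integer vector, 0 = none claimed).
#' @export
matchObjects <- function(reference, segmentation) {
  stopifnot(is(reference, "LabelImage"), is(segmentation, "LabelImage"))
  if (!identical(dim(reference@labels), dim(segmentation@labels)))
    stop("reference and segmentation must have the same shape")
  ref <- as.vector(reference@labels)
  seg <- as.vector(segmentation@labels)
  rlev <- sort(unique(ref))
  slev <- sort(unique(seg))
  ri <- match(ref, rlev)
  si <- match(seg, slev)
  counts <- tabulate((si - 1L) * length(rlev) + ri,
                     nbins = length(rlev) * length(slev))
  overlap <- matrix(counts, length(rlev), length(slev),
                    dimnames = list(as.character(rlev), as.character(slev)))
  if (!"0" %in% rownames(overlap))
    overlap <- rbind(`0` = 0L, overlap)
  if (!"0" %in% colnames(overlap))
    overlap <- cbind(`0` = 0L, overlap)

  segLabs <- setdiff(as.integer(colnames(overlap)), 0L)
  refLabs <- setdiff(as.integer(rownames(overlap)), 0L)
  seg_to_ref <- vapply(as.character(segLabs), function(j) {
    col <- overlap[, j]
    tot <- sum(col)
    if (col["0"] > tot / 2 || length(refLabs) == 0) return(0L)
    obj <- col[setdiff(names(col), "0")]
    as.integer(names(obj)[which.max(obj)])   # ties: smaller label (sorted)
  }, integer(1))
  ref_to_seg <- vapply(as.character(refLabs), function(i) {
    row <- overlap[i, ]
    tot <- sum(row)
    if (row["0"] > tot / 2 || length(segLabs) == 0) return(0L)
    obj <- row[setdiff(names(row), "0")]
    as.integer(names(obj)[which.max(obj)])
  }, integer(1))
  list(overlap = overlap, seg_to_ref = seg_to_ref, ref_to_seg = ref_to_seg)
}

# Pair-counting machinery. Background voxels are treated as unpaired
# singletons: two background voxels never count as "grouped together".
pairCounts <- function(reference, segmentation) {
  if (!identical(dim(reference@labels), dim(segmentation@labels)))
    stop("reference and segmentation must have the same shape")
  ref <- as.vector(reference@labels)
  seg <- as.vector(segmentation@labels)
  n <- length(ref)
  if (n < 2) stop("need at least 2 voxels for pair counting")
  choose2 <- function(x) x * (x - 1) / 2
  sameRef <- sum(choose2(tabulate(ref[ref > 0L])))
  sameSeg <- sum(choose2(tabulate(seg[seg > 0L])))
  both <- ref > 0L & seg > 0L
  if (any(both)) {
    key <- interaction(ref[both], seg[both], drop = TRUE)
    sameBoth <- sum(choose2(as.numeric(table(key))))
  } else sameBoth <- 0
  total <- choose2(n)
  agree <- total - sameRef - sameSeg + 2 * sameBoth
  list(agree = agree, disagree = total - agree, total = total)
}

#' Rand index of two label images
#'
#' Over all unordered voxel pairs, the fraction for which the two labelings
#' agree (both place the pair in one object, or neither does), as a
#' percentage. Background voxels are treated as unlabeled singletons.
#' Computed from the label contingency counts, not by pair enumeration.
#'
#' @param reference,segmentation [LabelImage-class] objects, same shape.
#' @return Percentage in `[0, 100]`; 100 for identical labelings.
#' @export
randIndex <- function(reference, segmentation) {
  pc <- pairCounts(reference, segmentation)
  100 * pc$agree / pc$total
}

#' Pair-based Jaccard index of two label images
#'
#' Ratio of agreeing to disagreeing voxel pairs (pairs as in [randIndex()]).
#' Not upper-bounded; `Inf` (degenerate) when every pair agrees.
#'
#' @param reference,segmentation [LabelImage-class] objects, same shape.
#' @return Non-negative ratio, possibly `Inf`.
#' @export
jaccardIndex <- function(reference, segmentation) {
  pc <- pairCounts(reference, segmentation)
  if (pc$disagree == 0) return(Inf)
  pc$agree / pc$disagree
}

# Boundary voxels of a voxel coordinate set: those with a face neighbor
# outside the set (or on the image edge).
boundaryCoords <- function(coords, d) {
  lin <- coordsToLinear(coords, d)
  inset <- logical(prod(d))
  inset[lin] <- TRUE
  nd <- ncol(coords)
  onb <- logical(nrow(coords))
  for (ax in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      nb <- coords
      nb[, ax] <- nb[, ax] + s
      out <- nb[, ax] < 1 | nb[, ax] > d[ax]
      nlin <- coordsToLinear(pmaxCoords(nb, d), d)
      onb <- onb | out | !inset[nlin]
    }
  }
  coords[onb, , drop = FALSE]
}

pmaxCoords <- function(coords, d) {
  for (ax in seq_len(ncol(coords)))
    coords[, ax] <- pmin(pmax(coords[, ax], 1L), d[ax])
  coords
}

# Min physical distance from each row of `from` to the set `to` (both
# coordinate matrices), chunked to bound memory.
minDistTo <- function(from, to, spacing) {
  if (nrow(from) == 0) return(numeric(0))
  fp <- physCoords(from, spacing)
  tp <- physCoords(to, spacing)
  out <- numeric(nrow(fp))
  chunk <- max(1L, as.integer(2e6 / max(1, nrow(tp))))
  for (i in seq(1, nrow(fp), by = chunk)) {
    j <- min(nrow(fp), i + chunk - 1)
    block <- fp[i:j, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rep(1, nrow(tp))) +
      outer(rep(1, nrow(block)), rowSums(tp^2)) -
      2 * block %*% t(tp)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Hausdorff metric between matched objects
#'
#' For every matched (reference, segmented) object pair the symmetric
#' Hausdorff distance between the two voxel sets is computed in physical
#' coordinates, and the mean over matched pairs is reported as the per-image
#' scalar. Unmatched objects are excluded. Internally the target set of each
#' directed distance is reduced to its boundary voxels, which leaves the
#' metric unchanged.
#'
#' @param reference,segmentation [LabelImage-class] objects, same shape.
#' @param assignment result of [matchObjects()]; computed if missing.
#' @return Mean symmetric Hausdorff distance (`NA` if no pairs match).
#' @export
hausdorffMetric <- function(reference, segmentation, assignment = NULL) {
  if (is.null(assignment)) assignment <- matchObjects(reference, segmentation)
  pairs <- matchedPairs(assignment)
  if (nrow(pairs) == 0) return(NA_real_)
  d <- dim(reference@labels)
  sp <- reference@spacing
  vals <- vapply(seq_len(nrow(pairs)), function(k) {
    A <- arrayInd(which(reference@labels == pairs$ref[k]), d)
    B <- arrayInd(which(segmentation@labels == pairs$seg[k]), d)
    directed <- function(from, to) {
      toB <- boundaryCoords(to, d)
      # voxels of `from` inside `to` are at distance 0
      inTo <- logical(prod(d))
      inTo[coordsToLinear(to, d)] <- TRUE
      outside <- from[!inTo[coordsToLinear(from, d)], , drop = FALSE]
      if (nrow(outside) == 0) 0 else max(minDistTo(outside, toB, sp))
    }
    max(directed(A, B), directed(B, A))
  }, numeric(1))
  mean(vals)
}

matchedPairs <- function(assignment) {
  s2r <- assignment$seg_to_ref
  keep <- s2r > 0
  data.frame(ref = as.integer(s2r[keep]),
             seg = as.integer(names(s2r)[keep]))
}

#' Normalized sum of distances between matched objects
#'
#' For each matched (reference, segmented) pair: the sum, over voxels where
#' the two objects disagree, of the physical distance to the border of the
#' reference object, divided by the same sum over the union of the two voxel
#' sets. 0 means perfect agreement, 1 maximal disagreement. The mean over
#' matched pairs is reported, both raw and multiplied by 10 (the scaling used
#' in common benchmark tables).
#'
#' @param reference,segmentation [LabelImage-class] objects, same shape.
#' @param assignment result of [matchObjects()]; computed if missing.
#' @return A list with `nsd` and `nsd_x10` (`NA` if no pairs match).
#' @export
normalizedSumDistances <- function(reference, segmentation, assignment = NULL) {
  if (is.null(assignment)) assignment <- matchObjects(reference, segmentation)
  pairs <- matchedPairs(assignment)
  if (nrow(pairs) == 0) return(list(nsd = NA_real_, nsd_x10 = NA_real_))
  d <- dim(reference@labels)
  sp <- reference@spacing
  vals <- vapply(seq_len(nrow(pairs)), function(k) {
    A <- which(reference@labels == pairs$ref[k])
    B <- which(segmentation@labels == pairs$seg[k])
    U <- union(A, B)
    D <- union(setdiff(A, B), setdiff(B, A))
    if (length(D) == 0) return(0)
    border <- boundaryCoords(arrayInd(A, d), d)
    distU <- minDistTo(arrayInd(U, d), border, sp)
    names(distU) <- as.character(U)
    denom <- sum(distU)
    if (denom == 0) return(0)
    sum(distU[as.character(D)]) / denom
  }, numeric(1))
  list(nsd = mean(vals), nsd_x10 = 10 * mean(vals))
}

#' Object-level error counts
#'
#' From the assignments of [matchObjects()]: `missing` reference objects
#' claim no segmented object (their voxels are majority
#' segmentation-background); `added` segmented objects are assigned to
#' background; a reference object with `k >= 2` assigned segments
#' contributes `k - 1` to `split`; a segmented object claimed as
#' maximal-overlap target by `k >= 2` reference objects contributes `k - 1`
#' to `merged`.
#'
#' @param assignment result of [matchObjects()].
#' @return A named integer vector `(n_split, n_merged, n_added, n_missing)`.
#' @export
countErrors <- function(assignment) {
  s2r <- assignment$seg_to_ref
  r2s <- assignment$ref_to_seg
  refLabs <- as.integer(names(r2s))
  n_added <- sum(s2r == 0L)
  n_missing <- sum(r2s == 0L)
  assignedPer <- table(factor(s2r[s2r > 0L], levels = refLabs))
  n_split <- sum(pmax(as.integer(assignedPer) - 1L, 0L))
  claims <- table(r2s[r2s > 0L])
  n_merged <- sum(pmax(as.integer(claims) - 1L, 0L))
  c(n_split = as.integer(n_split), n_merged = as.integer(n_merged),
    n_added = as.integer(n_added), n_missing = as.integer(n_missing))
}

#' Full segmentation quality report
#'
#' Convenience wrapper computing [randIndex()], [jaccardIndex()],
#' [hausdorffMetric()], [normalizedSumDistances()] and [countErrors()] for a
#' (reference, segmentation) pair.
#'
#' @param reference,segmentation [LabelImage-class] objects, same shape and
#'   spacing.
#' @return An [EvaluationReport-class].
#' @examples
#' ref <- LabelImage(matrix(c(0, 0, 1, 1), 2, 2))
#' seg <- LabelImage(matrix(c(0, 1, 0, 1), 2, 2))
#' evaluateSegmentation(ref, seg)
#' @export
evaluateSegmentation <- function(reference, segmentation) {
  m <- matchObjects(reference, segmentation)
  err <- countErrors(m)
  nsd <- normalizedSumDistances(reference, segmentation, m)
  new("EvaluationReport",
      rand_index = randIndex(reference, segmentation),
      jaccard_index = jaccardIndex(reference, segmentation),
      hausdorff = hausdorffMetric(reference, segmentation, m),
      nsd = nsd$nsd, nsd_x10 = nsd$nsd_x10,
      n_split = err[["n_split"]], n_merged = err[["n_merged"]],
      n_added = err[["n_added"]], n_missing = err[["n_missing"]],
      n_reference = length(m$ref_to_seg),
      n_segmented = length(m$seg_to_ref))
}
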