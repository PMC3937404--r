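# Seed extraction from the LoG scale-space MIP.

#' Detect nucleus seed points
#'
#' Extracts local maxima of the scale-space MIP over the full 8/26
#' neighborhood (a voxel qualifies if it is >= all neighbors and > at least
#' one; within a connected plateau of equal-valued maxima only the
#' lexicographically smallest voxel is kept). Maxima with response below or
#' equal to `seed_intensity_threshold` are discarded, and surviving candidates
#' are fused greedily: sorted by descending response, a candidate is accepted
#' only if it lies farther than `fusion_distance` (physical units) from every
#' already accepted seed. Each seed carries the scale stored in the scale map
#' at its position and the radius estimate [radiusFromScale()].
#'
#' @param ss a [ScaleSpaceResult-class] from [scaleSpaceMIP()].
#' @param params a [TwangParams-class]; uses `seed_intensity_threshold` and
#'   `fusion_distance` (`NA` = radius at `sigma_min`).
#' @return A `data.frame` with columns `id`, one voxel-index column per axis
#'   (`z`, `y`, `x` in 3D; `y`, `x` in 2D; 1-based), `scale`, `radius`,
#'   `response`, ordered by descending response. Zero rows if no maxima
#'   survive.
#' @export
detectSeeds <- function(ss, params = twangParams()) {
  stopifnot(is(ss, "ScaleSpaceResult"), is(params, "TwangParams"))
  mip <- imageData(ss@mip)
  d <- dim(mip)
  nd <- length(d)
  sp <- spacing(ss@mip)

  offs <- neighborOffsets(nd)
  geAll <- array(TRUE, d)
  gtAny <- array(FALSE, d)
  eqAny <- array(FALSE, d)
  for (i in seq_len(nrow(offs))) {
    nb <- shiftArray(mip, offs[i, ], fill = -Inf)
    geAll <- geAll & (mip >= nb)
    gtAny <- gtAny | (mip > nb)
    eqAny <- eqAny | (mip == nb)
  }
  candMask <- geAll & gtAny
  if (!any(candMask)) return(emptySeedFrame(nd))

  # Adjacent candidates necessarily share the same value (a strict inequality
  # would disqualify the smaller one), so plateaus are the connected
  # components of the candidate mask; keep the lexicographically first voxel.
  # Candidates without any equal-valued neighbor are singleton maxima and
  # need no component search.
  coords <- arrayInd(which(candMask & !eqAny), d)
  plateau <- candMask & eqAny
  if (any(plateau)) {
    comp <- labelComponents(plateau)
    pc <- arrayInd(which(plateau), d)
    labs <- comp[plateau]
    ord <- lexOrder(pc)
    first <- ord[!duplicated(labs[ord])]
    coords <- rbind(coords, pc[first, , drop = FALSE])
  }

  resp <- mip[coords]
  above <- resp > params@seed_intensity_threshold
  coords <- coords[above, , drop = FALSE]
  resp <- resp[above]
  if (nrow(coords) == 0) return(emptySeedFrame(nd))

  # Greedy fusion, strongest response first; ties broken lexicographically.
  fd <- params@fusion_distance
  if (is.na(fd)) fd <- radiusFromScale(params@sigma_min, nd)
  ord <- do.call(order, c(list(-resp), lapply(seq_len(nd), function(a) coords[, a])))
  coords <- coords[ord, , drop = FALSE]
  resp <- resp[ord]
  phys <- physCoords(coords, sp)
  accepted <- integer(0)
  for (i in seq_len(nrow(coords))) {
    if (length(accepted) == 0) {
      accepted <- i
    } else {
      dd <- sqrt(rowSums((phys[accepted, , drop = FALSE] -
                            matrix(phys[i, ], length(accepted), nd,
                                   byrow = TRUE))^2))
      if (all(dd > fd)) accepted <- c(accepted, i)
    }
  }
  coords <- coords[accepted, , drop = FALSE]
  resp <- resp[accepted]
  sc <- imageData(ss@scaleMap)[coords]

  out <- data.frame(id = seq_along(resp))
  ax <- axisNames(nd)
  for (a in seq_len(nd)) out[[ax[a]]] <- coords[, a]
  out$scale <- sc
  out$radius <- radiusFromScale(sc, nd)
  out$response <- resp
  out
}

axisNames <- function(ndim) if (ndim == 3) c("z", "y", "x") else c("y", "x")

emptySeedFrame <- function(ndim) {
  out <- data.frame(id = integer(0))
  for (a in axisNames(ndim)) out[[a]] <- integer(0)
  out$scale <- numeric(0)
  out$radius <- numeric(0)
  out$response <- numeric(0)
  out
}

# Coordinate matrix (n x ndim) from a seed data.frame.
seedCoords <- function(seeds, ndim) {
  as.matrix(seeds[, axisNames(ndim), drop = FALSE])
}
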