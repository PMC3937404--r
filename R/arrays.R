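# Internal n-D array utilities shared by seed detection, segmentation and
# evaluation: neighbor shifts, connected components, coordinate helpers.

# All offsets of the full (8/26) neighborhood for ndim axes.
neighborOffsets <- function(ndim) {
  g <- as.matrix(expand.grid(rep(list(-1:1), ndim)))
  dimnames(g) <- NULL
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Value of the neighbor at `off` for each voxel; `fill` outside the image.
shiftArray <- function(a, off, fill = -Inf) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (ax in seq_along(d)) {
    o <- off[ax]
    dst[[ax]] <- seq_len(d[ax])[(1 - min(o, 0)):(d[ax] - max(o, 0))]
    src[[ax]] <- dst[[ax]] + o
  }
  out_idx <- do.call(`[<-`, c(list(out), dst,
                              list(value = do.call(`[`, c(list(a), src)))))
  out_idx
}

# Linear index <-> coordinate helpers (1-based, column-major).
coordsToLinear <- function(coords, d) {
  strides <- cumprod(c(1, d[-length(d)]))
  as.vector(1 + (coords - 1) %*% strides)
}

# Connected component of `mask` containing the start voxel, full
# connectivity. `start` is a coordinate row vector. Returns a logical array.
floodFillComponent <- function(mask, start) {
  d <- dim(mask)
  nd <- length(d)
  offs <- neighborOffsets(nd)
  comp <- array(FALSE, d)
  if (!mask[matrix(start, 1)]) return(comp)
  comp[matrix(start, 1)] <- TRUE
  frontier <- matrix(start, 1)
  while (nrow(frontier) > 0) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                     drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), nrow(frontier)), , drop = FALSE]
    ok <- rep(TRUE, nrow(cand))
    for (ax in seq_len(nd))
      ok <- ok & cand[, ax] >= 1 & cand[, ax] <= d[ax]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    lin <- unique(coordsToLinear(cand, d))
    lin <- lin[mask[lin] & !comp[lin]]
    if (length(lin) == 0) break
    comp[lin] <- TRUE
    frontier <- arrayInd(lin, d)
  }
  comp
}

# Label all connected components of a logical mask (full connectivity).
# Returns an integer array; 0 = background. Labels are assigned in order of
# lowest linear index, so the result is deterministic.
labelComponents <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  remaining <- which(mask)
  k <- 0L
  while (length(remaining) > 0) {
    k <- k + 1L
    comp <- floodFillComponent(mask, arrayInd(remaining[1], d)[1, ])
    lab[comp] <- k
    remaining <- remaining[!comp[remaining]]
  }
  lab
}

# Physical coordinates of 1-based voxel coordinates.
physCoords <- function(coords, spacing) {
  sweep(coords - 1, 2, spacing, `*`)
}

# Order rows of a coordinate matrix lexicographically (axis 1 first).
lexOrder <- function(coords) {
  do.call(order, lapply(seq_len(ncol(coords)), function(ax) coords[, ax]))
}
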