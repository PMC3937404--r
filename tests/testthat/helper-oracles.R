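# Independent oracles and small renderers used across the test files.
# Oracles deliberately use direct summation / pair enumeration, not the
# package's separable or contingency-table code paths.

# Mirror (half-sample symmetric) index lookup, 1-based.
reflectIndex <- function(i, n) {
  p <- 2L * n
  i <- ((i - 1L) %% p + p) %% p
  ifelse(i >= n, p - 1L - i, i) + 1L
}

# Dense LoG oracle: smooth with the full outer-product Gaussian kernel by
# direct summation (mirror boundary), then apply the 3-point second
# difference per axis by direct neighbor lookup, negate, scale by sigma^2.
denseLoGOracle <- function(data, spacing, sigma) {
  d <- dim(data)
  nd <- length(d)
  s_vox <- sigma / spacing
  ks <- lapply(s_vox, function(s) {
    h <- max(1L, as.integer(ceiling(4 * s)))
    w <- exp(-((-h):h)^2 / (2 * s^2))
    w / sum(w)
  })
  at <- function(coord) {
    c2 <- mapply(reflectIndex, coord, d)
    data[matrix(c2, 1)]
  }
  sm <- array(0, d)
  coords <- as.matrix(expand.grid(lapply(d, seq_len)))
  hs <- vapply(ks, function(k) (length(k) - 1L) / 2L, numeric(1))
  offGrid <- as.matrix(expand.grid(lapply(hs, function(h) (-h):h)))
  wts <- rep(1, nrow(offGrid))
  for (ax in seq_len(nd))
    wts <- wts * ks[[ax]][offGrid[, ax] + hs[ax] + 1]
  for (i in seq_len(nrow(coords))) {
    acc <- 0
    for (j in seq_len(nrow(offGrid)))
      acc <- acc + wts[j] * at(coords[i, ] + offGrid[j, ])
    sm[matrix(coords[i, ], 1)] <- acc
  }
  smAt <- function(coord) {
    c2 <- mapply(reflectIndex, coord, d)
    sm[matrix(c2, 1)]
  }
  lap <- array(0, d)
  for (i in seq_len(nrow(coords))) {
    acc <- 0
    for (ax in seq_len(nd)) {
      e <- rep(0L, nd); e[ax] <- 1L
      acc <- acc + (smAt(coords[i, ] + e) - 2 * smAt(coords[i, ]) +
                      smAt(coords[i, ] - e)) / spacing[ax]^2
    }
    lap[matrix(coords[i, ], 1)] <- acc
  }
  -sigma^2 * lap
}

# Centre response of the dense LoG kernel by direct summation only at one
# voxel (cheap even for 3D volumes).
denseLoGCentre <- function(data, spacing, sigma, centre) {
  d <- dim(data)
  nd <- length(d)
  s_vox <- sigma / spacing
  ks <- lapply(s_vox, function(s) {
    h <- max(1L, as.integer(ceiling(4 * s)))
    w <- exp(-((-h):h)^2 / (2 * s^2))
    w / sum(w)
  })
  at <- function(coord) {
    c2 <- mapply(reflectIndex, coord, d)
    data[matrix(c2, 1)]
  }
  smAt <- function(coord) {
    hs <- vapply(ks, function(k) (length(k) - 1L) / 2L, numeric(1))
    offGrid <- as.matrix(expand.grid(lapply(hs, function(h) (-h):h)))
    wts <- rep(1, nrow(offGrid))
    for (ax in seq_len(nd))
      wts <- wts * ks[[ax]][offGrid[, ax] + hs[ax] + 1]
    acc <- 0
    for (j in seq_len(nrow(offGrid)))
      acc <- acc + wts[j] * at(coord + offGrid[j, ])
    acc
  }
  acc <- 0
  for (ax in seq_len(nd)) {
    e <- rep(0L, nd); e[ax] <- 1L
    acc <- acc + (smAt(centre + e) - 2 * smAt(centre) + smAt(centre - e)) /
      spacing[ax]^2
  }
  -sigma^2 * acc
}

# Pair-enumeration Rand/Jaccard oracle; background voxels are singletons.
pairEnumeration <- function(ref, seg) {
  r <- as.vector(ref); s <- as.vector(seg)
  n <- length(r)
  agree <- 0; disagree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sameR <- r[i] == r[j] && r[i] > 0
    sameS <- s[i] == s[j] && s[i] > 0
    if (sameR == sameS) agree <- agree + 1 else disagree <- disagree + 1
  }
  list(ri = 100 * agree / (agree + disagree),
       ji = if (disagree == 0) Inf else agree / disagree)
}

# All-pairs Hausdorff oracle between two voxel coordinate sets.
hausdorffBrute <- function(A, B, spacing) {
  pa <- sweep(A - 1, 2, spacing, `*`)
  pb <- sweep(B - 1, 2, spacing, `*`)
  dmat <- as.matrix(stats::dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                                nrow(pa) + seq_len(nrow(pb)),
                                                drop = FALSE]
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Exhaustive Otsu oracle: explicit loop over all 256 bin boundaries.
otsuBrute <- function(values) {
  x <- as.vector(values)
  lo <- min(x); hi <- max(x)
  nb <- 256L
  edges <- seq(lo, hi, length.out = nb + 1)
  mids <- (edges[-1] + edges[-(nb + 1)]) / 2
  bin <- pmin(nb - 1L, as.integer(floor((x - lo) / (hi - lo) * nb)))
  counts <- tabulate(bin + 1L, nb)
  n <- length(x)
  best <- -Inf; bestK <- NA
  for (k in 1:(nb - 1)) {
    n0 <- sum(counts[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / n0
    m1 <- sum(counts[(k + 1):nb] * mids[(k + 1):nb]) / n1
    v <- (n0 / n) * (n1 / n) * (m0 - m1)^2
    if (v > best) { best <- v; bestK <- k }
  }
  edges[bestK + 1]
}

# Sharp rendered sphere/disk (no blur, no noise) for geometry fixtures.
renderSphere <- function(shape, spacing, centre, radius, fg = 180, bg = 20) {
  d <- as.integer(shape)
  grid <- as.matrix(expand.grid(lapply(d, seq_len)))
  phys <- sweep(grid - 1, 2, spacing, `*`)
  dist <- sqrt(rowSums(sweep(phys, 2, centre)^2))
  img <- array(bg, d)
  img[dist <= radius] <- fg
  img
}

# 2D Gaussian spot image, unit spacing, centred on a voxel.
renderSpot2D <- function(n, s0, centre = c((n + 1) / 2, (n + 1) / 2),
                         amplitude = 1) {
  x <- seq_len(n)
  outer(x, x, function(a, b)
    amplitude * exp(-((a - centre[1])^2 + (b - centre[2])^2) / (2 * s0^2)))
}

# Map a SegmentCandidate mask into the full image frame.
maskInFullFrame <- function(seg, shape) {
  m <- array(FALSE, shape)
  if (is.null(seg)) return(m)
  co <- sweep(arrayInd(which(seg@mask), dim(seg@mask)), 2, seg@offset - 1L, `+`)
  m[co] <- TRUE
  m
}

# Run the per-seed chain on one seed (crop .. extract).
segmentOneSeed <- function(volume, seed, params = twangParams()) {
  crop <- cropRegion(volume, seed)
  grad <- smoothedGradient(crop, params@gradient_sigma)
  nf <- seedNormalField(crop)
  psi <- dotProductTransform(nf$normals, grad)
  w <- weightingKernel(nf$dist, seed$radius, params@kernel_multiplier,
                       params@kernel_sigma)
  extractSegment(combineImages(crop, psi, w, seed$radius), crop, seed, params)
}
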