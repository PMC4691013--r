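# independent oracles and small utilities shared by the tests; these are
# deliberately literal implementations of the definitions, kept separate
# from the package's algorithms

# (i,j,k) zero-based coordinates for 1-based linear indices
ijk0 <- function(lin, d) {
  lin0 <- lin - 1
  cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2]))
}

# all-pairs brute-force EDT in nm
bruteEDT <- function(mask) {
  d <- dim(mask)
  lab <- maskLabels(mask)
  B <- ijk0(which(lab == 1L), d)
  A <- ijk0(seq_len(prod(d)), d)
  vals <- apply(A, 1, function(p)
    sqrt(min((B[, 1] - p[1])^2 + (B[, 2] - p[2])^2 + (B[, 3] - p[3])^2)))
  array(vals * voxelSpacing(mask), d)
}

# literal double-loop maximal-sphere painting: for each centre x visit
# every voxel y with |y - x| <= D(x) and raise the output there
brutePaint <- function(D) {
  d <- dim(D)
  s <- voxelSpacing(D)
  rv <- volumeValues(D) / s
  out <- array(0, d)
  centres <- which(rv > 0)
  C <- ijk0(centres, d)
  for (t in seq_along(centres)) {
    r <- rv[centres[t]]
    ri <- floor(r + 1e-9)
    i0 <- max(0, C[t, 1] - ri); i1 <- min(d[1] - 1, C[t, 1] + ri)
    j0 <- max(0, C[t, 2] - ri); j1 <- min(d[2] - 1, C[t, 2] + ri)
    k0 <- max(0, C[t, 3] - ri); k1 <- min(d[3] - 1, C[t, 3] + ri)
    gi <- (i0:i1) - C[t, 1]; gj <- (j0:j1) - C[t, 2]; gk <- (k0:k1) - C[t, 3]
    d2 <- outer(outer(gi^2, gj^2, "+"), gk^2, "+")
    cov <- d2 <= r * r + 1e-7
    sub <- out[(i0:i1) + 1, (j0:j1) + 1, (k0:k1) + 1]
    sub[cov] <- pmax(sub[cov], r)
    out[(i0:i1) + 1, (j0:j1) + 1, (k0:k1) + 1] <- sub
  }
  out * s
}

# plateau-merged local maxima count: candidates have no strictly higher
# neighbour; one maximum per connected candidate component
countLocalMaxima <- function(edt, connectivity = 6) {
  v <- volumeValues(edt)
  d <- dim(v)
  off <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  off <- off[!(off$a == 0 & off$b == 0 & off$c == 0), ]
  m <- abs(off$a) + abs(off$b) + abs(off$c)
  off <- off[m <= switch(as.character(connectivity),
                         "6" = 1, "18" = 2, "26" = 3), ]
  big <- array(-Inf, d + 2)
  big[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  hasHigher <- array(FALSE, d)
  for (t in seq_len(nrow(off))) {
    nb <- big[2:(d[1] + 1) + off$a[t], 2:(d[2] + 1) + off$b[t],
              2:(d[3] + 1) + off$c[t]]
    hasHigher <- hasHigher | nb > v
  }
  # a maximum is a connected equal-value plateau none of whose members
  # touches strictly higher ground
  count <- 0L
  for (val in unique(v[v > 0])) {
    comp <- connectedComponents(v == val, connectivity)
    if (comp$count == 0) next
    touched <- unique(comp$labels[comp$labels > 0 & hasHigher])
    count <- count + comp$count - length(touched)
  }
  count
}

# do two labellings define the same partition of the same support?
samePartition <- function(l1, l2) {
  if (!identical(l1 > 0, l2 > 0)) return(FALSE)
  sel <- l1 > 0
  pairs <- unique(cbind(l1[sel], l2[sel]))
  !any(duplicated(pairs[, 1])) && !any(duplicated(pairs[, 2]))
}

# evaluate a curve's accessible area at arbitrary radii (step function,
# right-continuous between the curve's own radii)
curveAreaAt <- function(curve, r) {
  tb <- curveTable(curve)
  vapply(r, function(x) {
    j <- which(tb$radius_nm >= x - 1e-9)[1]   # area(r) = area at next knot
    if (is.na(j)) 0 else tb$area_nm2[j]
  }, numeric(1))
}

# small random test mask; lumen labels guaranteed by the generator
testBlobs <- function(shape, seed, spacing = 1, porosity = 0.5) {
  randomBlobsPhantom(shape, spacing = spacing, porosity = porosity,
                     rngSeed = seed)$mask
}

# physical voxel-centre coordinate arrays (z, y, x), mirroring the package
gridCoordsT <- function(shape, spacing = 1) {
  iz <- spacing * (seq_len(shape[1]) - 1)
  iy <- spacing * (seq_len(shape[2]) - 1)
  ix <- spacing * (seq_len(shape[3]) - 1)
  list(z = array(iz, shape),
       y = array(rep(iy, each = shape[1]), shape),
       x = array(rep(ix, each = shape[1] * shape[2]), shape))
}
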