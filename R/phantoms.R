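# synthetic 3D segmentations with analytically known accessibility
# structure; every solid is rasterized by a voxel-centre inclusion test, so
# recovered radii are accurate to about one voxel.

.phantom_result <- function(labels, spacing, origin, truth) {
  list(mask = SegmentationMask(labels, spacing = spacing, origin = origin),
       truth = truth)
}

#' Solid block with a single spherical pore
#'
#' Biomass everywhere except a spherical void of radius \code{R} at the
#' grid centre; optionally opened to the x-min face by a cylindrical
#' channel. Ground truth: the CRT equals \code{R} throughout the pore, and
#' the EDT at the pore centre equals \code{R} (both up to rasterization).
#'
#' @param shape grid dimensions (z, y, x), voxels.
#' @param spacing voxel edge, nm.
#' @param R pore radius, nm (>= 2 * spacing).
#' @param openToBoundary carve a channel from the pore to the x-min face.
#' @param channelRadius channel radius, nm (defaults to \code{R}:
#'   a degenerate opening with no bottleneck).
#' @param origin grid origin, nm.
#' @return list with elements \code{mask} (a
#'   \linkS4class{SegmentationMask}) and \code{truth} (named list of the
#'   generating parameters).
#' @export
spherePorePhantom <- function(shape = c(48, 48, 48), spacing = 1, R = 8,
                              openToBoundary = FALSE, channelRadius = R,
                              origin = c(0, 0, 0)) {
  if (R < 2 * spacing) stop("pore radius must be at least 2 voxels")
  ext <- spacing * (shape - 1)
  ctr <- origin + ext / 2
  if (!openToBoundary && any(R + spacing > ext / 2))
    stop("sphere does not fit inside the grid with a biomass margin")
  g <- .grid_coords(shape, spacing, origin)
  lab <- array(1L, shape)
  pore <- (g$z - ctr[1])^2 + (g$y - ctr[2])^2 + (g$x - ctr[3])^2 <= R^2
  lab[pore] <- 0L
  if (openToBoundary) {
    chan <- g$x <= ctr[3] &
      (g$z - ctr[1])^2 + (g$y - ctr[2])^2 <= channelRadius^2
    lab[chan] <- 0L
  }
  .phantom_result(lab, spacing, origin,
                  list(radius = R, centre = ctr,
                       channelRadius = if (openToBoundary) channelRadius else NA))
}

#' Two spherical cavities joined by a cylindrical channel
#'
#' The classic bottleneck geometry: cavities of radius \code{R1} (left)
#' and \code{R2} (right) on the x axis, joined by a channel of radius
#' \code{a} (the ground-truth bottleneck). Either cavity can be opened to
#' its nearest x face by a channel of radius \code{openRadius}; with
#' \code{lumenPad > 0} a void slab labelled LUMEN fills the first
#' \code{lumenPad} nm against the x-min face, joining the left opening.
#'
#' @param shape,spacing,origin as in [spherePorePhantom()].
#' @param R1,R2 cavity radii, nm.
#' @param a channel radius, nm; must be < min(R1, R2). \code{a = 0} omits
#'   the channel (sealed right cavity).
#' @param openSide which cavities open to the boundary.
#' @param openRadius radius of the opening channels, nm.
#' @param lumenPad thickness of the LUMEN slab at the x-min face, nm
#'   (0 = none).
#' @return list(mask, truth) as in [spherePorePhantom()]; \code{truth}
#'   records the bottleneck radius and cavity centres.
#' @export
dumbbellPhantom <- function(shape = c(64, 64, 64), spacing = 1, R1 = 10,
                            R2 = 6, a = 3,
                            openSide = c("left", "right", "both", "none"),
                            openRadius = a, lumenPad = 0,
                            origin = c(0, 0, 0)) {
  openSide <- match.arg(openSide)
  if (a >= min(R1, R2))
    stop("channel radius must be smaller than both cavity radii")
  ext <- spacing * (shape - 1)
  cy <- origin[2] + ext[2] / 2
  cz <- origin[1] + ext[1] / 2
  margin <- 2 * spacing
  c1x <- origin[3] + lumenPad + margin + R1
  c2x <- origin[3] + ext[3] - margin - R2
  if (c2x - c1x <= 0) stop("geometry overflow: cavities do not fit")
  if (min(cy - origin[2], cz - origin[1]) < max(R1, R2) + spacing)
    stop("geometry overflow: cavities too wide for the grid")
  g <- .grid_coords(shape, spacing, origin)
  lab <- array(1L, shape)
  rad2 <- (g$y - cy)^2 + (g$z - cz)^2
  lab[(g$x - c1x)^2 + (g$y - cy)^2 + (g$z - cz)^2 <= R1^2] <- 0L
  lab[(g$x - c2x)^2 + (g$y - cy)^2 + (g$z - cz)^2 <= R2^2] <- 0L
  if (a > 0)
    lab[g$x >= c1x & g$x <= c2x & rad2 <= a^2] <- 0L
  if (openSide %in% c("left", "both"))
    lab[g$x <= c1x & rad2 <= openRadius^2] <- 0L
  if (openSide %in% c("right", "both"))
    lab[g$x >= c2x & rad2 <= openRadius^2] <- 0L
  if (lumenPad > 0) {
    pad <- g$x < origin[3] + lumenPad
    lab[pad] <- 0L
    lab[pad] <- 2L
  }
  .phantom_result(lab, spacing, origin,
                  list(bottleneck = a, R1 = R1, R2 = R2,
                       centre1 = c(cz, cy, c1x), centre2 = c(cz, cy, c2x),
                       openRadius = openRadius, openSide = openSide,
                       lumenPad = lumenPad))
}

#' Cell-wall slab with internal planar delaminations
#'
#' A lumen (void labelled LUMEN) fills y < \code{lumenDepth}; the rest of
#' the grid is a biomass slab crossed by \code{nGaps} planar gaps parallel
#' to the wall. The gaps span the full section (z) axis -- so they touch
#' the axial boundary faces and are reachable from a boundary seed -- but
#' keep an x margin and do not meet the lumen unless \code{connectToLumen}
#' adds a narrow cylindrical neck of radius \code{neckRadius}.
#'
#' @param shape,spacing,origin grid geometry.
#' @param nGaps number of delamination gaps.
#' @param gapHalfWidths half-widths of the gaps, nm (recycled to nGaps).
#' @param connectToLumen carve a neck from the lumen into the first gap.
#' @param neckRadius neck radius, nm.
#' @param lumenDepth lumen thickness, nm (default: a quarter of the y
#'   extent).
#' @param xMargin biomass margin left at the x faces, voxels.
#' @return list(mask, truth); truth records gap half-widths, gap centre
#'   planes and the neck radius.
#' @export
delaminatedSlabPhantom <- function(shape = c(48, 64, 64), spacing = 1,
                                   nGaps = 2, gapHalfWidths = c(2, 2),
                                   connectToLumen = FALSE, neckRadius = 1.5,
                                   lumenDepth = NULL, xMargin = 3,
                                   origin = c(0, 0, 0)) {
  ext <- spacing * (shape - 1)
  if (is.null(lumenDepth)) lumenDepth <- ext[2] / 4
  gapHalfWidths <- rep(gapHalfWidths, length.out = nGaps)
  g <- .grid_coords(shape, spacing, origin)
  lab <- array(1L, shape)
  lumen <- g$y < origin[2] + lumenDepth
  lab[lumen] <- 2L
  wall0 <- origin[2] + lumenDepth
  slab <- ext[2] - lumenDepth
  ygaps <- wall0 + seq_len(nGaps) / (nGaps + 1) * slab
  if (any(ygaps + gapHalfWidths > origin[2] + ext[2] - spacing) ||
      any(ygaps - gapHalfWidths < wall0 + spacing))
    stop("geometry overflow: gaps do not fit in the slab")
  xlo <- origin[3] + xMargin * spacing
  xhi <- origin[3] + ext[3] - xMargin * spacing
  for (gi in seq_len(nGaps)) {
    sel <- abs(g$y - ygaps[gi]) <= gapHalfWidths[gi] &
      g$x >= xlo & g$x <= xhi
    lab[sel] <- 0L
  }
  if (connectToLumen) {
    cz <- origin[1] + ext[1] / 2
    cx <- origin[3] + ext[3] / 2
    neck <- (g$z - cz)^2 + (g$x - cx)^2 <= neckRadius^2 &
      g$y >= wall0 - spacing & g$y <= ygaps[1]
    lab[neck & lab != 2L] <- 0L
  }
  .phantom_result(lab, spacing, origin,
                  list(gapHalfWidths = gapHalfWidths, gapCentres = ygaps,
                       neckRadius = if (connectToLumen) neckRadius else NA,
                       lumenDepth = lumenDepth))
}

#' Rough (or flat) wall with no internal cavities
#'
#' A biomass wall fills y below an undulating height field
#' \code{wallDepth + amplitude * sin(2*pi*x/wavelength + phase)}, with the
#' phase drawn reproducibly from \code{rngSeed}. With
#' \code{amplitude = 0} the wall is planar. The void far from the wall
#' (top quarter of y by default) is labelled LUMEN.
#'
#' The ridges run along z, the section axis, so the geometry is invariant
#' through the axial faces -- as in a tomogram of a wall whose lumen
#' continues beyond the imaged sections. The default amplitude/wavelength
#' keep the surface slope below 1, so the void is star-shaped away from
#' the wall and contains no bottlenecks: the texture-only, no-cavity
#' reference geometry in which every seed strategy sees the same
#' accessibility.
#'
#' @param shape,spacing,origin grid geometry.
#' @param amplitude roughness amplitude, nm.
#' @param wavelength roughness wavelength, nm.
#' @param rngSeed integer seed for the roughness phases.
#' @param wallDepth mean wall thickness, nm (default: a quarter of the y
#'   extent).
#' @param lumenDepth thickness of the LUMEN slab at the y-max side, nm.
#' @return list(mask, truth).
#' @export
roughWallPhantom <- function(shape = c(48, 48, 48), spacing = 1,
                             amplitude = 4, wavelength = 32, rngSeed = 1,
                             wallDepth = NULL, lumenDepth = NULL,
                             origin = c(0, 0, 0)) {
  ext <- spacing * (shape - 1)
  if (is.null(wallDepth)) wallDepth <- ext[2] / 4
  if (is.null(lumenDepth)) lumenDepth <- ext[2] / 4
  phase <- .with_seed(rngSeed, runif(1, 0, 2 * pi))
  g <- .grid_coords(shape, spacing, origin)
  h <- wallDepth + amplitude * sin(2 * pi * g$x / wavelength + phase)
  lab <- array(0L, shape)
  lab[g$y <= origin[2] + h] <- 1L
  lum <- g$y >= origin[2] + ext[2] - lumenDepth & lab == 0L
  lab[lum] <- 2L
  .phantom_result(lab, spacing, origin,
                  list(amplitude = amplitude, wavelength = wavelength,
                       wallDepth = wallDepth, phase = phase,
                       rngSeed = rngSeed))
}

#' Irregular porous mask from thresholded smoothed noise
#'
#' White noise smoothed with a Gaussian kernel and thresholded at the
#' quantile matching the target porosity; void voxels in the first slabs
#' of the x axis are labelled LUMEN so every seed strategy is exercisable.
#' Used for oracle-equivalence property tests on irregular geometry.
#'
#' @param shape,spacing,origin grid geometry.
#' @param porosity target void fraction in (0, 1).
#' @param kernelSd Gaussian kernel standard deviation, voxels.
#' @param rngSeed integer seed (mandatory for reproducibility).
#' @param lumenFraction fraction of the x extent whose void voxels are
#'   labelled LUMEN (grown until at least one void voxel is found).
#' @return list(mask, truth).
#' @export
randomBlobsPhantom <- function(shape = c(16, 16, 16), spacing = 1,
                               porosity = 0.5, kernelSd = 1.5, rngSeed = 1,
                               lumenFraction = 0.15, origin = c(0, 0, 0)) {
  stopifnot(porosity > 0, porosity < 1)
  noise <- .with_seed(rngSeed, array(rnorm(prod(shape)), shape))
  sm <- .smooth_gaussian(noise, kernelSd)
  cut <- quantile(sm, 1 - porosity, names = FALSE)
  lab <- array(1L, shape)
  lab[sm >= cut] <- 0L
  if (!any(lab == 1L)) lab[1, 1, 1] <- 1L
  if (!any(lab == 0L)) lab[shape[1], shape[2], shape[3]] <- 0L
  nx <- shape[3]
  kmax <- max(1L, ceiling(lumenFraction * nx))
  repeat {
    sel <- lab[, , seq_len(kmax), drop = FALSE] == 0L
    if (any(sel) || kmax >= nx) break
    kmax <- kmax + 1L
  }
  sub <- lab[, , seq_len(kmax), drop = FALSE]
  sub[sub == 0L] <- 2L
  lab[, , seq_len(kmax)] <- sub
  .phantom_result(lab, spacing, origin,
                  list(porosity = porosity, kernelSd = kernelSd,
                       rngSeed = rngSeed, lumenSlabs = kmax))
}

#' Write a phantom's ground-truth record as a key-value sidecar file
#'
#' @param truth the \code{truth} list returned by a phantom generator.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGroundTruth <- function(truth, path) {
  writeLines(.key_value_lines(truth), path)
  invisible(path)
}
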