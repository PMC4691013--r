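# surface extraction, range-of-interaction sampling, area curves, stats

voxelBall <- function(R, n, spacing = 1) {
  ctr <- spacing * (n - 1) / 2
  g <- expand.grid(i = seq_len(n) - 1, j = seq_len(n) - 1, k = seq_len(n) - 1)
  lab <- array(0L, c(n, n, n))
  lab[(g$i * spacing - ctr)^2 + (g$j * spacing - ctr)^2 +
        (g$k * spacing - ctr)^2 <= R^2] <- 1L
  SegmentationMask(lab, spacing = spacing)
}

test_that("mesh area approximates analytic references within 5%", {
  ball <- voxelBall(20, 47)
  expect_lt(abs(meshArea(extractSurface(ball)) / (4 * pi * 400) - 1), 0.05)

  lab <- array(0L, c(30, 30, 30))
  lab[6:25, 6:25, 6:25] <- 1L   # 20^3-voxel box; offset surface side 20
  expect_lt(abs(meshArea(extractSurface(SegmentationMask(lab))) / 2400 - 1),
            0.05)
})

test_that("a single biomass voxel still yields a closed positive-area mesh", {
  lab <- array(0L, c(9, 9, 9))
  lab[5, 5, 5] <- 1L
  m <- extractSurface(SegmentationMask(lab))
  expect_gt(meshArea(m), 0)
  # closedness: every undirected edge is shared by exactly two triangles
  tr <- meshTriangles(m)
  edges <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
})

test_that("degenerate masks are rejected", {
  expect_error(extractSurface(SegmentationMask(array(1L, c(4, 4, 4)))),
               "all biomass")
  expect_error(extractSurface(SegmentationMask(array(0L, c(4, 4, 4)))),
               "all void")
})

test_that("vertex accessibility reads the max aCRT within epsilon", {
  # sealed gaps under lumen seeding read exactly zero at the default epsilon
  ph <- delaminatedSlabPhantom(c(32, 40, 40), 1, nGaps = 1,
                               gapHalfWidths = 2)
  mask <- ph$mask
  edt <- computeEDT(mask)
  al <- computeACRT(computeAEDT(edt, tagTree(buildContourTree(edt),
                                             selectSeed(mask, "lumen"))))
  mesh <- extractSurface(mask)
  acc <- sampleSurfaceAccessibility(mesh, al)
  v <- meshVertices(mesh)
  gap <- abs(v[, 2] - ph$truth$gapCentres[1]) < 2.2
  expect_gt(sum(gap), 100)
  expect_true(all(acc[gap] == 0))
  # lumen-facing wall vertices read a positive value
  expect_true(any(acc[v[, 2] < ph$truth$lumenDepth + 1] > 0))

  # vertexwise monotone in epsilon
  acc2 <- sampleSurfaceAccessibility(mesh, al, epsilon = 2.5)
  expect_true(all(acc2 >= acc))

  expect_error(sampleSurfaceAccessibility(mesh, al, epsilon = 0),
               "positive")
  other <- computeEDT(testBlobs(c(8, 8, 8), seed = 1))
  other@role <- "crt"
  expect_error(sampleSurfaceAccessibility(mesh, other), "grid mismatch")
})

test_that("area curves are exact at r = 0, vanish past the maximum, and decrease", {
  ph <- dumbbellPhantom(c(64, 64, 64), 1, R1 = 10, R2 = 6, a = 3,
                        openSide = "left", openRadius = 6, lumenPad = 4)
  mask <- ph$mask
  edt <- computeEDT(mask)
  acrt <- computeACRT(computeAEDT(edt, tagTree(buildContourTree(edt),
                                               selectSeed(mask, "lumen"))))
  mesh <- extractSurface(mask)
  acc <- sampleSurfaceAccessibility(mesh, acrt)
  cv <- accessibleAreaCurve(mesh, acc, strategy = "lumen")
  tb <- curveTable(cv)
  expect_identical(tb$area_nm2[1], meshArea(mesh))
  expect_identical(tb$frac_total_area[1], 1)
  expect_true(all(diff(tb$area_nm2) <= 1e-9))
  expect_identical(curveAreaAt(cv, max(acc) + 1), 0)

  # the drop across the bottleneck equals the area sealed behind it:
  # right cavity (minus the channel cap) plus the channel lateral wall
  lo <- curveAreaAt(cv, 2.6)
  hi <- curveAreaAt(cv, 3.2)
  chanLen <- (ph$truth$centre2[3] - ph$truth$centre1[3]) -
    sqrt(10^2 - 3^2) - sqrt(6^2 - 3^2)
  expected <- 4 * pi * 36 - 2 * pi * 6 * (6 - sqrt(36 - 9)) +
    2 * pi * 3 * chanLen
  expect_lt(abs((lo - hi) / expected - 1), 0.10)

  # explicit radius grids and the mean-vertex rule stay monotone
  cv2 <- accessibleAreaCurve(mesh, acc, radii = seq(0, 8, by = 0.5),
                             rule = "mean")
  expect_true(all(diff(curveTable(cv2)$area_nm2) <= 1e-9))
  expect_error(accessibleAreaCurve(mesh, acc, radii = numeric(0)), "empty")
  expect_error(accessibleAreaCurve(mesh, acc[-1]), "per vertex")
})

test_that("biomass statistics match analytic references", {
  lab <- array(0L, c(14, 14, 14))
  lab[3:12, 3:12, 3:12] <- 1L
  mask <- SegmentationMask(lab, spacing = 2)
  mesh <- extractSurface(mask)
  st <- biomassStats(mask, mesh)
  expect_identical(st$biomassVolume_nm3, 1000 * 8)   # count * spacing^3
  expect_equal(st$biomassVolume_um3, 8e-6)

  ball <- voxelBall(20, 47)
  stb <- biomassStats(ball, extractSurface(ball))
  expect_lt(abs(stb$surfaceArea_nm2 / stb$biomassVolume_nm3 / (3 / 20) - 1),
            0.10)

  rough <- roughWallPhantom(c(32, 32, 32), 1, amplitude = 6,
                            wavelength = 20, rngSeed = 3)
  flat <- roughWallPhantom(c(32, 32, 32), 1, amplitude = 0, rngSeed = 3)
  rr <- biomassStats(rough$mask, extractSurface(rough$mask))
  rf <- biomassStats(flat$mask, extractSurface(flat$mask))
  expect_gt(rr$areaToVolume_per_um, rf$areaToVolume_per_um)
})

test_that("delaminations sealed off from the lumen do not change the lumen curve", {
  gaps <- delaminatedSlabPhantom(c(28, 40, 40), 1, nGaps = 2,
                                 gapHalfWidths = c(2, 2))
  nogap <- delaminatedSlabPhantom(c(28, 40, 40), 1, nGaps = 0,
                                  gapHalfWidths = numeric(0))
  curves <- lapply(list(gaps, nogap), function(ph) {
    mask <- ph$mask
    edt <- computeEDT(mask)
    acrt <- computeACRT(computeAEDT(edt, tagTree(buildContourTree(edt),
                                                 selectSeed(mask, "lumen"))))
    mesh <- extractSurface(mask)
    accessibleAreaCurve(mesh, sampleSurfaceAccessibility(mesh, acrt))
  })
  rs <- seq(0.5, 12, by = 0.5)   # r = 0 counts total area, which differs
  expect_equal(curveAreaAt(curves[[1]], rs), curveAreaAt(curves[[2]], rs),
               tolerance = 1e-9)
})
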