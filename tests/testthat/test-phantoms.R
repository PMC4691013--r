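# phantom generators and their ground-truth records

test_that("sphere pore phantom has the stated EDT and CRT", {
  ph <- spherePorePhantom(c(41, 41, 41), spacing = 1, R = 8)
  edt <- computeEDT(ph$mask)
  ctr <- round(ph$truth$centre) + 1
  expect_lt(abs(volumeValues(edt)[ctr[1], ctr[2], ctr[3]] - 8), 0.5 + 1e-9)
  crt <- sphereMaxPaint(edt)
  pore <- maskLabels(ph$mask) != 1L
  expect_true(all(abs(volumeValues(crt)[pore] - 8) <= 1 + 1e-9))
  # against the literal painting oracle
  expect_equal(volumeValues(crt), brutePaint(edt), tolerance = 0)
})

test_that("degenerate opening (channel = R) leaves no bottleneck: boundary aCRT equals CRT", {
  ph <- spherePorePhantom(c(41, 41, 41), spacing = 1, R = 8,
                          openToBoundary = TRUE, channelRadius = 8)
  edt <- computeEDT(ph$mask)
  crt <- sphereMaxPaint(edt)
  tree <- buildContourTree(edt)
  seed <- selectSeed(ph$mask, "boundary", faces = "x-")
  acrt <- computeACRT(computeAEDT(edt, tagTree(tree, seed)))
  expect_equal(volumeValues(acrt), volumeValues(crt), tolerance = 0)
})

test_that("dumbbell phantom recovers bottleneck and cavity radii", {
  ph <- dumbbellPhantom(c(64, 64, 64), 1, R1 = 10, R2 = 6, a = 3,
                        openSide = "left")
  edt <- computeEDT(ph$mask)
  c2 <- round(ph$truth$centre2) + 1
  # plain CRT at the right cavity centre recovers R2
  crt <- sphereMaxPaint(edt)
  expect_lt(abs(volumeValues(crt)[c2[1], c2[2], c2[3]] - 6), 1 + 1e-9)
  # boundary-seeded aCRT in the right cavity recovers the bottleneck,
  # cross-checked against the widest-path oracle
  seed <- selectSeed(ph$mask, "boundary", faces = "x-")
  aedt <- aedtWidestPathOracle(edt, seed)
  acrt <- sphereMaxPaint(aedt)
  expect_lt(abs(volumeValues(acrt)[c2[1], c2[2], c2[3]] - 3), 1 + 1e-9)
})

test_that("a sealed cavity (a = 0) is tagged inaccessible", {
  ph <- dumbbellPhantom(c(48, 48, 48), 1, R1 = 8, R2 = 5, a = 0,
                        openSide = "left", openRadius = 4)
  edt <- computeEDT(ph$mask)
  seed <- selectSeed(ph$mask, "boundary", faces = "x-")
  aedt <- computeAEDT(edt, tagTree(buildContourTree(edt), seed))
  c2 <- round(ph$truth$centre2) + 1
  expect_identical(volumeValues(aedt)[c2[1], c2[2], c2[3]], 0)
})

test_that("delaminated slab: gaps carry their half-width from the boundary, the neck radius from the lumen", {
  ph <- delaminatedSlabPhantom(c(40, 48, 48), 1, nGaps = 2,
                               gapHalfWidths = c(2, 2))
  edt <- computeEDT(ph$mask)
  gy <- round(ph$truth$gapCentres) + 1
  sb <- selectSeed(ph$mask, "boundary")   # default axial (z) faces
  ab <- sphereMaxPaint(aedtWidestPathOracle(edt, sb))
  for (g in gy)
    expect_lt(abs(volumeValues(ab)[20, g, 24] - 2), 1 + 1e-9)
  # gaps do not reach the lumen
  sl <- selectSeed(ph$mask, "lumen")
  al <- sphereMaxPaint(aedtWidestPathOracle(edt, sl))
  expect_identical(volumeValues(al)[20, gy[1], 24], 0)

  ph2 <- delaminatedSlabPhantom(c(40, 48, 48), 1, nGaps = 2,
                                gapHalfWidths = c(2, 2),
                                connectToLumen = TRUE, neckRadius = 1)
  edt2 <- computeEDT(ph2$mask)
  al2 <- sphereMaxPaint(aedtWidestPathOracle(edt2,
                                             selectSeed(ph2$mask, "lumen")))
  gapval <- volumeValues(al2)[20, gy[1], 24]
  expect_gt(gapval, 0)
  expect_lt(abs(gapval - 1), 1 + 1e-9)    # neck radius +- 1 voxel
})

test_that("rough wall: amplitude 0 is planar; fixed seed reproduces; roughness adds area", {
  flat <- roughWallPhantom(c(32, 32, 32), 1, amplitude = 0, rngSeed = 1)
  lab <- maskLabels(flat$mask)
  perSlab <- apply(lab == 1L, 2, sum)
  expect_true(all(perSlab %in% c(0L, 32L * 32L)))   # full or empty y slabs
  again <- roughWallPhantom(c(32, 32, 32), 1, amplitude = 6,
                            wavelength = 20, rngSeed = 9)
  once <- roughWallPhantom(c(32, 32, 32), 1, amplitude = 6,
                           wavelength = 20, rngSeed = 9)
  expect_identical(maskLabels(again$mask), maskLabels(once$mask))
  rough <- roughWallPhantom(c(40, 40, 40), 1, amplitude = 6,
                            wavelength = 20, rngSeed = 3)
  flat2 <- roughWallPhantom(c(40, 40, 40), 1, amplitude = 0, rngSeed = 3)
  expect_gt(meshArea(extractSurface(rough$mask)),
            meshArea(extractSurface(flat2$mask)))
})

test_that("phantoms are reproducible from their spec and write ground truth sidecars", {
  a <- randomBlobsPhantom(c(12, 12, 12), rngSeed = 4)
  b <- randomBlobsPhantom(c(12, 12, 12), rngSeed = 4)
  expect_identical(maskLabels(a$mask), maskLabels(b$mask))
  f <- file.path(tempdir(), "truth.txt")
  writeGroundTruth(a$truth, f)
  lines <- readLines(f)
  expect_true(any(grepl("^porosity = 0.5", lines)))
})

test_that("phantom geometry that does not fit is rejected", {
  expect_error(spherePorePhantom(c(16, 16, 16), 1, R = 10), "fit")
  expect_error(dumbbellPhantom(c(24, 24, 24), 1, R1 = 10, R2 = 9, a = 3),
               "overflow|fit")
  expect_error(dumbbellPhantom(c(64, 64, 64), 1, R1 = 10, R2 = 6, a = 7),
               "channel radius")
})
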