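# seed regions, tagging, aEDT / aCRT, and the oracle equivalences

test_that("seed selection implements the three strategies", {
  lab <- array(1L, c(8, 10, 10))
  lab[, , 7:10] <- 0L
  lab[, , 9:10] <- 2L                      # a lumen slab
  mask <- SegmentationMask(lab)
  sl <- selectSeed(mask, "lumen")
  expect_identical(seedVoxels(sl), which(lab == 2L))

  # default boundary faces are normal to the thinnest axis
  mask2 <- testBlobs(c(8, 16, 16), seed = 2)
  sb <- selectSeed(mask2, "boundary")
  expect_identical(sb@faces, c("z-", "z+"))
  d <- dim(mask2)
  onface <- arrayInd(seedVoxels(sb), d)[, 1]
  expect_true(all(onface %in% c(1L, d[1])))
  expect_true(all(maskLabels(mask2)[seedVoxels(sb)] != 1L))

  sn <- selectSeed(mask, "none")
  expect_length(seedVoxels(sn), 0)

  expect_error(selectSeed(SegmentationMask(array(c(0L, 1L), c(4, 4, 4))),
                          "lumen"), "LUMEN")
  solid <- SegmentationMask(array(1L, c(4, 4, 4)))
  expect_error(selectSeed(solid, "boundary"), "empty seed")
  expect_error(selectSeed(mask, "boundary", faces = "w+"), "unknown faces")
})

test_that("a convex void seeded at the boundary is fully accessible: aEDT = EDT", {
  lab <- array(0L, c(16, 16, 16))
  lab[, 1:4, ] <- 1L                        # wall at low y, convex void above
  mask <- SegmentationMask(lab)
  edt <- computeEDT(mask)
  seed <- selectSeed(mask, "boundary", faces = c("y+"))
  tagged <- tagTree(buildContourTree(edt), seed)
  expect_true(all(is.infinite(arcTags(tagged))))
  expect_identical(volumeValues(computeAEDT(edt, tagged)),
                   volumeValues(edt))
})

test_that("the dumbbell right cavity is governed by the bottleneck", {
  ph <- dumbbellPhantom(c(64, 64, 64), 1, R1 = 10, R2 = 6, a = 3,
                        openSide = "left")
  edt <- computeEDT(ph$mask)
  tree <- buildContourTree(edt)
  seed <- selectSeed(ph$mask, "boundary", faces = "x-")
  tagged <- tagTree(tree, seed)
  aedt <- computeAEDT(edt, tagged)
  c2 <- round(ph$truth$centre2) + 1
  expect_lt(abs(volumeValues(aedt)[c2[1], c2[2], c2[3]] - 3), 1 + 1e-9)
  # near the right cavity wall, where EDT < bottleneck, aEDT follows EDT
  nearwall <- volumeValues(edt) > 0 & volumeValues(edt) < 2 &
    voxelArcMap(tree) > 0
  rightish <- array(FALSE, dim(edt))
  rightish[, , 50:64] <- TRUE
  sel <- nearwall & rightish & volumeValues(aedt) > 0
  expect_gt(sum(sel), 0)
  expect_identical(volumeValues(aedt)[sel], volumeValues(edt)[sel])
  # the right-cavity subtree tag equals the saddle level
  saddle <- treeNodes(tree)$value[treeNodes(tree)$kind == "branch"]
  rightArc <- voxelArcMap(tree)[c2[1], c2[2], c2[3]]
  expect_identical(arcTags(tagged)[rightArc], min(saddle))
})

test_that("contour-tree aEDT equals both independent oracles on irregular masks", {
  for (seed in c(0, 1, 2, 3, 4)) {
    mask <- testBlobs(c(16, 16, 16), seed = seed)
    edt <- computeEDT(mask)
    for (conn in c(6, 26)) {
      tree <- buildContourTree(edt, connectivity = conn)
      for (st in c("lumen", "boundary", "none")) {
        sd <- selectSeed(mask, st)
        aedt <- computeAEDT(edt, tagTree(tree, sd))
        o1 <- aedtWidestPathOracle(edt, sd, conn)
        o2 <- aedtFloodSweepOracle(edt, sd, conn)
        expect_equal(volumeValues(aedt), volumeValues(o1), tolerance = 0)
        expect_equal(volumeValues(o1), volumeValues(o2), tolerance = 0)
      }
    }
  }
})

test_that("aEDT and aCRT never exceed their unrestricted counterparts", {
  mask <- testBlobs(c(16, 16, 16), seed = 6)
  edt <- computeEDT(mask)
  crt <- sphereMaxPaint(edt)
  tree <- buildContourTree(edt)
  for (st in c("lumen", "boundary")) {
    aedt <- computeAEDT(edt, tagTree(tree, selectSeed(mask, st)))
    expect_true(all(volumeValues(aedt) <= volumeValues(edt) + 1e-12))
    acrt <- computeACRT(aedt)
    expect_true(all(volumeValues(acrt) <= volumeValues(crt) + 1e-12))
    expect_identical(volumeRole(acrt), "acrt")
  }
})

test_that("growing the seed region can only increase the aEDT", {
  mask <- testBlobs(c(14, 14, 14), seed = 9)
  edt <- computeEDT(mask)
  tree <- buildContourTree(edt)
  lum <- selectSeed(mask, "lumen")
  half <- new("SeedRegion", strategy = "lumen",
              voxels = seedVoxels(lum)[seq(1, length(seedVoxels(lum)), 2)],
              faces = character(0), dim = dim(mask))
  a1 <- computeAEDT(edt, tagTree(tree, half))
  a2 <- computeAEDT(edt, tagTree(tree, lum))
  expect_true(all(volumeValues(a1) <= volumeValues(a2) + 1e-12))
})

test_that("strategy ordering holds voxelwise: lumen <= boundary <= none", {
  ph <- delaminatedSlabPhantom(c(32, 40, 40), 1, nGaps = 2,
                               gapHalfWidths = c(2, 2))
  mask <- ph$mask
  edt <- computeEDT(mask)
  tree <- buildContourTree(edt)
  crt <- sphereMaxPaint(edt)
  al <- computeACRT(computeAEDT(edt, tagTree(tree, selectSeed(mask, "lumen"))))
  ab <- computeACRT(computeAEDT(edt, tagTree(tree, selectSeed(mask, "boundary"))))
  expect_true(all(volumeValues(al) <= volumeValues(ab) + 1e-12))
  expect_true(all(volumeValues(ab) <= volumeValues(crt) + 1e-12))
})

test_that("strategy 'none' reproduces the plain CRT", {
  mask <- testBlobs(c(12, 12, 12), seed = 21)
  edt <- computeEDT(mask)
  tree <- buildContourTree(edt)
  aedt <- computeAEDT(edt, tagTree(tree, selectSeed(mask, "none")))
  expect_identical(volumeValues(aedt), volumeValues(edt))
  expect_identical(volumeValues(computeACRT(aedt)),
                   volumeValues(sphereMaxPaint(edt)))
})

test_that("grid mismatches and empty seeds are rejected", {
  mask <- testBlobs(c(10, 10, 10), seed = 1)
  edt <- computeEDT(mask)
  tree <- buildContourTree(edt)
  other <- computeEDT(testBlobs(c(10, 10, 10), seed = 2))
  tagged <- tagTree(tree, selectSeed(mask, "boundary"))
  expect_error(computeAEDT(other, tagged), "mismatched grids")
  empty <- new("SeedRegion", strategy = "lumen", voxels = integer(0),
               faces = character(0), dim = dim(mask))
  expect_error(tagTree(tree, empty), "empty seed")
})
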