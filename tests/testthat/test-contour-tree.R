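# join tree construction and the Void(r) index it provides

test_that("a single spherical pore gives one leaf and one root", {
  ph <- spherePorePhantom(c(32, 32, 32), 1, R = 6)
  tree <- buildContourTree(computeEDT(ph$mask))
  k <- table(treeNodes(tree)$kind)
  expect_identical(unname(k["leaf"]), 1L)
  expect_identical(unname(k["root"]), 1L)
})

test_that("the closed dumbbell has two leaves and a saddle at the channel radius", {
  ph <- dumbbellPhantom(c(48, 48, 48), 1, R1 = 8, R2 = 5, a = 2,
                        openSide = "none")
  tree <- buildContourTree(computeEDT(ph$mask))
  nodes <- treeNodes(tree)
  expect_identical(sum(nodes$kind == "leaf"), 2L)
  expect_identical(sum(nodes$kind == "branch"), 1L)
  expect_lt(abs(nodes$value[nodes$kind == "branch"] - 2), 1 + 1e-9)
})

test_that("leaf count equals the plateau-merged local-maximum count", {
  for (seed in c(11, 23)) {
    edt <- computeEDT(testBlobs(c(20, 20, 20), seed = seed))
    for (conn in c(6, 26)) {
      tree <- buildContourTree(edt, connectivity = conn)
      expect_identical(sum(treeNodes(tree)$kind == "leaf"),
                       countLocalMaxima(edt, conn))
    }
  }
})

test_that("tree structural invariants hold", {
  edt <- computeEDT(testBlobs(c(18, 18, 18), seed = 13))
  tree <- buildContourTree(edt)
  nodes <- treeNodes(tree)
  arcs <- treeArcs(tree)
  # along every arc the level strictly decreases
  expect_true(all(nodes$value[arcs$upper] > nodes$value[arcs$lower]))
  # every void voxel maps to exactly one arc whose span holds its value
  va <- voxelArcMap(tree)
  void <- volumeValues(edt) > 0
  expect_true(all(va[void] > 0L))
  expect_true(all(va[!void] == 0L))
  v <- volumeValues(edt)[void]
  a <- va[void]
  expect_true(all(v <= nodes$value[arcs$upper][a] + 1e-12))
  expect_true(all(v > nodes$value[arcs$lower][a] - 1e-12))
  # one root per connected component of Void(0)
  expect_identical(sum(nodes$kind == "root"),
                   connectedComponents(void, 6)$count)
  # merges are at least binary: leaves - roots >= branches
  expect_gte(sum(nodes$kind == "leaf") - sum(nodes$kind == "root"),
             sum(nodes$kind == "branch"))
})

test_that("treeComponentsAt is a lossless index of Void(r) connectivity", {
  edt <- computeEDT(testBlobs(c(16, 16, 16), seed = 17))
  tree <- buildContourTree(edt)
  rmax <- max(volumeValues(edt))
  for (r in seq(0, rmax * 0.999, length.out = 20)) {
    direct <- connectedComponents(thresholdVoid(edt, r), 6)
    fromTree <- treeComponentsAt(tree, r)
    expect_identical(fromTree$count, direct$count)
    expect_true(samePartition(fromTree$labels, direct$labels))
  }
  # above the global maximum the partition is empty
  expect_identical(treeComponentsAt(tree, rmax)$count, 0L)
  # r = 0: one component per root
  expect_identical(treeComponentsAt(tree, 0)$count,
                   sum(treeNodes(tree)$kind == "root"))
})

test_that("an edge list can be exported for inspection", {
  ph <- dumbbellPhantom(c(48, 48, 48), 1, R1 = 8, R2 = 5, a = 2,
                        openSide = "none")
  tree <- buildContourTree(computeEDT(ph$mask))
  f <- file.path(tempdir(), "tree.csv")
  writeTreeEdgeList(tree, f)
  df <- read.csv(f)
  expect_identical(nrow(df), nrow(treeArcs(tree)))
  expect_true(all(df$upper_value_nm > df$lower_value_nm))
})
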