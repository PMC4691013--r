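# volume, mesh and curve I/O

float32safe <- function(x) sample(0:1000, x, replace = TRUE) / 64

test_that("MRC round trip preserves values, spacing and origin", {
  set.seed(7)
  v <- ScalarVolume(array(float32safe(16^3), c(16, 16, 16)), spacing = 2,
                    origin = c(1, 2, 3))
  f <- file.path(tempdir(), "rt.mrc")
  writeVolume(v, f)
  r <- readVolume(f)
  expect_identical(volumeValues(r), volumeValues(v))
  expect_equal(voxelSpacing(r), 2)
  expect_equal(voxelOrigin(r), c(1, 2, 3))
})

test_that("MRC spacing honours the unit override (angstrom to nm)", {
  v <- ScalarVolume(array(0, c(4, 4, 4)), spacing = 2.2)
  f <- file.path(tempdir(), "unit.mrc")
  writeVolume(v, f)
  r <- readVolume(f, units = "angstrom")
  expect_equal(voxelSpacing(r), 0.22, tolerance = 1e-6)  # float32 header
})

test_that("NRRD round trip is bitwise and keeps the role metadata", {
  set.seed(7)
  v <- ScalarVolume(array(rnorm(8^3), c(8, 8, 8)), spacing = 1.5,
                    origin = c(0, 0.5, 1))
  v@values <- abs(v@values)
  v@role <- "edt"
  f <- file.path(tempdir(), "rt.nrrd")
  writeVolume(v, f)
  r <- readVolume(f)
  expect_identical(volumeValues(r), volumeValues(v))
  expect_identical(volumeRole(r), "edt")
  expect_equal(voxelSpacing(r), 1.5)
  expect_equal(voxelOrigin(r), c(0, 0.5, 1))
})

test_that("anisotropic NRRD spacing is rejected, naming the values", {
  f <- file.path(tempdir(), "aniso.nrrd")
  con <- file(f, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3",
               "sizes: 2 2 2", "spacings: 2.0 2.0 2.6",
               "endian: little", "encoding: raw", ""), con)
  writeBin(as.numeric(1:8), con, size = 8, endian = "little")
  close(con)
  expect_error(readVolume(f), "anisotropic.*2\\.6")
})

test_that("TIFF stack round trips [0,1] float data; spacing is caller-supplied", {
  set.seed(7)
  v <- ScalarVolume(array(sample(0:255, 6^3, TRUE) / 255, c(6, 6, 6)),
                    spacing = 2)
  f <- file.path(tempdir(), "rt.tif")
  writeVolume(v, f)
  expect_error(readVolume(f), "spacing")
  r <- readVolume(f, spacing = 2)
  expect_equal(volumeValues(r), volumeValues(v), tolerance = 1e-7)
  expect_error(writeVolume(ScalarVolume(array(5, c(2, 2, 2))),
                           file.path(tempdir(), "bad.tif")),
               "\\[0, 1\\]")
})

test_that("writing into a missing directory fails cleanly", {
  v <- ScalarVolume(array(0, c(2, 2, 2)))
  expect_error(writeVolume(v, "/nonexistent-dir-xyz/a.nrrd"),
               "directory does not exist")
})

test_that("thresholdSegment labels dark voxels as biomass and warns on degenerate cutoffs", {
  vals <- array(c(100, 150), c(4, 4, 4))
  v <- ScalarVolume(vals)
  m <- thresholdSegment(v, 130)
  expect_identical(maskLabels(m) == 1L, vals < 130)
  expect_false(any(maskLabels(m) == 2L))
  expect_warning(thresholdSegment(v, min(vals)), "all-void")
  expect_warning(thresholdSegment(v, max(vals) + 1), "all-biomass")
})

test_that("thresholdSegment is monotone in the cutoff", {
  set.seed(11)
  v <- ScalarVolume(array(runif(10^3, 0, 100), c(10, 10, 10)))
  cuts <- c(20, 40, 60, 80)
  prev <- array(FALSE, dim(v))
  for (ct in cuts) {
    cur <- maskLabels(thresholdSegment(v, ct)) == 1L
    expect_true(all(cur[prev]))   # raising the cutoff never removes biomass
    prev <- cur
  }
})

test_that("noisy two-intensity phantom is segmented with >= 99% agreement", {
  ph <- randomBlobsPhantom(c(16, 16, 16), rngSeed = 5)
  truthBio <- maskLabels(ph$mask) == 1L
  set.seed(6)
  inten <- ifelse(truthBio, 100, 150) +
    rnorm(length(truthBio), sd = 0.05 * 150)
  v <- ScalarVolume(array(inten, dim(truthBio)))
  m <- thresholdSegment(v, 125)
  agree <- mean((maskLabels(m) == 1L) == truthBio)
  expect_gte(agree, 0.99)
})

test_that("mesh round trips through PLY, OBJ and VTK", {
  tri <- new("SurfaceMesh",
             vertices = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE),
             triangles = matrix(c(1L, 2L, 3L), 1),
             vertexData = data.frame(accessibility = c(0.5, 1.25, 2)),
             provenance = list())
  for (fmt in c("ply", "obj", "vtk")) {
    f <- file.path(tempdir(), paste0("tri.", fmt))
    writeMesh(tri, f)
    r <- readMesh(f)
    expect_equal(meshVertices(r), meshVertices(tri), tolerance = 1e-7)
    expect_identical(meshTriangles(r), meshTriangles(tri))
  }
  r <- readMesh(file.path(tempdir(), "tri.ply"))
  expect_equal(vertexData(r)$accessibility, c(0.5, 1.25, 2),
               tolerance = 1e-7)
})

test_that("curves round trip with the documented column headers", {
  cv <- new("AccessibilityCurve", radii = c(0, 1, 2),
            area = c(30, 20, 10), fracTotalArea = c(1, 2 / 3, 1 / 3),
            areaPerVol = c(3, 2, 1), strategy = "lumen", totalArea = 30,
            biomassVolume = 1e4)
  for (fmt in c("csv", "tsv")) {
    f <- file.path(tempdir(), paste0("curve.", fmt))
    writeCurve(cv, f)
    hdr <- readLines(f, n = 1)
    for (col in c("radius_nm", "area_nm2", "frac_total_area",
                  "area_per_biomass_vol_per_um"))
      expect_match(hdr, col)
    r <- readCurve(f, strategy = "lumen")
    expect_equal(r@radii, cv@radii)
    expect_equal(r@area, cv@area)
  }
})

test_that("label volumes round trip and coerce back to masks", {
  ph <- randomBlobsPhantom(c(8, 8, 8), rngSeed = 2)
  f <- file.path(tempdir(), "mask.nrrd")
  writeVolume(ScalarVolume(array(as.double(maskLabels(ph$mask)), c(8, 8, 8)),
                           spacing = 1), f)
  m <- asSegmentationMask(readVolume(f))
  expect_identical(maskLabels(m), maskLabels(ph$mask))
})
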