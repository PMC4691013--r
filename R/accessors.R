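# generics, accessors and show methods

#' @rdname accessors
#' @param x an object from this package.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Accessors for grid-backed objects
#'
#' \code{voxelSpacing}, \code{voxelOrigin} return the grid geometry;
#' \code{volumeValues}, \code{volumeRole} the field array and its role;
#' \code{maskLabels} the label array of a mask.
#'
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname accessors
#' @export
setGeneric("volumeValues", function(x) standardGeneric("volumeValues"))

#' @rdname accessors
#' @export
setGeneric("volumeRole", function(x) standardGeneric("volumeRole"))

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

setMethod("voxelSpacing", "ScalarVolume", function(x) x@spacing)
setMethod("voxelSpacing", "SegmentationMask", function(x) x@spacing)
setMethod("voxelSpacing", "BinaryVolume", function(x) x@spacing)
setMethod("voxelOrigin", "ScalarVolume", function(x) x@origin)
setMethod("voxelOrigin", "SegmentationMask", function(x) x@origin)
setMethod("voxelOrigin", "BinaryVolume", function(x) x@origin)
setMethod("volumeValues", "ScalarVolume", function(x) x@values)
setMethod("volumeValues", "BinaryVolume", function(x) x@values)
setMethod("volumeRole", "ScalarVolume", function(x) x@role)
setMethod("maskLabels", "SegmentationMask", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("dim", "ScalarVolume", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("dim", "SegmentationMask", function(x) dim(x@labels))

#' @rdname accessors
#' @export
setMethod("dim", "BinaryVolume", function(x) dim(x@values))

#' Contour-tree accessors
#'
#' \code{treeNodes} and \code{treeArcs} return the critical points and arcs
#' as data.frames; \code{voxelArcMap} the voxel-to-arc index array;
#' \code{arcTags} the per-arc accessibility tags of a tagged tree.
#'
#' @param x a \linkS4class{ContourTree} or \linkS4class{TaggedContourTree}.
#' @rdname tree-accessors
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' @rdname tree-accessors
#' @export
setGeneric("treeArcs", function(x) standardGeneric("treeArcs"))

#' @rdname tree-accessors
#' @export
setGeneric("voxelArcMap", function(x) standardGeneric("voxelArcMap"))

#' @rdname tree-accessors
#' @export
setGeneric("arcTags", function(x) standardGeneric("arcTags"))

setMethod("treeNodes", "ContourTree", function(x) x@nodes)
setMethod("treeArcs", "ContourTree", function(x) x@arcs)
setMethod("voxelArcMap", "ContourTree", function(x) x@voxelArc)
setMethod("arcTags", "TaggedContourTree", function(x) x@tag)

#' Seed-region accessors
#' @param x a \linkS4class{SeedRegion}.
#' @rdname seed-accessors
#' @export
setGeneric("seedStrategy", function(x) standardGeneric("seedStrategy"))

#' @rdname seed-accessors
#' @export
setGeneric("seedVoxels", function(x) standardGeneric("seedVoxels"))

setMethod("seedStrategy", "SeedRegion", function(x) x@strategy)
setMethod("seedVoxels", "SeedRegion", function(x) x@voxels)

#' Mesh accessors
#'
#' \code{meshVertices}/\code{meshTriangles} return the geometry;
#' \code{vertexData} the per-vertex scalar table; \code{meshArea} the total
#' triangle area in nm^2.
#'
#' @param x a \linkS4class{SurfaceMesh}.
#' @rdname mesh-accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname mesh-accessors
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))

#' @rdname mesh-accessors
#' @export
setGeneric("vertexData", function(x) standardGeneric("vertexData"))

#' @rdname mesh-accessors
#' @param value replacement data.frame.
#' @export
setGeneric("vertexData<-", function(x, value) standardGeneric("vertexData<-"))

#' @rdname mesh-accessors
#' @export
setGeneric("meshArea", function(x) standardGeneric("meshArea"))

setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)
setMethod("meshTriangles", "SurfaceMesh", function(x) x@triangles)
setMethod("vertexData", "SurfaceMesh", function(x) x@vertexData)
setMethod("vertexData<-", "SurfaceMesh", function(x, value) {
  x@vertexData <- value
  validObject(x)
  x
})

.triangle_areas <- function(v, tr) {
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

setMethod("meshArea", "SurfaceMesh", function(x) {
  sum(.triangle_areas(x@vertices, x@triangles))
})

#' Curve accessor: the curve as a data.frame
#'
#' Columns: \code{radius_nm}, \code{area_nm2}, \code{frac_total_area},
#' \code{area_per_biomass_vol_per_um}.
#'
#' @param x an \linkS4class{AccessibilityCurve}.
#' @return data.frame with one row per radius.
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

setMethod("curveTable", "AccessibilityCurve", function(x) {
  data.frame(
    radius_nm = x@radii,
    area_nm2 = x@area,
    frac_total_area = x@fracTotalArea,
    area_per_biomass_vol_per_um = x@areaPerVol
  )
})

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScalarVolume (%s): %d x %d x %d voxels (z,y,x), %.4g nm spacing\n",
              object@role, d[1], d[2], d[3], object@spacing))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("SegmentationMask: %d x %d x %d voxels (z,y,x), %.4g nm spacing\n",
              d[1], d[2], d[3], object@spacing))
  cat(sprintf("  biomass %d, void %d, lumen %d voxels\n",
              sum(object@labels == 1L), sum(object@labels == 0L),
              sum(object@labels == 2L)))
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryVolume: %d x %d x %d voxels, %d TRUE\n",
              d[1], d[2], d[3], sum(object@values)))
})

setMethod("show", "SeedRegion", function(object) {
  cat(sprintf("SeedRegion (%s): %d seed voxels", object@strategy,
              length(object@voxels)))
  if (length(object@faces)) cat(" on faces", paste(object@faces, collapse = ","))
  cat("\n")
})

setMethod("show", "ContourTree", function(object) {
  k <- table(factor(object@nodes$kind, c("leaf", "branch", "root")))
  cat(sprintf("ContourTree: %d leaves, %d branches, %d roots, %d arcs (%d-connectivity)\n",
              k[["leaf"]], k[["branch"]], k[["root"]], nrow(object@arcs),
              object@connectivity))
})

setMethod("show", "TaggedContourTree", function(object) {
  callNextMethod()
  cat(sprintf("  tags: %d seeded (Inf), %d bottlenecked, %d unreachable; seed strategy '%s'\n",
              sum(is.infinite(object@tag)),
              sum(is.finite(object@tag) & object@tag > 0),
              sum(object@tag == 0), object@seed@strategy))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles, area %.6g nm^2\n",
              nrow(object@vertices), nrow(object@triangles), meshArea(object)))
  if (ncol(object@vertexData))
    cat("  per-vertex scalars:", paste(names(object@vertexData), collapse = ", "), "\n")
})

setMethod("show", "AccessibilityCurve", function(object) {
  cat(sprintf("AccessibilityCurve (%s): %d radii in [%.4g, %.4g] nm, total area %.6g nm^2\n",
              object@strategy, length(object@radii), min(object@radii),
              max(object@radii), object@totalArea))
})

#' Write a contour tree as a plain-text edge list
#'
#' One line per arc: upper node id, lower node id, upper level, lower level,
#' and node kinds -- handy for inspecting or plotting small trees.
#'
#' @param tree a \linkS4class{ContourTree}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeTreeEdgeList <- function(tree, path) {
  n <- tree@nodes
  a <- tree@arcs
  df <- data.frame(
    upper = a$upper, lower = a$lower,
    upper_value_nm = n$value[a$upper], lower_value_nm = n$value[a$lower],
    upper_kind = n$kind[a$upper], lower_kind = n$kind[a$lower]
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
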