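#' ScalarVolume: a 3D scalar field on an isotropic voxel grid
#'
#' Holds tomogram intensities or any of the derived distance fields (EDT,
#' CRT, aEDT, aCRT). Values are indexed \code{[i, j, k]} = (z, y, x) with z
#' the section axis; voxel centres sit at \code{origin + spacing * (i, j, k)}
#' (zero-based, nm).
#'
#' @slot values 3D numeric array.
#' @slot spacing voxel edge length in nm (isotropic, > 0).
#' @slot origin physical coordinate of voxel (0,0,0)'s centre, nm,
#'   in (z, y, x) order.
#' @slot role one of \code{"intensity"}, \code{"edt"}, \code{"crt"},
#'   \code{"aedt"}, \code{"acrt"}. Distance-field roles require all values
#'   to be non-negative; they are zero exactly on biomass voxels.
#' @export
setClass("ScalarVolume",
  representation(values = "array", spacing = "numeric",
                 origin = "numeric", role = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive number")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must have length 3")
    roles <- c("intensity", "edt", "crt", "aedt", "acrt")
    if (length(object@role) != 1L || !object@role %in% roles)
      msg <- c(msg, paste("role must be one of:", paste(roles, collapse = ", ")))
    if (length(object@role) == 1L && object@role != "intensity" &&
        any(object@values < 0))
      msg <- c(msg, "distance-field volumes must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Construct a ScalarVolume
#'
#' @param values 3D numeric array in (z, y, x) index order.
#' @param spacing isotropic voxel edge length, nm.
#' @param origin physical centre of voxel (0,0,0), nm, (z, y, x) order.
#' @param role field role; see \linkS4class{ScalarVolume}.
#' @return A \linkS4class{ScalarVolume}.
#' @examples
#' v <- ScalarVolume(array(0, c(4, 4, 4)), spacing = 2)
#' voxelSpacing(v)
#' @export
ScalarVolume <- function(values, spacing = 1, origin = c(0, 0, 0),
                         role = "intensity") {
  storage.mode(values) <- "double"
  new("ScalarVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), role = role)
}

#' SegmentationMask: biomass / void / lumen labels on a voxel grid
#'
#' Label codes are \code{VOID = 0}, \code{BIOMASS = 1}, \code{LUMEN = 2}.
#' Lumen voxels are void space for all distance computations and double as
#' the lumen seed region.
#'
#' @slot labels 3D integer array with values in \{0, 1, 2\}.
#' @slot spacing,origin as in \linkS4class{ScalarVolume}.
#' @export
setClass("SegmentationMask",
  representation(labels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (!all(object@labels %in% c(0L, 1L, 2L)))
      msg <- c(msg, "labels must be in {VOID=0, BIOMASS=1, LUMEN=2}")
    if (length(object@spacing) != 1L || object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Construct a SegmentationMask
#'
#' @param labels 3D array of integer labels in \{0, 1, 2\}.
#' @inheritParams ScalarVolume
#' @return A \linkS4class{SegmentationMask}.
#' @export
SegmentationMask <- function(labels, spacing = 1, origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  new("SegmentationMask", labels = labels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' BinaryVolume: a thresholded volume such as Void(r)
#'
#' @slot values 3D logical array.
#' @slot spacing,origin as in \linkS4class{ScalarVolume}.
#' @export
setClass("BinaryVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L) return("values must be a 3D array")
    if (!is.logical(object@values)) return("values must be logical")
    TRUE
  })

#' Construct a BinaryVolume
#' @param values 3D logical array.
#' @inheritParams ScalarVolume
#' @return A \linkS4class{BinaryVolume}.
#' @export
BinaryVolume <- function(values, spacing = 1, origin = c(0, 0, 0)) {
  new("BinaryVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' SeedRegion: source voxels for diffusing spherical probes
#'
#' @slot strategy \code{"lumen"}, \code{"boundary"} or \code{"none"}.
#'   \code{"none"} means everything is considered accessible (the aCRT
#'   reduces to the plain CRT).
#' @slot voxels linear (column-major) indices of the seed voxels; always a
#'   subset of void space. Empty for strategy \code{"none"}.
#' @slot faces for the boundary strategy, the selected grid faces, e.g.
#'   \code{c("z-", "z+")}.
#' @slot dim grid dimensions the indices refer to.
#' @export
setClass("SeedRegion",
  representation(strategy = "character", voxels = "integer",
                 faces = "character", dim = "integer"),
  validity = function(object) {
    if (!object@strategy %in% c("lumen", "boundary", "none"))
      return("strategy must be lumen, boundary or none")
    TRUE
  })

#' ContourTree: join tree of the EDT's superlevel sets
#'
#' Leaves are (plateau-merged) local maxima of the EDT over void space,
#' branch nodes are bottlenecks where superlevel components merge as the
#' level decreases, and each connected component of void space is closed by
#' a root node at level 0. Every void voxel maps to exactly one arc whose
#' closed level span contains its EDT value.
#'
#' @slot nodes data.frame with columns \code{id}, \code{value} (nm),
#'   \code{voxel} (1-based linear index of the critical voxel, NA for
#'   roots), \code{kind} (\code{"leaf"}, \code{"branch"}, \code{"root"}).
#' @slot arcs data.frame with columns \code{id}, \code{upper}, \code{lower}
#'   (node ids; \code{upper} has the larger EDT value).
#' @slot voxelArc integer array mapping each voxel to its arc id (0 on
#'   biomass).
#' @slot connectivity 6, 18 or 26.
#' @slot edt the source EDT volume.
#' @export
setClass("ContourTree",
  representation(nodes = "data.frame", arcs = "data.frame",
                 voxelArc = "array", connectivity = "integer",
                 edt = "ScalarVolume"))

#' TaggedContourTree: a ContourTree with per-arc accessibility tags
#'
#' The tag of an arc is the radius of the largest probe that can reach that
#' part of the tree from the seed region: \code{Inf} marks seeded descent
#' paths (the EDT itself governs there), a finite value is the smallest
#' bottleneck on the best path from the seed, and 0 marks void that is
#' unreachable at any positive radius.
#'
#' @slot tag numeric vector, one value per arc.
#' @slot seed the \linkS4class{SeedRegion} used for tagging.
#' @export
setClass("TaggedContourTree", contains = "ContourTree",
  representation(tag = "numeric", seed = "SeedRegion"))

#' SurfaceMesh: triangulated biomass surface
#'
#' @slot vertices n x 3 numeric matrix of physical coordinates, columns
#'   (x, y, z), nm.
#' @slot triangles m x 3 integer matrix of 1-based vertex indices.
#' @slot vertexData data.frame of per-vertex scalars (e.g. accessibility).
#' @slot provenance list recording iso-level, prefilter weight and the
#'   source grid geometry.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 vertexData = "data.frame", provenance = "list"),
  validity = function(object) {
    msg <- character(0)
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (ncol(object@triangles) != 3L) msg <- c(msg, "triangles must be m x 3")
    if (nrow(object@triangles) &&
        (max(object@triangles) > nrow(object@vertices) ||
         min(object@triangles) < 1L))
      msg <- c(msg, "triangle indices out of range")
    if (nrow(object@vertexData) &&
        nrow(object@vertexData) != nrow(object@vertices))
      msg <- c(msg, "vertexData rows must match vertex count")
    if (length(msg)) msg else TRUE
  })

#' AccessibilityCurve: accessible surface area versus probe radius
#'
#' @slot radii sorted probe radii, nm.
#' @slot area accessible surface area at each radius, nm^2 (non-increasing).
#' @slot fracTotalArea area as a fraction of the total mesh area.
#' @slot areaPerVol area divided by the biomass volume, 1/um (NA when the
#'   biomass volume was not supplied).
#' @slot strategy seed strategy label.
#' @slot totalArea total mesh area, nm^2.
#' @slot biomassVolume biomass volume, nm^3 (NA if unknown).
#' @export
setClass("AccessibilityCurve",
  representation(radii = "numeric", area = "numeric",
                 fracTotalArea = "numeric", areaPerVol = "numeric",
                 strategy = "character", totalArea = "numeric",
                 biomassVolume = "numeric"),
  validity = function(object) {
    msg <- character(0)
    nr <- length(object@radii)
    if (length(object@area) != nr || length(object@fracTotalArea) != nr)
      msg <- c(msg, "radii, area and fracTotalArea must have equal length")
    if (nr > 1 && any(diff(object@radii) < 0))
      msg <- c(msg, "radii must be sorted increasing")
    if (nr > 1 && any(diff(object@area) > 1e-9 * max(object@area, 1)))
      msg <- c(msg, "area must be non-increasing in radius")
    if (length(msg)) msg else TRUE
  })
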