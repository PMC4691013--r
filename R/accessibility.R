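# seed regions, accessibility tagging of the contour tree, aEDT / aCRT,
# and two independent oracles

#' Select a seed region for accessibility analysis
#'
#' The seed region is the set of voxels acting as the source of diffusing
#' spherical probes. Strategies: \code{"lumen"} takes all LUMEN-labelled
#' voxels (the physiological entry route; a lower bound on accessibility);
#' \code{"boundary"} takes all void voxels on selected grid faces
#' (paths may re-enter through the section boundary; an upper bound);
#' \code{"none"} declares everything accessible, reducing the aCRT to the
#' plain CRT.
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @param strategy \code{"lumen"}, \code{"boundary"} or \code{"none"}.
#' @param faces for \code{"boundary"}: a character vector drawn from
#'   \code{c("z-","z+","y-","y+","x-","x+")}. Default: the two faces
#'   normal to the thinnest grid dimension (the axial section faces;
#'   ties resolve to z, the section axis).
#' @return A \linkS4class{SeedRegion}.
#' @export
selectSeed <- function(mask, strategy = c("lumen", "boundary", "none"),
                       faces = NULL) {
  stopifnot(is(mask, "SegmentationMask"))
  strategy <- match.arg(strategy)
  d <- dim(mask@labels)
  if (strategy == "none")
    return(new("SeedRegion", strategy = "none", voxels = integer(0),
               faces = character(0), dim = d))
  if (strategy == "lumen") {
    vox <- which(mask@labels == 2L)
    if (!length(vox))
      stop("strategy 'lumen' requires LUMEN labels in the mask")
    return(new("SeedRegion", strategy = "lumen", voxels = vox,
               faces = character(0), dim = d))
  }
  axes <- c("z", "y", "x")
  if (is.null(faces)) {
    ax <- axes[which.min(d)]
    faces <- paste0(ax, c("-", "+"))
  }
  bad <- setdiff(faces, paste0(rep(axes, each = 2), c("-", "+")))
  if (length(bad)) stop("unknown faces: ", paste(bad, collapse = ", "))
  vox <- integer(0)
  for (f in faces) {
    ax <- match(substr(f, 1, 1), axes)
    idx <- lapply(d, seq_len)
    idx[[ax]] <- if (substr(f, 2, 2) == "-") 1L else d[ax]
    face <- array(FALSE, d)
    face[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
    vox <- c(vox, which(face & mask@labels != 1L))
  }
  vox <- sort(unique(vox))
  if (!length(vox))
    stop("empty seed: selected boundary faces contain no void voxels")
  new("SeedRegion", strategy = "boundary", voxels = vox,
      faces = faces, dim = d)
}

#' Tag a contour tree with accessible radii
#'
#' Implements the accessibility tagging of the join tree. Every arc whose
#' voxel region intersects the seed is seeded at the seed voxels' EDT
#' values; the tag is then propagated through the tree as a widest-path
#' (maximum-bottleneck) value: moving between adjacent arcs through a node
#' of level b caps the tag at b. The per-arc tag B is the radius of the
#' largest probe that can reach that part of the tree from the seed. Arcs
#' with B equal to their upper level lie on a seeded descent path -- there
#' the EDT itself governs and the stored tag is the +Inf sentinel;
#' elsewhere the finite tag is the smallest bottleneck on the best path
#' (0 for unreachable subtrees).
#'
#' For a seed that covers the leaves this reduces to: descend from the
#' seed leaves to the roots preserving EDT values, then give each
#' untagged subtree the level of the branch node where it hangs off the
#' tagged path -- the largest bottleneck leading into it from a more
#' accessible region.
#'
#' @param tree a \linkS4class{ContourTree}.
#' @param seed a \linkS4class{SeedRegion} on the same grid.
#' @return A \linkS4class{TaggedContourTree}.
#' @export
tagTree <- function(tree, seed) {
  stopifnot(is(tree, "ContourTree"), is(seed, "SeedRegion"))
  if (!identical(dim(tree@voxelArc), seed@dim))
    stop("tree and seed refer to different grids")
  nA <- nrow(tree@arcs)
  if (seed@strategy == "none") {
    return(new("TaggedContourTree", tree, tag = rep(Inf, nA), seed = seed))
  }
  if (!length(seed@voxels))
    stop("empty seed region")
  sa <- tree@voxelArc[seed@voxels]
  if (any(sa == 0L))
    stop("seed voxels must lie in void space")
  sv <- tree@edt@values[seed@voxels]
  B <- numeric(nA)
  agg <- tapply(sv, sa, max)
  B[as.integer(names(agg))] <- agg
  nv <- tree@nodes$value
  up <- tree@arcs$upper
  lo <- tree@arcs$lower
  # widest-path propagation over the arc graph (arcs meet at nodes; the
  # node level caps the value); the tree is small, so a quadratic
  # max-selection loop is fine
  nodeArcs <- split(rep(seq_len(nA), 2L), c(up, lo))
  done <- logical(nA)
  repeat {
    cand <- which(!done & B > 0)
    if (!length(cand)) break
    a <- cand[which.max(B[cand])]
    done[a] <- TRUE
    for (nd in c(up[a], lo[a])) {
      v <- min(B[a], nv[nd])
      if (v <= 0) next
      nbrs <- nodeArcs[[as.character(nd)]]
      imp <- nbrs[!done[nbrs] & B[nbrs] < v]
      B[imp] <- v
    }
  }
  hi <- nv[up]
  tag <- ifelse(B >= hi, Inf, B)
  new("TaggedContourTree", tree, tag = tag, seed = seed)
}

#' Accessible Euclidean distance transform from a tagged tree
#'
#' The aEDT at x is the largest radius r such that a path from the seed
#' region reaches x entirely within Void(r): the smaller of the local
#' clearance EDT(x) and the bottleneck tag of x's arc. Void that is
#' disconnected from the seed at every positive radius gets 0, as does
#' biomass. aEDT <= EDT everywhere.
#'
#' @param edt the EDT volume the tree was built from.
#' @param tagged a \linkS4class{TaggedContourTree}.
#' @return A \linkS4class{ScalarVolume} with role \code{"aedt"}.
#' @export
computeAEDT <- function(edt, tagged) {
  stopifnot(is(edt, "ScalarVolume"), is(tagged, "TaggedContourTree"))
  if (!identical(dim(edt@values), dim(tagged@voxelArc)))
    stop("mismatched grids")
  if (!isTRUE(all.equal(edt@values, tagged@edt@values, tolerance = 0)))
    stop("mismatched grids: the tagged tree was built from a different EDT")
  va <- tagged@voxelArc
  out <- numeric(length(va))
  sel <- va > 0L
  out[sel] <- pmin(edt@values[sel], tagged@tag[va[sel]])
  ScalarVolume(array(out, dim(edt@values)), spacing = edt@spacing,
               origin = edt@origin, role = "aedt")
}

#' Accessible covering radius transform
#'
#' The covering transform of the aEDT, computed exactly as the CRT is
#' computed from the EDT: the value at x is the radius of the largest
#' sphere that can both diffuse from the seed region and overlap x. An
#' entire cavity guarded by a bottleneck of radius b is labelled b
#' throughout its interior.
#'
#' @param aedt a \linkS4class{ScalarVolume} with role \code{"aedt"} from
#'   [computeAEDT()].
#' @param centres optional painting centres, as in [sphereMaxPaint()].
#' @return A \linkS4class{ScalarVolume} with role \code{"acrt"}.
#' @export
computeACRT <- function(aedt, centres = NULL) {
  stopifnot(is(aedt, "ScalarVolume"))
  if (aedt@role != "aedt")
    stop("computeACRT expects an aEDT volume (role 'aedt')")
  sphereMaxPaint(aedt, centres = centres)
}

#' Widest-path oracle for the accessible EDT
#'
#' Direct implementation of the aEDT definition on the discrete voxel
#' graph: the value at x is the maximum over paths from any seed voxel of
#' the minimum EDT along the path (endpoints included), computed by a
#' multi-source maximum-bottleneck Dijkstra sweep. Independent of the
#' contour-tree route and used as ground truth for [computeAEDT()] on
#' small grids.
#'
#' @param edt an EDT volume.
#' @param seed a \linkS4class{SeedRegion}; strategy \code{"none"} returns
#'   the EDT itself (everything accessible).
#' @param connectivity 6, 18 or 26 -- use the same value as the tree.
#' @return A \linkS4class{ScalarVolume} with role \code{"aedt"}.
#' @export
aedtWidestPathOracle <- function(edt, seed, connectivity = 6) {
  stopifnot(is(edt, "ScalarVolume"), is(seed, "SeedRegion"))
  if (seed@strategy == "none")
    return(ScalarVolume(edt@values, spacing = edt@spacing,
                        origin = edt@origin, role = "aedt"))
  if (!length(seed@voxels)) stop("empty seed region")
  out <- cpp_widest_path(edt@values, dim(edt@values),
                         as.integer(seed@voxels), as.integer(connectivity))
  ScalarVolume(array(out, dim(edt@values)), spacing = edt@spacing,
               origin = edt@origin, role = "aedt")
}

#' Threshold-sweep flood-fill oracle for the accessible EDT
#'
#' A second independent oracle: for every distinct positive EDT value t in
#' descending order, flood the superlevel set \{EDT >= t\} from the seed
#' voxels; the aEDT at x is the largest t at which the flood reaches x.
#' Agrees exactly with [aedtWidestPathOracle()] under the same
#' connectivity.
#'
#' @inheritParams aedtWidestPathOracle
#' @return A \linkS4class{ScalarVolume} with role \code{"aedt"}.
#' @export
aedtFloodSweepOracle <- function(edt, seed, connectivity = 6) {
  stopifnot(is(edt, "ScalarVolume"), is(seed, "SeedRegion"))
  if (seed@strategy == "none")
    return(ScalarVolume(edt@values, spacing = edt@spacing,
                        origin = edt@origin, role = "aedt"))
  if (!length(seed@voxels)) stop("empty seed region")
  out <- cpp_flood_sweep(edt@values, dim(edt@values),
                         as.integer(seed@voxels), as.integer(connectivity))
  ScalarVolume(array(out, dim(edt@values)), spacing = edt@spacing,
               origin = edt@origin, role = "aedt")
}
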