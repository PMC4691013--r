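# join tree of the EDT's superlevel sets, the index structure for
# accessibility tagging

#' Build the contour (join) tree of a distance field
#'
#' A descending sweep over the distinct EDT values with union-find merging
#' of connected superlevel components: a leaf is born where a component
#' first appears (a pore maximum, possibly a plateau), a branch node where
#' two or more components merge (a bottleneck), and each connected
#' component of void space is closed by a root node at level 0. Ties are
#' broken in column-major voxel order, and same-value plateau artefacts
#' are collapsed so node values strictly decrease from any leaf to its
#' root. Only the join structure is built -- the merging of superlevel
#' components as the level decreases is the whole of what accessibility
#' tagging needs; EDT minima carry no information here.
#'
#' Boundary maxima are ordinary leaves: they are possible entry points for
#' probes from outside the imaged volume.
#'
#' @param edt a \linkS4class{ScalarVolume} with role \code{"edt"} from
#'   [computeEDT()]; must contain at least one void voxel.
#' @param connectivity 6 (default), 18 or 26; use the same value
#'   throughout a pipeline.
#' @return A \linkS4class{ContourTree}.
#' @export
buildContourTree <- function(edt, connectivity = 6) {
  stopifnot(is(edt, "ScalarVolume"))
  if (edt@role != "edt")
    stop("buildContourTree expects an EDT volume (role 'edt')")
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  if (!any(edt@values > 0)) stop("empty void space")
  res <- cpp_join_tree(edt@values, dim(edt@values), as.integer(connectivity))
  kinds <- c("leaf", "branch", "root")
  nodes <- data.frame(
    id = seq_along(res$nodeValue),
    value = res$nodeValue,
    voxel = res$nodeVoxel,
    kind = kinds[res$nodeKind]
  )
  arcs <- data.frame(
    id = seq_along(res$arcUpper),
    upper = res$arcUpper,
    lower = res$arcLower
  )
  new("ContourTree", nodes = nodes, arcs = arcs,
      voxelArc = array(res$voxelArc, dim(edt@values)),
      connectivity = as.integer(connectivity), edt = edt)
}

#' Partition Void(r) into components using the contour tree
#'
#' Reads the connectivity of \code{Void(r)} straight off the tree: each
#' arc whose level span straddles r (lower node value <= r < upper node
#' value) identifies one component, and every voxel with EDT > r belongs
#' to the component of the straddling arc found by descending from its own
#' arc. For every r this partition is identical (up to label numbering) to
#' \code{connectedComponents(thresholdVoid(edt, r))}.
#'
#' @param tree a \linkS4class{ContourTree}.
#' @param r probe radius, nm (>= 0).
#' @return list with \code{labels} (integer array, 0 outside Void(r)) and
#'   \code{count}.
#' @export
treeComponentsAt <- function(tree, r) {
  stopifnot(is(tree, "ContourTree"))
  if (r < 0) stop("negative radius")
  nodes <- tree@nodes
  arcs <- tree@arcs
  hi <- nodes$value[arcs$upper]
  lo <- nodes$value[arcs$lower]
  straddle <- lo <= r & hi > r
  dims <- dim(tree@voxelArc)
  labels <- array(0L, dims)
  if (!any(straddle))
    return(list(labels = labels, count = 0L))
  # the arc directly below each arc (via its lower node); NA below roots
  parentArc <- match(arcs$lower, arcs$upper)
  rep <- integer(nrow(arcs))
  for (a in seq_len(nrow(arcs))) {
    if (rep[a] != 0L) next
    chain <- integer(0)
    cur <- a
    while (!straddle[cur] && rep[cur] == 0L) {
      chain <- c(chain, cur)
      cur <- parentArc[cur]
      if (is.na(cur)) break
    }
    tgt <- if (!is.na(cur) && straddle[cur]) cur
           else if (!is.na(cur)) rep[cur] else 0L
    rep[chain] <- tgt
    if (straddle[a]) rep[a] <- a
  }
  comps <- which(straddle)
  sel <- tree@edt@values > r
  labels[sel] <- match(rep[tree@voxelArc[sel]], comps)
  list(labels = labels, count = length(comps))
}
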