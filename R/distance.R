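# Euclidean distance transform of a segmentation and its thresholded
# void sets.

#' Exact Euclidean distance transform
#'
#' Distance (nm) from each voxel centre to the nearest biomass voxel
#' centre, exact (not a chamfer approximation): squared distances are
#' computed separably as integers in voxel units and scaled by the
#' spacing. Lumen voxels count as void; the grid boundary is open (edge
#' voxels measure distance only to biomass inside the grid).
#'
#' @param mask a \linkS4class{SegmentationMask} with at least one biomass
#'   voxel.
#' @return A \linkS4class{ScalarVolume} with role \code{"edt"}; zero
#'   exactly on biomass.
#' @examples
#' lab <- array(0L, c(8, 8, 8)); lab[1, 1, 1] <- 1L
#' edt <- computeEDT(SegmentationMask(lab, spacing = 2))
#' volumeValues(edt)[1, 4, 5]  # 5 voxels away: 10 nm
#' @export
computeEDT <- function(mask) {
  stopifnot(is(mask, "SegmentationMask"))
  bio <- mask@labels == 1L
  if (!any(bio)) stop("EDT undefined: empty biomass")
  d2 <- cpp_edt_sq(bio, dim(bio))
  vals <- array(mask@spacing * sqrt(d2), dim(bio))
  ScalarVolume(vals, spacing = mask@spacing, origin = mask@origin,
               role = "edt")
}

#' Threshold a distance field: Void(r)
#'
#' \code{Void(r)} is the set of voxels whose EDT is \emph{strictly}
#' greater than r -- the positions where a probe of radius r can sit.
#' \code{Void(0)} is all of void space.
#'
#' @param edt a \linkS4class{ScalarVolume} with role \code{"edt"} (or
#'   \code{"aedt"}).
#' @param r probe radius, nm (>= 0).
#' @return A \linkS4class{BinaryVolume}.
#' @export
thresholdVoid <- function(edt, r) {
  stopifnot(is(edt, "ScalarVolume"))
  if (!edt@role %in% c("edt", "aedt"))
    stop("thresholdVoid expects a distance field (role edt/aedt)")
  if (r < 0) stop("negative radius")
  BinaryVolume(edt@values > r, spacing = edt@spacing, origin = edt@origin)
}

#' Connected components of a binary volume
#'
#' Components are numbered 1..K in column-major discovery order; 0 is
#' background. The default 6-connectivity is the conservative physical
#' choice for probe motion (a finite sphere cannot pass through a
#' voxel-corner contact); 18 and 26 are available for sensitivity
#' analysis.
#'
#' @param binary a \linkS4class{BinaryVolume} (or logical array).
#' @param connectivity 6, 18 or 26.
#' @return list with \code{labels} (integer array) and \code{count}.
#' @export
connectedComponents <- function(binary, connectivity = 6) {
  if (is(binary, "BinaryVolume")) binary <- binary@values
  stopifnot(is.logical(binary), length(dim(binary)) == 3L)
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  res <- cpp_label(binary, dim(binary), as.integer(connectivity))
  list(labels = array(res$labels, dim(binary)), count = res$count)
}
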