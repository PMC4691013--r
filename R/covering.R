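# covering-radius-type transforms by maximal-sphere painting

#' Covering radius transform by maximal-sphere painting
#'
#' For every voxel x carrying a distance value D(x) > 0, every voxel y
#' with |y - x| <= D(x) (physical distance between voxel centres,
#' inclusive) receives at least the value D(x); the output at y is the
#' maximum over all covering spheres, and 0 where no sphere reaches (in
#' particular on biomass). Applied to an EDT this is the covering radius
#' transform (local thickness); applied to an accessible EDT it yields the
#' accessible CRT. Spheres are clipped at the grid boundary.
#'
#' @param D a \linkS4class{ScalarVolume} with role \code{"edt"} or
#'   \code{"aedt"} (any non-negative field is accepted).
#' @param centres optional integer vector of linear voxel indices to paint
#'   from (e.g. the output of [nonredundantCenters()]); default: all
#'   voxels with D > 0.
#' @return A \linkS4class{ScalarVolume} with role \code{"crt"} (from an
#'   EDT) or \code{"acrt"} (from an aEDT); pointwise >= D on void.
#' @export
sphereMaxPaint <- function(D, centres = NULL) {
  stopifnot(is(D, "ScalarVolume"))
  if (any(D@values < 0)) stop("negative values in distance field")
  dims <- dim(D@values)
  use <- logical(0)
  if (!is.null(centres)) {
    use <- logical(prod(dims))
    use[centres] <- TRUE
  }
  rvox <- D@values / D@spacing
  out <- cpp_paint(rvox, dims, use) * D@spacing
  role <- switch(D@role, edt = "crt", aedt = "acrt", "crt")
  ScalarVolume(array(out, dims), spacing = D@spacing, origin = D@origin,
               role = role)
}

#' Non-redundant sphere centres of a distance field
#'
#' A centre x is redundant when another centre x' satisfies
#' D(x') >= D(x) + |x - x'|: its sphere lies inside the other's, so
#' painting from the non-redundant subset (centres along the ridges of D)
#' reproduces the full painting exactly. Intended as a painting speedup;
#' correctness is guaranteed by construction and enforced by the equality
#' property tests.
#'
#' @param D a \linkS4class{ScalarVolume} distance field.
#' @return sorted integer vector of linear voxel indices; painting from
#'   these equals painting from all voxels.
#' @export
nonredundantCenters <- function(D) {
  stopifnot(is(D, "ScalarVolume"))
  if (any(D@values < 0)) stop("negative values in distance field")
  keep <- cpp_nonredundant(D@values / D@spacing, dim(D@values))
  which(keep)
}
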