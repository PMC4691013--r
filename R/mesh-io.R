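# mesh and curve I/O: ASCII PLY / OBJ / legacy VTK, CSV/TSV curves

.guess_mesh_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("ply", "obj", "vtk"))
    stop("cannot infer mesh format from extension '.", ext, "'")
  ext
}

#' Write a surface mesh to PLY, OBJ or legacy VTK
#'
#' PLY and VTK carry the per-vertex scalar columns of \code{vertexData}
#' (PLY as named float properties, VTK as point-data scalars); OBJ stores
#' geometry only.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output file.
#' @param format \code{"auto"}, \code{"ply"}, \code{"obj"} or \code{"vtk"}.
#' @return invisibly, the path.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "obj", "vtk")) {
  stopifnot(is(mesh, "SurfaceMesh"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_mesh_format(path)
  if (!dir.exists(dirname(path)))
    stop("cannot write mesh: directory does not exist: ", dirname(path))
  v <- mesh@vertices
  tr <- mesh@triangles
  sc <- mesh@vertexData
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "ply") {
    props <- c("x", "y", "z", names(sc))
    writeLines(c(
      "ply", "format ascii 1.0",
      paste("element vertex", nrow(v)),
      paste("property float", props),
      paste("element face", nrow(tr)),
      "property list uchar int vertex_indices",
      "end_header"), con)
    tab <- cbind(v, as.matrix(sc))
    writeLines(apply(format(tab, digits = 9, trim = TRUE, scientific = FALSE),
                     1, paste, collapse = " "), con)
    writeLines(paste(3, tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  } else if (format == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  } else {
    writeLines(c("# vtk DataFile Version 3.0", "tomoaccess surface",
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(v))), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4L * nrow(tr)), con)
    writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                       tr[, 3] - 1L), con)
    if (ncol(sc)) {
      writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
      for (nm in names(sc)) {
        writeLines(c(sprintf("SCALARS %s float 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", sc[[nm]]), con)
      }
    }
  }
  invisible(path)
}

#' Read a surface mesh written by [writeMesh()]
#'
#' @param path input PLY, OBJ or legacy-VTK file.
#' @param format as in [writeMesh()].
#' @return A \linkS4class{SurfaceMesh} (per-vertex scalars recovered from
#'   PLY and VTK).
#' @export
readMesh <- function(path, format = c("auto", "ply", "obj", "vtk")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_mesh_format(path)
  lines <- readLines(path)
  if (format == "ply") {
    endh <- match("end_header", lines)
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    props <- sub("property float ", "",
                 grep("^property float", lines, value = TRUE))
    vt <- read.table(text = lines[(endh + 1):(endh + nv)])
    names(vt) <- props
    ft <- read.table(text = lines[(endh + nv + 1):(endh + nv + nf)])
    v <- as.matrix(vt[, c("x", "y", "z")])
    sc <- vt[, setdiff(props, c("x", "y", "z")), drop = FALSE]
    tr <- as.matrix(ft[, 2:4]) + 1L
  } else if (format == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- as.matrix(read.table(text = sub("^v ", "", vl)))
    tr <- as.matrix(read.table(text = sub("^f ", "", fl)))
    if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1)
    sc <- data.frame()
  } else {
    ip <- grep("^POINTS", lines)
    nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
    v <- as.matrix(read.table(text = lines[(ip + 1):(ip + nv)]))
    ig <- grep("^POLYGONS", lines)
    nf <- as.integer(strsplit(lines[ig], "\\s+")[[1]][2])
    tr <- as.matrix(read.table(text = lines[(ig + 1):(ig + nf)])[, 2:4]) + 1L
    sc <- data.frame()
    isc <- grep("^SCALARS", lines)
    for (s in isc) {
      nm <- strsplit(lines[s], "\\s+")[[1]][2]
      sc[[nm]] <- numeric(0)
      vals <- as.numeric(lines[(s + 2):(s + 1 + nv)])
      if (!nrow(sc)) sc <- data.frame(row.names = seq_len(nv))
      sc[[nm]] <- vals
    }
  }
  colnames(v) <- c("x", "y", "z")
  storage.mode(tr) <- "integer"
  if (!is.data.frame(sc)) sc <- as.data.frame(sc)
  if (!nrow(sc)) sc <- data.frame(row.names = seq_len(nrow(v)))
  new("SurfaceMesh", vertices = unname(v), triangles = unname(tr[, 1:3, drop = FALSE]),
      vertexData = sc, provenance = list(source = path))
}

#' Write an accessibility curve to CSV or TSV
#'
#' Columns: \code{radius_nm}, \code{area_nm2}, \code{frac_total_area},
#' \code{area_per_biomass_vol_per_um}.
#'
#' @param curve an \linkS4class{AccessibilityCurve}.
#' @param path output file.
#' @param format \code{"auto"} (by extension), \code{"csv"} or \code{"tsv"}.
#' @return invisibly, the path.
#' @export
writeCurve <- function(curve, path, format = c("auto", "csv", "tsv")) {
  stopifnot(is(curve, "AccessibilityCurve"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext == "tsv") "tsv" else "csv"
  }
  if (!dir.exists(dirname(path)))
    stop("cannot write curve: directory does not exist: ", dirname(path))
  df <- curveTable(curve)
  if (format == "csv") write.csv(df, path, row.names = FALSE)
  else write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an accessibility curve written by [writeCurve()]
#'
#' @param path input CSV/TSV file.
#' @param strategy seed-strategy label to attach.
#' @return An \linkS4class{AccessibilityCurve}.
#' @export
readCurve <- function(path, strategy = "") {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.csv(path, sep = sep)
  new("AccessibilityCurve", radii = df$radius_nm, area = df$area_nm2,
      fracTotalArea = df$frac_total_area,
      areaPerVol = df$area_per_biomass_vol_per_um,
      strategy = strategy, totalArea = max(df$area_nm2),
      biomassVolume = NA_real_)
}
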