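# volume I/O: MRC (2014, modes 0/1/2/6), NRRD (raw encoding), TIFF stacks,
# plus the global-threshold segmentation baseline.

.check_isotropic <- function(s3) {
  if (max(s3) - min(s3) > 1e-3 * max(s3))
    stop(sprintf("anisotropic voxel spacing: (%g, %g, %g)",
                 s3[1], s3[2], s3[3]))
  mean(s3)
}

.guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    mrc = "mrc", rec = "mrc", map = "mrc",
    nrrd = "nrrd",
    tif = "tiff", tiff = "tiff",
    stop("cannot infer volume format from extension '.", ext, "'")
  )
}

#' Read a 3D volume from MRC, NRRD or a multi-page TIFF
#'
#' Returns a \linkS4class{ScalarVolume} with the array stored in (z, y, x)
#' index order (z = section axis; within the file, x is the fastest-varying
#' axis as usual for MRC/NRRD). Spacing is taken from the file metadata
#' when present; TIFF carries no spacing, so \code{spacing} must be given.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"mrc"}, \code{"nrrd"}
#'   or \code{"tiff"}.
#' @param spacing optional override of the voxel spacing (one value, or
#'   three values that must agree within 0.1\%), interpreted in
#'   \code{units}.
#' @param units unit of the spacing metadata / override: \code{"nm"}
#'   (default) or \code{"angstrom"} (converted to nm).
#' @param role field role to assign when the file metadata carries none.
#' @return A \linkS4class{ScalarVolume} with spacing in nm.
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, format = c("auto", "mrc", "nrrd", "tiff"),
                       spacing = NULL, units = c("nm", "angstrom"),
                       role = NULL) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  r <- switch(format,
    mrc = .read_mrc(path),
    nrrd = .read_nrrd(path),
    tiff = .read_tiff(path)
  )
  fac <- if (units == "angstrom") 0.1 else 1
  s3 <- if (!is.null(spacing)) rep(spacing, length.out = 3) else r$spacing
  if (is.null(s3)) stop("no voxel spacing in ", format,
                        " metadata; supply `spacing`")
  sp <- .check_isotropic(s3) * fac
  ScalarVolume(r$values, spacing = sp,
               origin = if (is.null(r$origin)) c(0, 0, 0) else r$origin * fac,
               role = if (!is.null(role)) role
                      else if (is.null(r$role)) "intensity" else r$role)
}

#' Write a 3D volume to MRC, NRRD or a multi-page TIFF
#'
#' MRC is written as mode-2 float32 with the voxel size in the cell-size
#' header and the origin in the MRC2014 origin words. NRRD is written as
#' raw little-endian doubles (lossless round trip) with the field role and
#' origin in key-value pairs. TIFF is written as 32-bit float pages and --
#' a limitation of the underlying TIFF bindings -- supports only values in
#' [0, 1]; it carries no spacing metadata.
#'
#' @param volume a \linkS4class{ScalarVolume}.
#' @param path output file; the parent directory must exist.
#' @param format as in [readVolume()].
#' @return invisibly, the path.
#' @export
writeVolume <- function(volume, path, format = c("auto", "mrc", "nrrd", "tiff")) {
  stopifnot(is(volume, "ScalarVolume"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!dir.exists(dirname(path)))
    stop("cannot write volume: directory does not exist: ", dirname(path))
  switch(format,
    mrc = .write_mrc(volume, path),
    nrrd = .write_nrrd(volume, path),
    tiff = .write_tiff(volume, path)
  )
  invisible(path)
}

# ---- MRC ----

.read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- h1[1]; ny <- h1[2]; nz <- h1[3]; mode <- h1[4]
  mx <- h1[8]; my <- h1[9]; mz <- h1[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 3 * 4))          # cellb
  invisible(readBin(con, "integer", n = 3, size = 4, endian = "little")) # mapc/r/s
  invisible(readBin(con, "numeric", n = 3, size = 4, endian = "little")) # dmin/max/mean
  invisible(readBin(con, "integer", n = 1, size = 4, endian = "little")) # ispg
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 25 * 4))         # extra, words 25-49
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little") # x,y,z
  invisible(readBin(con, "raw", n = 1024 - 52 * 4 + max(0L, nsymbt)))
  n <- as.double(nx) * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode: ", mode)
  )
  if (length(vals) != n) stop("truncated MRC data in ", path)
  arr <- aperm(array(as.double(vals), c(nx, ny, nz)), c(3, 2, 1))
  sp <- NULL
  grid <- c(mx, my, mz)
  grid[grid == 0] <- c(nx, ny, nz)[grid == 0]
  if (all(cella > 0)) sp <- rev(cella / grid)  # (z,y,x)
  list(values = arr, spacing = sp, origin = rev(orig), role = NULL)
}

.write_mrc <- function(volume, path) {
  d <- dim(volume@values)            # (z,y,x)
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(nx, ny, nz, 2L, 0L, 0L, 0L, nx, ny, nz)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(volume@spacing * c(nx, ny, nz)), con, size = 4,
           endian = "little")                        # cella
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  rng <- range(volume@values)
  writeBin(as.numeric(c(rng[1], rng[2], mean(volume@values))), con,
           size = 4, endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little") # ispg, nsymbt
  writeBin(raw(25 * 4), con)                         # extra
  writeBin(as.numeric(rev(volume@origin)), con, size = 4, endian = "little")
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # little-endian stamp
  writeBin(as.numeric(stats::sd(volume@values)), con, size = 4,
           endian = "little")
  writeBin(as.integer(0L), con, size = 4, endian = "little") # nlabl
  writeBin(raw(1024 - 56 * 4), con)
  writeBin(as.numeric(aperm(volume@values, c(3, 2, 1))), con, size = 4,
           endian = "little")
}

# ---- NRRD ----

.read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not a NRRD file: ", path)
  fields <- list(); kv <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    if (grepl(":=", line)) {
      p <- regmatches(line, regexpr(":=", line), invert = TRUE)[[1]]
      kv[[trimws(p[1])]] <- trimws(p[2])
    } else {
      p <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
      fields[[tolower(trimws(p[1]))]] <- trimws(p[2])
    }
  }
  if (is.null(fields$sizes)) stop("NRRD header missing sizes")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD volumes are supported")
  if (!is.null(fields$encoding) && fields$encoding != "raw")
    stop("unsupported NRRD encoding: ", fields$encoding)
  endian <- if (is.null(fields$endian)) "little" else fields$endian
  type <- fields$type
  n <- prod(as.double(sizes))
  vals <- switch(type,
    "double" = readBin(con, "numeric", n = n, size = 8, endian = endian),
    "float" = readBin(con, "numeric", n = n, size = 4, endian = endian),
    "unsigned char" = , "uchar" = , "uint8" =
      readBin(con, "integer", n = n, size = 1, signed = FALSE),
    "short" = , "int16" = readBin(con, "integer", n = n, size = 2,
                                  endian = endian),
    "int" = , "int32" = readBin(con, "integer", n = n, size = 4,
                                endian = endian),
    stop("unsupported NRRD type: ", type)
  )
  if (length(vals) != n) stop("truncated NRRD data in ", path)
  sp <- NULL
  if (!is.null(fields$spacings)) {
    sp <- rev(as.numeric(strsplit(fields$spacings, "\\s+")[[1]]))
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    sp <- rev(sqrt(rowSums(m^2)))
  }
  orig <- if (!is.null(kv$origin_nm))
    as.numeric(strsplit(kv$origin_nm, "\\s+")[[1]]) else NULL
  arr <- aperm(array(as.double(vals), sizes), c(3, 2, 1))
  list(values = arr, spacing = sp, origin = orig, role = kv$role)
}

.write_nrrd <- function(volume, path) {
  d <- dim(volume@values)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# generated by tomoaccess",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[3], d[2], d[1]),
    sprintf("spacings: %.10g %.10g %.10g", volume@spacing, volume@spacing,
            volume@spacing),
    "endian: little",
    "encoding: raw",
    sprintf("role:=%s", volume@role),
    "spacing_unit:=nm",
    sprintf("origin_nm:=%.10g %.10g %.10g", volume@origin[1],
            volume@origin[2], volume@origin[3]),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(aperm(volume@values, c(3, 2, 1))), con, size = 8,
           endian = "little")
}

# ---- TIFF ----

.read_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]   # grayscale stored with channels
    arr[i, , ] <- p
  }
  list(values = arr, spacing = NULL, origin = NULL, role = NULL)
}

.write_tiff <- function(volume, path) {
  v <- volume@values
  if (min(v) < 0 || max(v) > 1)
    stop("TIFF storage supports values in [0, 1] only; rescale first or ",
         "use NRRD/MRC")
  slices <- lapply(seq_len(dim(v)[1]), function(i) v[i, , ])
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
}

# ---- segmentation ----

#' Global-threshold segmentation of an intensity volume
#'
#' Labels voxels darker than \code{cutoff} as biomass -- in stained TEM
#' tomograms biomass is dark -- and everything else as void. With
#' \code{invert = TRUE} the polarity flips (biomass bright). No lumen
#' labels are assigned; add those separately if lumen seeding is wanted.
#'
#' @param volume a \linkS4class{ScalarVolume} with role \code{"intensity"}.
#' @param cutoff intensity threshold.
#' @param invert label voxels \emph{above} the cutoff as biomass instead.
#' @return A \linkS4class{SegmentationMask}. A warning is emitted when the
#'   cutoff leaves the mask all-void or all-biomass (downstream transforms
#'   will reject such masks).
#' @export
thresholdSegment <- function(volume, cutoff, invert = FALSE) {
  stopifnot(is(volume, "ScalarVolume"))
  if (volume@role != "intensity")
    stop("thresholdSegment expects an intensity volume, got role '",
         volume@role, "'")
  bio <- if (invert) volume@values > cutoff else volume@values < cutoff
  if (!any(bio))
    warning("cutoff ", cutoff, " produced an all-void mask")
  if (all(bio))
    warning("cutoff ", cutoff, " produced an all-biomass mask")
  lab <- array(0L, dim(volume@values))
  lab[bio] <- 1L
  SegmentationMask(lab, spacing = volume@spacing, origin = volume@origin)
}

#' Coerce a label-valued ScalarVolume to a SegmentationMask
#'
#' For masks stored on disk as volumes of 0/1/2 labels.
#'
#' @param volume a \linkS4class{ScalarVolume} whose values are all in
#'   \{0, 1, 2\}.
#' @return A \linkS4class{SegmentationMask}.
#' @export
asSegmentationMask <- function(volume) {
  stopifnot(is(volume, "ScalarVolume"))
  v <- round(volume@values)
  if (max(abs(v - volume@values)) > 1e-6 || !all(v %in% c(0, 1, 2)))
    stop("volume values are not labels in {0, 1, 2}")
  SegmentationMask(array(as.integer(v), dim(v)), spacing = volume@spacing,
                   origin = volume@origin)
}
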