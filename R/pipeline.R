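# end-to-end pipeline: segment/phantom -> EDT -> contour tree -> tagging
# -> aEDT -> aCRT -> surface -> curves, driven by a key = value config

.pipeline_keys <- c(
  "input_mask", "phantom", "spacing", "rng_seed", "strategies", "faces",
  "epsilon", "radii", "connectivity", "out_dir", "prefilter_weight",
  "mesh_rule", "cutoff",
  # phantom parameters
  "shape", "r", "channel_radius", "open_to_boundary", "r1", "r2", "a",
  "open_side", "open_radius", "lumen_pad", "n_gaps", "gap_half_widths",
  "connect_to_lumen", "neck_radius", "lumen_depth", "amplitude",
  "wavelength", "porosity"
)

.parse_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("config error: not a key = value line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!key %in% .pipeline_keys)
      stop("config error: unknown config key: ", key)
    cfg[[key]] <- val
  }
  cfg
}

.cfg_num <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) return(default)
  as.numeric(strsplit(cfg[[key]], "[,[:space:]]+")[[1]])
}

.cfg_chr <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) return(default)
  strsplit(cfg[[key]], "[,[:space:]]+")[[1]]
}

.cfg_lgl <- function(cfg, key, default = FALSE) {
  if (is.null(cfg[[key]])) return(default)
  tolower(cfg[[key]]) %in% c("true", "yes", "1")
}

.pipeline_mask <- function(cfg) {
  spacing <- .cfg_num(cfg, "spacing", 1)
  if (!is.null(cfg$input_mask)) {
    if (!file.exists(cfg$input_mask))
      stop("config error: input_mask file not found: ", cfg$input_mask)
    vol <- readVolume(cfg$input_mask,
                      spacing = if (is.null(cfg$spacing)) NULL else spacing)
    mask <- if (!is.null(cfg$cutoff))
      thresholdSegment(vol, .cfg_num(cfg, "cutoff"))
    else asSegmentationMask(vol)
    return(list(mask = mask, truth = NULL))
  }
  if (is.null(cfg$phantom))
    stop("config error: missing key 'phantom' or 'input_mask'")
  shape <- .cfg_num(cfg, "shape", c(48, 48, 48))
  seedv <- .cfg_num(cfg, "rng_seed", 1)
  switch(cfg$phantom,
    sphere_pore = spherePorePhantom(
      shape, spacing, R = .cfg_num(cfg, "r", 8),
      openToBoundary = .cfg_lgl(cfg, "open_to_boundary"),
      channelRadius = .cfg_num(cfg, "channel_radius",
                               .cfg_num(cfg, "r", 8))),
    dumbbell = dumbbellPhantom(
      shape, spacing, R1 = .cfg_num(cfg, "r1", 10),
      R2 = .cfg_num(cfg, "r2", 6), a = .cfg_num(cfg, "a", 3),
      openSide = .cfg_chr(cfg, "open_side", "left"),
      openRadius = .cfg_num(cfg, "open_radius", .cfg_num(cfg, "a", 3)),
      lumenPad = .cfg_num(cfg, "lumen_pad", 0)),
    delaminated_slab = delaminatedSlabPhantom(
      shape, spacing, nGaps = .cfg_num(cfg, "n_gaps", 2),
      gapHalfWidths = .cfg_num(cfg, "gap_half_widths", c(2, 2)),
      connectToLumen = .cfg_lgl(cfg, "connect_to_lumen"),
      neckRadius = .cfg_num(cfg, "neck_radius", 1.5),
      lumenDepth = .cfg_num(cfg, "lumen_depth", NULL)),
    rough_wall = roughWallPhantom(
      shape, spacing, amplitude = .cfg_num(cfg, "amplitude", 4),
      wavelength = .cfg_num(cfg, "wavelength", 32), rngSeed = seedv),
    random_blobs = randomBlobsPhantom(
      shape, spacing, porosity = .cfg_num(cfg, "porosity", 0.5),
      rngSeed = seedv),
    stop("config error: unknown phantom: ", cfg$phantom)
  )
}

#' Run the full accessibility pipeline from a config file
#'
#' The config is a plain-text file of \code{key = value} lines (\code{#}
#' comments allowed). Either \code{input_mask} (a volume of 0/1/2 labels,
#' or an intensity volume together with \code{cutoff}) or \code{phantom}
#' (one of \code{sphere_pore}, \code{dumbbell}, \code{delaminated_slab},
#' \code{rough_wall}, \code{random_blobs}, with its parameters) selects
#' the input. Other keys: \code{strategies} (default
#' \code{lumen,boundary,none}; strategies whose seed is unavailable are
#' skipped with a note in the log), \code{faces}, \code{epsilon} (nm),
#' \code{radii} (nm list for the curves; default: exact step grid),
#' \code{connectivity} (6), \code{prefilter_weight}, \code{mesh_rule}
#' (\code{all}/\code{mean}), \code{rng_seed}, \code{spacing} (nm),
#' \code{out_dir}.
#'
#' Outputs under \code{out_dir}: the mask and EDT/CRT volumes
#' (\code{.nrrd}), per-strategy aEDT/aCRT volumes, a mesh
#' (\code{surface_<strategy>.ply}) with the accessibility scalar, one
#' curve CSV per strategy, \code{stats.txt}, the phantom ground truth (if
#' any) and \code{run.log} recording package version, parameters, seeds
#' and connectivity.
#'
#' @param config path to the config file, or a named list with the same
#'   keys.
#' @param outDir overrides the config's \code{out_dir}.
#' @return invisibly, a named list of output paths.
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- if (is.character(config)) .parse_config(config) else config
  unknown <- setdiff(names(cfg), .pipeline_keys)
  if (length(unknown))
    stop("config error: unknown config key: ", paste(unknown, collapse = ", "))
  out <- outDir
  if (is.null(out)) out <- cfg$out_dir
  if (is.null(out)) stop("config error: missing key 'out_dir'")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  logLines <- c(
    sprintf("tomoaccess %s", as.character(packageVersion("tomoaccess"))),
    sprintf("R %s", R.version.string),
    sprintf("date %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    vapply(names(cfg), function(k)
      sprintf("config %s = %s", k, paste(cfg[[k]], collapse = " ")), "")
  )
  paths <- list()

  ph <- .pipeline_mask(cfg)
  mask <- ph$mask
  conn <- .cfg_num(cfg, "connectivity", 6)
  eps <- .cfg_num(cfg, "epsilon", 1.1 * mask@spacing)
  radii <- .cfg_num(cfg, "radii", NULL)
  rule <- .cfg_chr(cfg, "mesh_rule", "all")
  strategies <- .cfg_chr(cfg, "strategies", c("lumen", "boundary", "none"))
  faces <- .cfg_chr(cfg, "faces", NULL)
  logLines <- c(logLines,
                sprintf("connectivity %d", conn),
                sprintf("epsilon_nm %g", eps))

  paths$mask <- file.path(out, "mask.nrrd")
  writeVolume(ScalarVolume(array(as.double(mask@labels), dim(mask)),
                           spacing = mask@spacing, origin = mask@origin),
              paths$mask)
  if (!is.null(ph$truth)) {
    paths$ground_truth <- file.path(out, "ground_truth.txt")
    writeGroundTruth(ph$truth, paths$ground_truth)
  }

  edt <- computeEDT(mask)
  paths$edt <- file.path(out, "edt.nrrd")
  writeVolume(edt, paths$edt)
  crt <- sphereMaxPaint(edt)
  paths$crt <- file.path(out, "crt.nrrd")
  writeVolume(crt, paths$crt)

  tree <- buildContourTree(edt, connectivity = conn)
  paths$tree <- file.path(out, "contour_tree.csv")
  writeTreeEdgeList(tree, paths$tree)

  mesh <- extractSurface(mask,
                         prefilterWeight = .cfg_num(cfg, "prefilter_weight",
                                                    0.1))
  stats <- biomassStats(mask, mesh)
  paths$stats <- file.path(out, "stats.txt")
  writeLines(.key_value_lines(stats), paths$stats)

  for (st in strategies) {
    seed <- tryCatch(selectSeed(mask, st, faces = faces),
                     error = function(e) e)
    if (inherits(seed, "error")) {
      logLines <- c(logLines, sprintf("strategy %s skipped: %s", st,
                                      conditionMessage(seed)))
      next
    }
    acrt <- if (st == "none") {
      crt
    } else {
      tagged <- tagTree(tree, seed)
      aedt <- computeAEDT(edt, tagged)
      paths[[paste0("aedt_", st)]] <- file.path(out,
                                                sprintf("aedt_%s.nrrd", st))
      writeVolume(aedt, paths[[paste0("aedt_", st)]])
      computeACRT(aedt)
    }
    paths[[paste0("acrt_", st)]] <- file.path(out,
                                              sprintf("acrt_%s.nrrd", st))
    writeVolume(acrt, paths[[paste0("acrt_", st)]])
    acc <- sampleSurfaceAccessibility(mesh, acrt, epsilon = eps)
    m2 <- mesh
    vertexData(m2) <- data.frame(accessibility = acc)
    paths[[paste0("surface_", st)]] <- file.path(out,
                                                 sprintf("surface_%s.ply", st))
    writeMesh(m2, paths[[paste0("surface_", st)]])
    curve <- accessibleAreaCurve(m2, acc, radii = radii, rule = rule,
                                 biomassVolume = stats$biomassVolume_nm3,
                                 strategy = st)
    paths[[paste0("curve_", st)]] <- file.path(out,
                                               sprintf("curve_%s.csv", st))
    writeCurve(curve, paths[[paste0("curve_", st)]])
    logLines <- c(logLines, sprintf("strategy %s: %d seed voxels", st,
                                    length(seed@voxels)))
  }

  paths$log <- file.path(out, "run.log")
  writeLines(logLines, paths$log)
  invisible(paths)
}
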