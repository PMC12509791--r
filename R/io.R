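#' Write a volume to MHA or NIfTI
#'
#' MetaImage (`.mha`, text header + local raw float32 payload) and NIfTI
#' (`.nii` / `.nii.gz`, via RNifti) are supported; voxel spacing and origin
#' are recorded and round-trip with the float32 payload.
#'
#' @param vol a [volume()].
#' @param path destination; format chosen from the extension.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "cbct_volume"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- "nii"
  if (ext == "mha") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c(
      "ObjectType = Image",
      "NDims = 3",
      "BinaryData = True",
      "BinaryDataByteOrderMSB = False",
      "CompressedData = False",
      "TransformMatrix = 1 0 0 0 1 0 0 0 1",
      sprintf("Offset = %.9g %.9g %.9g", vol$grid$origin_mm[1],
              vol$grid$origin_mm[2], vol$grid$origin_mm[3]),
      sprintf("ElementSpacing = %.9g %.9g %.9g", vol$grid$voxel_size_mm[1],
              vol$grid$voxel_size_mm[2], vol$grid$voxel_size_mm[3]),
      sprintf("DimSize = %d %d %d", vol$grid$shape[1], vol$grid$shape[2],
              vol$grid$shape[3]),
      "ElementType = MET_FLOAT",
      "ElementDataFile = LOCAL")
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(vol$values), con, size = 4L, endian = "little")
  } else if (ext == "nii") {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$grid$voxel_size_mm
    aff <- rbind(cbind(diag(vol$grid$voxel_size_mm), vol$grid$origin_mm),
                 c(0, 0, 0, 1))
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path, datatype = "float")
  } else {
    stop(sprintf("unknown volume format '.%s' (use .mha or .nii[.gz])", ext))
  }
  invisible(path)
}

#' Read a volume from MHA or NIfTI
#'
#' @param path file written by [write_volume()] (or any axis-aligned MHA /
#'   NIfTI scalar volume).
#' @return a [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- "nii"
  if (ext == "mha") {
    con <- file(path, "rb")
    on.exit(close(con))
    fields <- list()
    repeat {
      line <- readLines(con, n = 1L)
      if (length(line) == 0L) stop("corrupt MHA header: no ElementDataFile")
      kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop(sprintf("corrupt MHA header line: '%s'", line))
      fields[[kv[1]]] <- kv[2]
      if (kv[1] == "ElementDataFile") break
    }
    if (!identical(fields[["ElementDataFile"]], "LOCAL")) {
      stop("only local-payload MHA is supported")
    }
    if (!identical(fields[["ElementType"]], "MET_FLOAT")) {
      stop("only MET_FLOAT MHA payloads are supported")
    }
    dims <- as.integer(strsplit(fields[["DimSize"]], " ")[[1]])
    spacing <- as.numeric(strsplit(fields[["ElementSpacing"]], " ")[[1]])
    origin <- as.numeric(strsplit(fields[["Offset"]], " ")[[1]])
    n <- prod(dims)
    vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
    if (length(vals) != n) stop("truncated MHA payload")
    volume(volume_grid(dims, spacing, origin), array(vals, dims))
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)
    aff <- RNifti::xform(img)
    origin <- aff[1:3, 4]
    vals <- array(as.numeric(img), dim = dim(img))
    volume(volume_grid(dim(img), spacing, origin), vals)
  } else {
    stop(sprintf("unknown volume format '.%s'", ext))
  }
}

#' Serialize a scan geometry to JSON
#' @param geom a [scan_geometry()].
#' @param path destination `.json` path.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "scan_geometry"))
  jsonlite::write_json(unclass(geom), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scan geometry from JSON
#' @param path file written by [write_geometry()].
#' @return a [scan_geometry()].
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("source_to_isocenter_mm", "source_to_detector_mm",
            "detector_rows", "detector_cols", "pixel_spacing_mm",
            "angles_deg", "timestamps_s")
  miss <- setdiff(need, names(g))
  if (length(miss)) {
    stop(sprintf("geometry JSON missing fields: %s",
                 paste(miss, collapse = ", ")))
  }
  scan_geometry(g$source_to_isocenter_mm, g$source_to_detector_mm,
                g$detector_rows, g$detector_cols, g$pixel_spacing_mm,
                g$angles_deg, g$timestamps_s)
}

#' Write projections as multi-page TIFF plus geometry JSON
#'
#' One 32-bit page per frame, normalized to the unit TIFF range; the
#' normalization scale, acquisition geometry and data domain go to a JSON
#' sidecar, so values round-trip to within the 32-bit quantization of the
#' stack's dynamic range.
#'
#' @param proj a [projection_set()].
#' @param path destination `.tif` path.
#' @param geometry_path destination for the geometry JSON; defaults to
#'   `path` with a `.json` extension.
#' @export
write_projections <- function(proj, path, geometry_path = NULL) {
  stopifnot(inherits(proj, "projection_set"))
  if (is.null(geometry_path)) {
    geometry_path <- paste0(tools::file_path_sans_ext(path), ".json")
  }
  lo <- min(proj$values)
  hi <- max(proj$values)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(proj$geometry$n_frames),
                  function(t) (proj$values[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(unclass(proj$geometry),
            list(domain = proj$domain, value_offset = lo,
                 value_scale = scale))
  jsonlite::write_json(meta, geometry_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read projections written by [write_projections()]
#'
#' @param path the `.tif` stack.
#' @param geometry_path the JSON sidecar; defaults to `path` with `.json`.
#' @return a [projection_set()].
#' @export
read_projections <- function(path, geometry_path = NULL) {
  if (is.null(geometry_path)) {
    geometry_path <- paste0(tools::file_path_sans_ext(path), ".json")
  }
  meta <- jsonlite::read_json(geometry_path, simplifyVector = TRUE)
  geom <- scan_geometry(meta$source_to_isocenter_mm,
                        meta$source_to_detector_mm,
                        meta$detector_rows, meta$detector_cols,
                        meta$pixel_spacing_mm, meta$angles_deg,
                        meta$timestamps_s)
  domain <- if (is.null(meta$domain)) "line_integral" else meta$domain
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != geom$n_frames) {
    stop(sprintf("frame count mismatch: %d TIFF pages vs %d frames in geometry",
                 length(pages), geom$n_frames))
  }
  lo <- if (is.null(meta$value_offset)) 0 else meta$value_offset
  scale <- if (is.null(meta$value_scale)) 1 else meta$value_scale
  vals <- array(0, c(geom$detector_rows, geom$detector_cols, geom$n_frames))
  for (t in seq_along(pages)) vals[, , t] <- pages[[t]] * scale + lo
  if (domain == "counts") vals <- pmax(vals, 0)
  projection_set(geom, vals, domain)
}

#' Serialize motion parameters to JSON
#' @param params a [motion_parameters()].
#' @param path destination `.json` path.
#' @export
write_motion_parameters <- function(params, path) {
  stopifnot(inherits(params, "motion_parameters"))
  obj <- list(
    config = unclass(params$config),
    grid = unclass(params$grid),
    time_range_s = params$time_range_s,
    n_components = params$n_components,
    components = lapply(params$components, function(cmp) {
      list(cx = as.numeric(cmp$cx), cy = as.numeric(cmp$cy),
           cz = as.numeric(cmp$cz), ct = cmp$ct)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read motion parameters written by [write_motion_parameters()]
#' @param path the `.json` file.
#' @return a [motion_parameters()].
#' @export
read_motion_parameters <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- spline_config(o$config$spatial_control_points,
                       o$config$temporal_rate_hz)
  grid <- volume_grid(o$grid$shape, o$grid$voxel_size_mm, o$grid$origin_mm)
  ncp <- cfg$spatial_control_points
  comps <- lapply(seq_len(o$n_components), function(i) {
    cmp <- if (is.data.frame(o$components)) as.list(o$components[i, ]) else o$components[[i]]
    list(cx = array(unlist(cmp$cx), ncp), cy = array(unlist(cmp$cy), ncp),
         cz = array(unlist(cmp$cz), ncp), ct = as.numeric(unlist(cmp$ct)))
  })
  motion_parameters(cfg, grid, o$time_range_s, o$n_components, comps)
}

config_presets <- function() {
  list(
    insilico = list(),
    phantom = list(spatial_control_points = 7),
    clinical = list(n_components = 3, temporal_rate_hz = 3.0,
                    max_alternations = 20))
}

#' Load a framework configuration from YAML
#'
#' Keys absent from the file take the in-silico defaults (200 SIRT
#' iterations, 100 estimation epochs, learning rate 0.1, lambda 1e-6, 32
#' spatial control points per dimension, 2.0 temporal control points per
#' second, rank 1, at most 50 alternations). Unknown keys are rejected
#' with the offending key named.
#'
#' @param path YAML file; `NULL` or an empty file gives pure defaults.
#' @param preset `"insilico"` (default), `"phantom"` (7 spatial control
#'   points) or `"clinical"` (rank 3, 3.0 temporal control points per
#'   second, at most 20 alternations); file keys override the preset.
#' @return a [moco_config()].
#' @export
load_config <- function(path = NULL,
                        preset = c("insilico", "phantom", "clinical")) {
  preset <- match.arg(preset)
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  allowed <- c("max_alternations", "convergence_rel_tol", "n_iterations",
               "nonnegativity", "extended_domain_margin", "learning_rate",
               "n_epochs", "init_scale", "rng_seed", "lambda",
               "spatial_control_points", "temporal_rate_hz", "n_components")
  bad <- setdiff(names(user), allowed)
  if (length(bad)) {
    stop(sprintf("unknown configuration key: %s", bad[1]))
  }
  opts <- utils::modifyList(config_presets()[[preset]], user)
  get_opt <- function(key, default) {
    if (!is.null(opts[[key]])) opts[[key]] else default
  }
  moco_config(
    max_alternations = get_opt("max_alternations", 50),
    convergence_rel_tol = get_opt("convergence_rel_tol", 1e-3),
    estimation = estimation_config(
      learning_rate = get_opt("learning_rate", 0.1),
      n_epochs = get_opt("n_epochs", 100),
      init_scale = get_opt("init_scale", 0.01),
      rng_seed = get_opt("rng_seed", 0L)),
    sirt = sirt_config(
      n_iterations = get_opt("n_iterations", 200),
      extended_domain_margin = get_opt("extended_domain_margin", 0.25)),
    regularizer = regularizer_config(weight = get_opt("lambda", 1e-6)),
    spline = spline_config(
      spatial_control_points = get_opt("spatial_control_points", 32),
      temporal_rate_hz = get_opt("temporal_rate_hz", 2.0)),
    n_components = get_opt("n_components", 1L))
}
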