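#' Read a multi-page TIFF stack as an intensity volume
#'
#' One TIFF page per z-slice. Pixel values are returned as stored (integer
#' grayscale), not rescaled. All pages must share the same shape.
#'
#' @param path file path.
#' @param geometry [volume_geometry()] to attach; defaults to 10 x 10 x 40 nm.
#' @return a [voxel_volume()] with z extent equal to the page count.
#' @export
read_stack <- function(path, geometry = volume_geometry()) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("ragged TIFF: pages have differing shapes in ", path)
  d <- dims[[1]]
  if (length(d) != 2L)
    stop("unsupported TIFF layout (expected single-channel grayscale pages) in ", path)
  arr <- array(0, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  voxel_volume(arr, geometry)
}

#' Write an intensity volume as a multi-page TIFF
#'
#' Values are stored at the requested integer bit depth; the volume must fit
#' in `[0, 2^bits - 1]`. Round-trips through [read_stack()] are bit-exact for
#' integer-valued volumes.
#'
#' @param volume a [voxel_volume()] (or 3D array).
#' @param path output path.
#' @param bits 8 or 16.
#' @export
write_stack <- function(volume, path, bits = 8L) {
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16")
  if (any(volume < 0) || any(volume > 2^bits - 1))
    stop("volume values outside [0, ", 2^bits - 1, "]; rescale before writing")
  scale <- 2^bits - 1
  slices <- lapply(seq_len(dim(volume)[3]),
                   function(k) volume[, , k, drop = TRUE] / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

# ---- NRRD (minimal: 3D, raw encoding) ---------------------------------------
# No NRRD reader exists in the R stack used here, so a minimal reader/writer
# for detached-free, raw-encoded 3D NRRD files is provided. Covers the label
# volumes this pipeline exchanges (uint8/uint16/int16/int32/float/double).

.nrrd_types <- list(
  uint8  = list(what = "integer", size = 1, signed = FALSE),
  uint16 = list(what = "integer", size = 2, signed = FALSE),
  int16  = list(what = "integer", size = 2, signed = TRUE),
  int32  = list(what = "integer", size = 4, signed = TRUE),
  float  = list(what = "double",  size = 4, signed = TRUE),
  double = list(what = "double",  size = 8, signed = TRUE))

#' Read a raw-encoded 3D NRRD file
#'
#' Minimal NRRD support: dimension 3, `encoding: raw`, attached data.
#' `spacings` in the header, when present, populate the returned geometry.
#'
#' @param path file path.
#' @param geometry optional [volume_geometry()] override; if `NULL`, header
#'   spacings (or unit spacing) are used.
#' @return a plain 3D array with a `geometry` attribute.
#' @export
read_nrrd <- function(path, geometry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not a NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  if (is.null(fields$dimension) || as.integer(fields$dimension) != 3L)
    stop("only 3D NRRD volumes are supported")
  if (!identical(fields$encoding, "raw"))
    stop("only raw-encoded NRRD is supported (got ", fields$encoding, ")")
  type <- fields$type
  if (type %in% c("unsigned char", "uchar")) type <- "uint8"
  if (type %in% c("unsigned short")) type <- "uint16"
  if (type %in% c("short")) type <- "int16"
  if (type %in% c("int", "signed int")) type <- "int32"
  spec <- .nrrd_types[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("bad sizes field in ", path)
  endian <- if (!is.null(fields$endian)) fields$endian else "little"
  n <- prod(sizes)
  vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = if (spec$size >= 4) TRUE else spec$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NRRD data in ", path)
  arr <- array(vals, dim = sizes)
  if (is.null(geometry)) {
    sp <- c(1, 1, 1)
    if (!is.null(fields$spacings)) {
      sp3 <- suppressWarnings(as.numeric(strsplit(fields$spacings, "\\s+")[[1]]))
      if (length(sp3) == 3L && all(is.finite(sp3)) && all(sp3 > 0)) sp <- sp3
    }
    # stored axis order is (row=y, col=x, slice=z); spacings are per stored axis
    geometry <- volume_geometry(spacing = c(sp[2], sp[1], sp[3]))
  }
  attr(arr, "geometry") <- geometry
  arr
}

#' Write a 3D array as a raw-encoded NRRD file
#'
#' @param data 3D array (integer arrays are written as `uint8` when they fit,
#'   otherwise `int32`; doubles as `double`).
#' @param path output path.
#' @param geometry optional [volume_geometry()]; spacings are recorded
#'   per stored axis (row, column, slice).
#' @export
write_nrrd <- function(data, path, geometry = attr(data, "geometry")) {
  if (!is.array(data) || length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (is.logical(data)) storage.mode(data) <- "integer"
  if (is.integer(data)) {
    if (min(data) >= 0L && max(data) <= 255L) {
      type <- "uint8"; size <- 1
    } else {
      type <- "int32"; size <- 4
    }
  } else {
    type <- "double"; size <- 8
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by myoquant",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(data), collapse = " ")),
           "encoding: raw",
           "endian: little")
  if (!is.null(geometry)) {
    s <- geometry$spacing
    hdr <- c(hdr, paste0("spacings: ", s[["y"]], " ", s[["x"]], " ", s[["z"]]))
  }
  writeLines(c(hdr, ""), con, sep = "\n")
  writeBin(as.vector(data), con, size = size, endian = "little")
  invisible(path)
}

#' Write / read a label volume (NRRD or TIFF by extension)
#'
#' @param labels a [label_volume()].
#' @param path output path ending in `.nrrd`, `.tif` or `.tiff`.
#' @export
write_label_volume <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    write_nrrd(labels, path, geometry = volume_geom(labels))
  } else if (ext %in% c("tif", "tiff")) {
    arr <- labels
    attributes(arr) <- list(dim = dim(labels))
    write_stack(arr, path, bits = 8L)
  } else stop("unsupported label volume extension: .", ext)
  invisible(path)
}

#' Read and validate a label volume produced externally
#'
#' Accepts per-voxel label files from any segmentation tool (for example a
#' deep-learning segmenter run elsewhere). Every stored value must be
#' declared in `class_map`; undeclared values are an error listing the
#' offending values.
#'
#' @param path NRRD or TIFF file.
#' @param class_map named integer vector, see [em_class_map()].
#' @param geometry optional [volume_geometry()] override.
#' @param quiet suppress the per-class voxel count log message.
#' @return a validated [label_volume()].
#' @export
ingest_label_volume <- function(path, class_map = em_class_map(),
                                geometry = NULL, quiet = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    arr <- read_nrrd(path, geometry = geometry)
    geom <- attr(arr, "geometry")
  } else if (ext %in% c("tif", "tiff")) {
    vol <- read_stack(path, geometry = if (is.null(geometry)) volume_geometry() else geometry)
    arr <- unclass(vol)
    geom <- volume_geom(vol)
    attributes(arr) <- list(dim = dim(arr))
  } else stop("unsupported label volume extension: .", ext)
  lv <- label_volume(arr, geometry = geom, class_map = class_map)
  if (!quiet) {
    counts <- label_counts(lv)
    message("ingested label volume ", basename(path), ": ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  lv
}

# ---- tables and reports -----------------------------------------------------

#' Write a per-object angle table as CSV
#'
#' Schema: `object_id, theta_deg, phi_deg, n_voxels` (matching the layout of
#' per-myofibril angle source tables). Values are written at full precision
#' with "." as the decimal separator regardless of locale.
#'
#' @param angles data.frame with at least those columns.
#' @param path output CSV path.
#' @export
write_angle_table <- function(angles, path) {
  need <- c("object_id", "theta_deg", "phi_deg", "n_voxels")
  miss <- setdiff(need, names(angles))
  if (length(miss)) stop("angle table missing columns: ", paste(miss, collapse = ", "))
  out <- angles[need]
  for (cl in c("theta_deg", "phi_deg"))
    out[[cl]] <- trimws(formatC(out[[cl]], digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-object angle table
#'
#' Tolerant reader for per-myofibril angle CSVs: column names are matched
#' case-insensitively and `theta`/`phi`/`angle` prefixes are accepted, so
#' externally produced tables with one angle column also load.
#'
#' @param path CSV path.
#' @return data.frame with columns `object_id`, `theta_deg`, `phi_deg`,
#'   `n_voxels` (absent ones filled with `NA`).
#' @export
read_angle_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  nm <- tolower(names(raw))
  pick <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, nm)
      if (length(hit)) return(raw[[hit[1]]])
    }
    rep(NA_real_, nrow(raw))
  }
  data.frame(
    object_id = {
      id <- pick(c("^object_id$", "^fibril_id$", "\\bid\\b", "^object"))
      if (all(is.na(id))) seq_len(nrow(raw)) else id
    },
    theta_deg = as.numeric(pick(c("^theta_deg$", "theta", "transmural"))),
    phi_deg = as.numeric(pick(c("^phi_deg$", "phi", "elliptical"))),
    n_voxels = as.numeric(pick(c("^n_voxels$", "voxel", "area", "pixel")))
  )
}

#' Write an analysis report (fraction report, aggregate, or angle summary)
#'
#' Data frames go to CSV at full precision; lists (for example an
#' `angle_summary`) go to JSON. Mandatory numeric fields must be finite.
#'
#' @param report data.frame or list.
#' @param path output path (`.csv` or `.json`).
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  check_finite <- function(x, where) {
    if (is.numeric(x) && any(is.nan(x)))
      stop("NaN in mandatory report field: ", where)
  }
  if (is.data.frame(report)) {
    for (nm in names(report)) check_finite(report[[nm]], nm)
    if (ext != "csv") stop("data.frame reports are written as CSV")
    out <- report
    for (nm in names(out))
      if (is.double(out[[nm]]))
        out[[nm]] <- trimws(formatC(out[[nm]], digits = 17, format = "g"))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (is.list(report)) {
    rapply(report, function(x) check_finite(x, "list field"), how = "unlist")
    if (ext != "json") stop("list reports are written as JSON")
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else stop("unsupported report type")
  invisible(path)
}

#' Read a phantom or pipeline configuration file (YAML or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param require_seed error when no `seed` entry is present (mandatory for
#'   simulation configs).
#' @return named list.
#' @export
read_config <- function(path, require_seed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config extension: .", ext))
  if (require_seed && is.null(cfg$seed))
    stop("config ", path, " has no `seed` entry (mandatory)")
  cfg
}

#' Read a landmark table
#'
#' Expected columns: `frame, x, y[, z], unit`. Frames and units are explicit;
#' no unit inference is performed.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lm <- utils::read.csv(path)
  need <- c("frame", "x", "y", "unit")
  miss <- setdiff(need, names(lm))
  if (length(miss)) stop("landmark table missing columns: ", paste(miss, collapse = ", "))
  lm
}
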