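#' Class maps for label volumes
#'
#' `em_class_map()` is the ultrastructural segmentation alphabet used
#' throughout the EM pipeline: extracellular space, nucleus, mitochondrion,
#' myofibril, remaining (other) cytoplasm, and an ignore value for voxels
#' outside the evaluated region. `heart_class_map()` is the whole-heart
#' micro-CT alphabet: background, tissue, and the two ventricular lumens.
#'
#' @return named integer vector mapping class names to stored voxel values.
#' @export
em_class_map <- function() {
  c(extracellular = 0L, nucleus = 1L, mitochondrion = 2L,
    myofibril = 3L, cytoplasm = 4L, outside = 255L)
}

#' @rdname em_class_map
#' @export
heart_class_map <- function() {
  c(background = 0L, tissue = 1L, lv_lumen = 2L, rv_lumen = 3L)
}

#' Intensity volume container
#'
#' A 3D numeric array of grayscale values with attached [volume_geometry()].
#' Array dimensions are `(ny, nx, nz)`: rows index y, columns index x,
#' the third margin indexes z-slices, matching image row/column order.
#'
#' @param data 3D numeric array.
#' @param geometry a [volume_geometry()].
#' @return object of class `voxel_volume` (a plain array with attributes).
#' @export
voxel_volume <- function(data, geometry = volume_geometry()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(data)) stop("`data` must be numeric")
  stopifnot(inherits(geometry, "volume_geometry"))
  structure(data, geometry = geometry, class = c("voxel_volume", "array"))
}

#' Label volume container
#'
#' Integer class mask over a voxel grid. Every voxel carries exactly one
#' class and the class map is closed: any stored value not declared in
#' `class_map` is an error.
#'
#' @param data 3D integer array.
#' @param geometry a [volume_geometry()].
#' @param class_map named integer vector (see [em_class_map()]).
#' @return object of class `label_volume`.
#' @export
label_volume <- function(data, geometry = volume_geometry(),
                         class_map = em_class_map()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (is.double(data)) {
    if (any(data != round(data), na.rm = TRUE))
      stop("label data must be integer-valued")
    storage.mode(data) <- "integer"
  }
  if (anyNA(data)) stop("label data must not contain NA")
  if (is.null(names(class_map)) || any(names(class_map) == ""))
    stop("`class_map` must be a fully named integer vector")
  bad <- setdiff(unique(as.vector(data)), as.integer(class_map))
  if (length(bad))
    stop("undeclared label values present: ", paste(sort(bad), collapse = ", "))
  stopifnot(inherits(geometry, "volume_geometry"))
  structure(data, geometry = geometry, class_map = as.integer(class_map) |>
              stats::setNames(names(class_map)),
            class = c("label_volume", "array"))
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  g <- volume_geom(x)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels (y, x, z); spacing (%g, %g, %g) %s\n",
              d[1], d[2], d[3], g$spacing[1], g$spacing[2], g$spacing[3], g$unit))
  cat(sprintf("  intensity range [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cm <- attr(x, "class_map")
  cat(sprintf("<label_volume> %d x %d x %d voxels (y, x, z)\n", d[1], d[2], d[3]))
  counts <- label_counts(x)
  for (nm in names(counts))
    cat(sprintf("  %-14s %d (%d)\n", nm, cm[[nm]], counts[[nm]]))
  invisible(x)
}

#' Geometry accessor
#' @param x a `voxel_volume` or `label_volume`.
#' @return the attached [volume_geometry()].
#' @export
volume_geom <- function(x) {
  g <- attr(x, "geometry")
  if (is.null(g)) stop("object carries no geometry")
  g
}

#' Per-class voxel counts of a label volume
#' @param x a `label_volume`.
#' @return named integer vector, one entry per declared class (zeros kept).
#' @export
label_counts <- function(x) {
  cm <- attr(x, "class_map")
  if (is.null(cm)) stop("`x` is not a label_volume")
  tab <- tabulate(match(as.vector(x), cm), nbins = length(cm))
  stats::setNames(as.integer(tab), names(cm))
}
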