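#' Voxel grid geometry
#'
#' Ties voxel indices of a 3D stack to physical coordinates. The axis
#' semantics follow the SBF-SEM acquisition convention: `x` is the in-plane
#' direction approximately parallel to the ventricular wall (circumferential),
#' `y` is the in-plane radial direction, and `z` is the stack/section
#' (longitudinal) direction. A voxel at (row i, column j, slice k), 0-based,
#' sits at physical position `(x, y, z) = (j*sx, i*sy, k*sz) + origin`.
#'
#' @param spacing numeric length-3, physical length per voxel along (x, y, z).
#'   Defaults to the acquisition geometry of 10 nm lateral and 40 nm section
#'   spacing.
#' @param unit length unit label (metadata only; no conversion is performed).
#' @param origin physical offset of voxel (0, 0, 0).
#' @return An object of class `volume_geometry`.
#' @examples
#' g <- volume_geometry()
#' voxel_to_physical(cbind(i = 0, j = 3, k = 2), g)  # x = 30, y = 0, z = 80
#' @export
volume_geometry <- function(spacing = c(10, 10, 40), unit = "nm",
                            origin = c(0, 0, 0)) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  structure(
    list(spacing = c(x = spacing[1], y = spacing[2], z = spacing[3]),
         unit = as.character(unit)[1],
         origin = c(x = origin[1], y = origin[2], z = origin[3])),
    class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry> spacing (%g, %g, %g) %s; origin (%g, %g, %g)\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$unit,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Convert voxel indices to physical coordinates
#'
#' @param ijk matrix (or vector) of voxel indices with columns (i, j, k).
#'   Indices are 0-based by default; set `one_based = TRUE` to pass R-style
#'   array indices.
#' @param geometry a [volume_geometry()].
#' @param one_based logical; are the supplied indices 1-based?
#' @return numeric matrix with columns (x, y, z).
#' @export
voxel_to_physical <- function(ijk, geometry, one_based = FALSE) {
  stopifnot(inherits(geometry, "volume_geometry"))
  ijk <- rbind(ijk)
  if (ncol(ijk) != 3L) stop("`ijk` must have 3 columns (i, j, k)")
  off <- if (one_based) 1 else 0
  s <- geometry$spacing
  o <- geometry$origin
  cbind(x = (ijk[, 2] - off) * s[["x"]] + o[["x"]],
        y = (ijk[, 1] - off) * s[["y"]] + o[["y"]],
        z = (ijk[, 3] - off) * s[["z"]] + o[["z"]])
}

#' Physical voxel volume (product of spacings)
#' @param geometry a [volume_geometry()].
#' @return scalar, in `unit^3`.
#' @export
voxel_physical_volume <- function(geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  prod(geometry$spacing)
}
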