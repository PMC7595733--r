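# Landmark-based similarity transforms between imaging frames (micro-CT,
# semithin section, EM sub-ROI). Blood vessels and trabeculae act as the
# landmarks in practice; here any point correspondences in explicit frames
# are accepted. Similarity (isotropic scale + rotation + translation) is the
# default model because physical sections rotate, translate and shrink
# approximately isotropically.

#' Least-squares similarity transform between landmark sets
#'
#' Closed-form least-squares fit (Umeyama/Procrustes) of the similarity
#' transform `q = s * R * p + t` minimizing the sum of squared residuals
#' over the point pairs. Works in 2D (>= 2 non-coincident pairs) or 3D
#' (>= 3 non-collinear pairs). Reflections are excluded (det(R) = +1).
#'
#' @param src,dst numeric matrices of corresponding points, one row per
#'   landmark, 2 or 3 columns.
#' @param source_frame,target_frame frame identifiers carried on the map.
#' @param allow_affine if `TRUE`, fit a full affine map instead (available
#'   behind this flag for sections with anisotropic distortion; logged in
#'   the returned object).
#' @return object of class `similarity_map`: `scale`, `rotation` (matrix),
#'   `translation`, `source_frame`, `target_frame`, `rms` (residual RMS
#'   over the fitting landmarks), `model`.
#' @export
estimate_similarity <- function(src, dst, source_frame = "source",
                                target_frame = "target",
                                allow_affine = FALSE) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  storage.mode(src) <- "double"; storage.mode(dst) <- "double"
  if (!identical(dim(src), dim(dst)))
    stop("landmark sets must have matching dimensions")
  d <- ncol(src); n <- nrow(src)
  if (!d %in% c(2L, 3L)) stop("landmarks must be 2D or 3D")
  if (n < d) stop("need at least ", d, " point pairs in ", d, "D")
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  cs <- sweep(src, 2, mu_s); cd <- sweep(dst, 2, mu_d)
  var_s <- sum(cs^2) / n
  if (var_s == 0) stop("degenerate configuration: source landmarks coincide")
  if (allow_affine) {
    if (n < d + 1) stop("affine fit needs at least ", d + 1, " pairs")
    A <- tryCatch(qr.solve(cbind(src, 1), dst),
                  error = function(e) stop("degenerate configuration: ",
                                           conditionMessage(e)))
    fitted <- cbind(src, 1) %*% A
    map <- structure(list(scale = NA_real_, rotation = t(A[seq_len(d), , drop = FALSE]),
                          translation = A[d + 1, ], source_frame = source_frame,
                          target_frame = target_frame,
                          rms = sqrt(mean(rowSums((dst - fitted)^2))),
                          model = "affine"),
                     class = "similarity_map")
    return(map)
  }
  H <- crossprod(cd, cs) / n          # d x d covariance between sets
  sv <- svd(H)
  if (d == 3L && sv$d[2] <= 1e-12 * max(sv$d[1], .Machine$double.eps))
    stop("degenerate configuration: landmarks are collinear")
  S <- diag(d)
  if (det(sv$u %*% t(sv$v)) < 0) S[d, d] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  s <- sum(diag(diag(sv$d, d, d) %*% S)) / var_s
  if (s <= 0) stop("degenerate configuration: non-positive scale")
  t_vec <- mu_d - s * as.vector(R %*% mu_s)
  fitted <- t(s * R %*% t(src) + t_vec)
  structure(list(scale = s, rotation = R, translation = t_vec,
                 source_frame = source_frame, target_frame = target_frame,
                 rms = sqrt(mean(rowSums((dst - fitted)^2))),
                 model = "similarity"),
            class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  ang <- if (nrow(x$rotation) == 2L)
    sprintf("; rotation %.3f deg", atan2(x$rotation[2, 1], x$rotation[1, 1]) * 180 / pi)
  else ""
  cat(sprintf("<similarity_map> %s -> %s (%s): scale %s%s; RMS %.3g\n",
              x$source_frame, x$target_frame, x$model,
              if (is.na(x$scale)) "affine" else format(x$scale), ang, x$rms))
  invisible(x)
}

#' Apply a similarity map to points
#'
#' Exact affine application `s * R * p + t`. When the points carry a frame
#' attribute it must match the map's source frame.
#'
#' @param map a `similarity_map`.
#' @param points matrix of points (rows) in the source frame; may carry a
#'   `frame` attribute.
#' @return matrix of mapped points with `frame` set to the target frame.
#' @export
map_points <- function(map, points) {
  stopifnot(inherits(map, "similarity_map"))
  fr <- attr(points, "frame")  # read before rbind(), which drops attributes
  points <- rbind(points)
  if (!is.null(fr) && !identical(fr, map$source_frame))
    stop("frame mismatch: points are in '", fr, "', map expects '",
         map$source_frame, "'")
  s <- if (is.na(map$scale)) 1 else map$scale
  out <- t(s * map$rotation %*% t(points) + map$translation)
  attr(out, "frame") <- map$target_frame
  out
}

#' Invert a similarity map
#' @param map a `similarity_map` (similarity model only).
#' @return the inverse map (target frame back to source frame).
#' @export
invert_similarity <- function(map) {
  stopifnot(inherits(map, "similarity_map"))
  if (is.na(map$scale)) stop("only similarity-model maps are invertible here")
  Rinv <- t(map$rotation)
  sinv <- 1 / map$scale
  structure(list(scale = sinv, rotation = Rinv,
                 translation = -sinv * as.vector(Rinv %*% map$translation),
                 source_frame = map$target_frame, target_frame = map$source_frame,
                 rms = NA_real_, model = "similarity"),
            class = "similarity_map")
}

#' Compose two similarity maps
#'
#' `compose_similarity(a, b)` is "b after a": points in `a`'s source frame
#' are mapped to `b`'s target frame. `a`'s target frame must equal `b`'s
#' source frame.
#'
#' @param a,b `similarity_map`s.
#' @return the composed `similarity_map`.
#' @export
compose_similarity <- function(a, b) {
  stopifnot(inherits(a, "similarity_map"), inherits(b, "similarity_map"))
  if (!identical(a$target_frame, b$source_frame))
    stop("broken chain: map into '", a$target_frame,
         "' cannot feed map from '", b$source_frame, "'")
  if (is.na(a$scale) || is.na(b$scale)) stop("composition requires similarity models")
  structure(list(scale = b$scale * a$scale,
                 rotation = b$rotation %*% a$rotation,
                 translation = b$scale * as.vector(b$rotation %*% a$translation) +
                   b$translation,
                 source_frame = a$source_frame, target_frame = b$target_frame,
                 rms = NA_real_, model = "similarity"),
            class = "similarity_map")
}

#' Map a sub-ROI rectangle through a chain of frames
#'
#' Composes the given maps (in order: sub-ROI -> ... -> micro-CT) and maps
#' the rectangle's corners through the composed transform.
#'
#' @param maps list of `similarity_map`s whose frames chain
#'   (each map's target is the next map's source).
#' @param rect corner points of the sub-ROI rectangle (matrix, one corner
#'   per row) in the first map's source frame.
#' @return polygon matrix of mapped corners, with `frame` attribute set to
#'   the final target frame.
#' @export
locate_subroi <- function(maps, rect) {
  if (!length(maps)) stop("broken chain: no maps supplied")
  comp <- maps[[1]]
  for (m in maps[-1]) comp <- compose_similarity(comp, m)
  map_points(comp, rect)
}
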