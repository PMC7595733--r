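# Baseline intensity segmentation of the extracellular space, morphological
# cleanup, and the pixelwise accuracy evaluator. Organelle segmentation by
# deep learning is deliberately not reimplemented: external per-voxel label
# volumes are accepted through ingest_label_volume() and scored with
# evaluate_segmentation().

#' Segment the extracellular space by intensity
#'
#' The extracellular space (resin-filled) is recognized purely by its
#' intensity level. Three threshold choices are supported:
#' * `fixed` — a user-supplied threshold `t`; the mask is exactly the set of
#'   voxels on the EC side of `t`.
#' * `bimodal-valley` — the minimum of a smoothed intensity density between
#'   its two dominant modes; fails on a unimodal histogram with advice to
#'   use `fixed`.
#' * `quantile` — the `1 - q` upper quantile when EC is bright (`q` is the
#'   EC volume fraction to select; `q = 0` selects nothing).
#'
#' @param volume a [voxel_volume()].
#' @param method one of `"fixed"`, `"bimodal-valley"`, `"quantile"`.
#' @param threshold threshold for `method = "fixed"`.
#' @param q EC fraction for `method = "quantile"`.
#' @param ec_bright is the extracellular phase the bright side? (default
#'   TRUE: resin backscatters more than stained tissue in these stacks).
#' @return logical 3D array (same shape), `TRUE` = extracellular; attribute
#'   `threshold` records the cut used.
#' @export
segment_extracellular <- function(volume,
                                  method = c("bimodal-valley", "fixed", "quantile"),
                                  threshold = NULL, q = NULL,
                                  ec_bright = TRUE) {
  method <- match.arg(method)
  if (length(volume) == 0) stop("`volume` is empty")
  v <- as.vector(volume)
  t <- switch(method,
    "fixed" = {
      if (is.null(threshold)) stop("`threshold` required for method = \"fixed\"")
      threshold
    },
    "quantile" = {
      if (is.null(q)) stop("`q` required for method = \"quantile\"")
      if (q < 0 || q > 1) stop("`q` must lie in [0, 1]")
      if (q == 0) Inf * (if (ec_bright) 1 else -1)
      else stats::quantile(v, probs = if (ec_bright) 1 - q else q, names = FALSE)
    },
    "bimodal-valley" = .valley_threshold(v)
  )
  mask <- if (ec_bright) array(volume >= t, dim = dim(volume))
          else array(volume <= t, dim = dim(volume))
  attr(mask, "threshold") <- t
  attr(mask, "geometry") <- attr(volume, "geometry")
  mask
}

# Valley between the two dominant modes of a smoothed intensity density.
.valley_threshold <- function(v) {
  if (length(v) > 2e6) v <- v[seq(1, length(v), length.out = 2e6)]
  d <- stats::density(v, n = 512)
  y <- d$y
  ispeak <- which(diff(sign(diff(y))) == -2) + 1L
  ispeak <- ispeak[y[ispeak] > 0.05 * max(y)]
  if (length(ispeak) < 2L)
    stop("intensity histogram is unimodal; no valley to threshold on - ",
         "use method = \"fixed\" with an explicit threshold")
  top2 <- ispeak[order(y[ispeak], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  d$x[lo + which.min(y[lo:hi]) - 1L]
}

#' Morphological cleanup of a binary mask
#'
#' Fixed operation order: closing (ball dilation then erosion), hole
#' filling (background components not connected to the volume border become
#' foreground), then removal of connected components smaller than
#' `min_object_voxels`. Idempotent: applying it twice equals applying it
#' once. Connectivity for components is 26-neighbour; holes use the
#' complementary 6-neighbour background connectivity.
#'
#' @param mask logical 3D array.
#' @param min_object_voxels smallest surviving component size (0 keeps all).
#' @param closing_radius ball radius in voxels (0 = no closing).
#' @param fill_holes fill enclosed background cavities?
#' @return cleaned logical array.
#' @export
cleanup_mask <- function(mask, min_object_voxels = 0L, closing_radius = 0,
                         fill_holes = FALSE) {
  if (min_object_voxels < 0) stop("`min_object_voxels` must be >= 0")
  if (closing_radius < 0) stop("`closing_radius` must be >= 0")
  d <- dim(mask)
  m <- as.logical(mask)
  if (closing_radius > 0) {
    m <- .ball_morph_3d(m, d, closing_radius, TRUE)
    m <- .ball_morph_3d(m, d, closing_radius, FALSE)
  }
  if (fill_holes) {
    bg <- .cc_label_3d(!m, d, 6L)
    bga <- array(bg, dim = d)
    border <- unique(c(bga[1, , ], bga[d[1], , ], bga[, 1, ], bga[, d[2], ],
                       bga[, , 1], bga[, , d[3]]))
    border <- border[border != 0L]
    m <- m | !(bg %in% c(0L, border))
  }
  if (min_object_voxels > 0) {
    lab <- .cc_label_3d(m, d, 26L)
    ncomp <- attr(lab, "n_components")
    if (ncomp > 0) {
      sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
      keep <- which(sizes >= min_object_voxels)
      m <- m & (lab %in% keep)
    }
  }
  out <- array(m, dim = d)
  attr(out, "geometry") <- attr(mask, "geometry")
  out
}

#' Pixelwise segmentation accuracy against a reference labelling
#'
#' Per-class accuracy is truth-class recall: the fraction of voxels of that
#' truth class that the prediction labels correctly, in percent. The overall
#' pixel accuracy and the full confusion matrix are also reported. Voxels
#' whose truth is the ignore class are excluded. A class absent from the
#' truth has undefined accuracy, reported as `NA`.
#'
#' @param predicted,truth [label_volume()]s of equal shape sharing a class
#'   map.
#' @param classes class names to score (default: all non-ignore classes in
#'   the map).
#' @param ignore_class name of the ignore class (default `"outside"` when
#'   present).
#' @return object of class `segmentation_accuracy`: list with `per_class`
#'   (named percentages), `overall` (percent), `confusion` (truth x
#'   predicted counts), `n_pixels`.
#' @export
evaluate_segmentation <- function(predicted, truth, classes = NULL,
                                  ignore_class = "outside") {
  if (!identical(dim(predicted), dim(truth)))
    stop("predicted and truth shapes differ")
  cm <- attr(truth, "class_map")
  if (is.null(cm)) cm <- attr(predicted, "class_map")
  if (is.null(cm)) stop("no class map on either volume")
  keep_names <- names(cm)
  if (!is.null(ignore_class) && ignore_class %in% keep_names) {
    sel <- as.vector(truth) != cm[[ignore_class]]
    keep_names <- setdiff(keep_names, ignore_class)
  } else sel <- rep(TRUE, length(truth))
  tv <- factor(as.vector(truth)[sel], levels = cm[keep_names], labels = keep_names)
  pv <- factor(as.vector(predicted)[sel], levels = cm[keep_names], labels = keep_names)
  conf <- table(truth = tv, predicted = pv)
  n <- sum(conf)
  per <- 100 * diag(conf) / rowSums(conf)  # NaN when class absent from truth
  per[is.nan(per)] <- NA_real_
  if (!is.null(classes)) per <- per[classes]
  structure(list(per_class = per,
                 overall = 100 * sum(diag(conf)) / n,
                 confusion = conf, n_pixels = n),
            class = "segmentation_accuracy")
}

#' @export
print.segmentation_accuracy <- function(x, ...) {
  cat(sprintf("<segmentation_accuracy> %d voxels; overall %.2f%%\n",
              x$n_pixels, x$overall))
  for (nm in names(x$per_class))
    cat(sprintf("  %-14s %s\n", nm,
                if (is.na(x$per_class[[nm]])) "undefined (class absent in truth)"
                else sprintf("%.2f%%", x$per_class[[nm]])))
  invisible(x)
}
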