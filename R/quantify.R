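# Stereological quantification: the slice-sampling rule, the area-fraction
# formulas S_E/S_T and S_i/(S_T - S_E), their aggregation, and the
# whole-heart ventricular volume ratio.

#' Evenly spaced slice sampling
#'
#' Returns every `stride`-th slice starting from the first, plus the final
#' slice when it is not already a multiple of the stride. This rule
#' reproduces the published sampling counts: 17 slices from an 800-slice
#' stack and 21 from a 1000-slice stack at stride 50 ("every 50th image"),
#' which plain multiples alone (16 and 20) would not.
#'
#' @param n_slices number of slices in the stack (>= 1).
#' @param stride sampling stride (>= 1).
#' @return strictly increasing 1-based slice indices.
#' @examples
#' length(sample_slices(800, 50))   # 17
#' length(sample_slices(1000, 50))  # 21
#' @export
sample_slices <- function(n_slices, stride) {
  n_slices <- as.integer(n_slices)
  stride <- as.integer(stride)
  if (n_slices < 1L) stop("`n_slices` must be >= 1")
  if (stride < 1L) stop("`stride` must be >= 1")
  idx <- seq.int(1L, n_slices, by = stride)
  if (idx[length(idx)] != n_slices) idx <- c(idx, n_slices)
  idx
}

#' Area/volume fractions of a labelled region
#'
#' Tallies, over the selected voxels, the total evaluated area `S_T` and the
#' areas of extracellular space `S_E`, nuclei `S_N`, mitochondria `S_Mit`
#' and myofibrils `S_Myo`, then derives the extracellular fraction
#' `S_E / S_T` and the organelle-per-cell fractions `S_i / (S_T - S_E)`.
#' Counts are exact integer tallies; `outside` voxels are excluded from
#' `S_T`. When the region is all extracellular (`S_T == S_E`) the organelle
#' fractions are undefined and reported as `NA`, not 0.
#'
#' @param labels a [label_volume()] with the EM class map.
#' @param slices optional slice indices (e.g. from [sample_slices()]).
#' @param crop optional rectangular crop `list(i = range, j = range)` in
#'   voxel indices, recorded in the report for provenance.
#' @param region_id identifier copied into the report.
#' @return one-row data.frame of class `fraction_report`: voxel tallies,
#'   fractions, and the crop/slice provenance.
#' @export
compute_fractions <- function(labels, slices = NULL, crop = NULL,
                              region_id = NA_character_) {
  cm <- attr(labels, "class_map")
  if (is.null(cm)) stop("`labels` must be a label_volume")
  sub <- labels
  if (!is.null(slices)) sub <- sub[, , slices, drop = FALSE]
  if (!is.null(crop)) {
    sub <- sub[crop$i, crop$j, , drop = FALSE]
  }
  v <- as.vector(sub)
  if ("outside" %in% names(cm)) v <- v[v != cm[["outside"]]]
  if (length(v) == 0L) stop("region is empty after excluding ignore-class voxels")
  s_t <- length(v)
  cnt <- function(cls) sum(v == cm[[cls]])
  s_e <- cnt("extracellular"); s_n <- cnt("nucleus")
  s_mit <- cnt("mitochondrion"); s_myo <- cnt("myofibril")
  cell <- s_t - s_e
  frac <- function(x) if (cell == 0L) NA_real_ else x / cell
  rep_ <- data.frame(
    region_id = region_id,
    S_T = s_t, S_E = s_e, S_N = s_n, S_Mit = s_mit, S_Myo = s_myo,
    ec_fraction = s_e / s_t,
    nucleus_fraction = frac(s_n),
    mito_fraction = frac(s_mit),
    myo_fraction = frac(s_myo),
    slices = if (is.null(slices)) "all" else paste(slices, collapse = ";"),
    crop = if (is.null(crop)) "full" else
      sprintf("i%d:%d,j%d:%d", min(crop$i), max(crop$i), min(crop$j), max(crop$j)),
    stringsAsFactors = FALSE)
  class(rep_) <- c("fraction_report", "data.frame")
  rep_
}

#' Aggregate fraction reports
#'
#' Mean and sample standard deviation (n-1 denominator) of each fraction
#' across reports, the representation used when a dataset is quantified
#' from several slices or crops. Undefined (`NA`) fractions are excluded
#' per quantity with their count logged in `n_undefined`. A single report
#' gets SD 0 by convention, flagged by `n = 1`.
#'
#' @param reports a `fraction_report` (rows = regions) or list of them.
#' @return data.frame with columns `quantity, mean, sd, n, n_undefined`.
#' @export
aggregate_fractions <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  if (nrow(reports) < 1L) stop("need at least one report")
  qs <- c("ec_fraction", "nucleus_fraction", "mito_fraction", "myo_fraction")
  out <- lapply(qs, function(q) {
    x <- reports[[q]]
    nu <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      return(data.frame(quantity = q, mean = NA_real_, sd = NA_real_,
                        n = 0L, n_undefined = nu))
    data.frame(quantity = q, mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               n = length(x), n_undefined = nu)
  })
  res <- do.call(rbind, out)
  if (all(res$n == 0L)) stop("all values undefined; nothing to aggregate")
  res
}

#' Ventricular lumen volumes and RV/LV ratio
#'
#' Lumen volumes are voxel counts times the physical voxel volume; the
#' ratio is RV volume / LV volume. Published reference points: about 0.6
#' for a normal heart and about 1.3 for a tetralogy-of-Fallot heart at the
#' same developmental stage.
#'
#' @param heart a [label_volume()] with the heart class map
#'   ([heart_class_map()]); both lumen classes must be present.
#' @return list `lv_volume`, `rv_volume` (physical units^3), `rv_over_lv`.
#' @export
ventricle_volume_ratio <- function(heart) {
  cm <- attr(heart, "class_map")
  if (is.null(cm) || !all(c("lv_lumen", "rv_lumen") %in% names(cm)))
    stop("`heart` must be a label_volume with lv_lumen and rv_lumen classes")
  counts <- label_counts(heart)
  for (cls in c("lv_lumen", "rv_lumen"))
    if (counts[[cls]] == 0L)
      stop("lumen class absent from volume: ", cls)
  vv <- voxel_physical_volume(volume_geom(heart))
  lv <- counts[["lv_lumen"]] * vv
  rv <- counts[["rv_lumen"]] * vv
  list(lv_volume = lv, rv_volume = rv, rv_over_lv = rv / lv)
}
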