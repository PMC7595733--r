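#' Parameters for a synthetic EM phantom volume
#'
#' Describes a phantom SBF-SEM sub-ROI: cylindrical myofibrils with folded
#' normal transmural (theta) and elliptical (phi) angle distributions,
#' ellipsoidal nuclei, blob-like mitochondria, an extracellular phase of
#' controlled volume fraction carved from the remaining cytoplasm, per-class
#' grayscale means with i.i.d. Gaussian noise, optional per-slice brightness
#' offsets and per-slice translation jitter.
#'
#' Angles are *axial*: a draw from `N(mean, sd)` is folded modulo 180 degrees
#' into `[0, 180)`, because fibrils are unoriented axes. `theta` is the angle
#' of the axis's x-y projection from +x (circumferential); `phi` the angle of
#' its x-z projection from +x.
#'
#' @param grid_shape voxel counts `(nx, ny, nz)`.
#' @param spacing physical voxel size per axis, nm; default 10 x 10 x 40 nm
#'   (10 nm lateral pixels, 40 nm sections).
#' @param n_myofibrils,fibril_radius,fibril_length fibril count and cylinder
#'   radius/length in nm. Embryonic myofibril calibre is not a measured
#'   quantity here; the defaults (250 nm radius, 2000 nm length) are free
#'   parameters chosen as plausible for maturing myocardium.
#' @param theta_mean,theta_sd,phi_mean,phi_sd folded-normal angle parameters,
#'   degrees.
#' @param n_nuclei,nucleus_semiaxes nucleus count and ellipsoid semiaxes (nm).
#' @param n_mitochondria,mito_semiaxes mitochondrion count and base ellipsoid
#'   semiaxes (nm); each mitochondrion's semiaxes are jittered by +/-30%.
#' @param ec_fraction_target extracellular volume fraction in `[0, 1)`.
#' @param intensity_means named grayscale means, one per class
#'   (`extracellular`, `nucleus`, `mitochondrion`, `myofibril`, `cytoplasm`),
#'   pairwise distinct.
#' @param noise_sd additive Gaussian noise SD (grayscale units).
#' @param slice_offset_sd SD of per-slice brightness offsets (grayscale
#'   units); exercises cross-sample intensity matching.
#' @param slice_jitter_sd SD of per-slice integer translation jitter
#'   (voxels), applied circularly to the intensity stack only (labels stay
#'   in the specimen frame); exercises alignment.
#' @param seed mandatory RNG seed.
#' @return object of class `em_phantom_params`.
#' @export
em_phantom_params <- function(grid_shape = c(400, 600, 100),
                              spacing = c(10, 10, 40),
                              n_myofibrils = 100,
                              fibril_radius = 250,
                              fibril_length = 2000,
                              theta_mean = 45, theta_sd = 32,
                              phi_mean = 70, phi_sd = 36,
                              n_nuclei = 2,
                              nucleus_semiaxes = c(1500, 800, 800),
                              n_mitochondria = 50,
                              mito_semiaxes = c(400, 300, 300),
                              ec_fraction_target = 0.2,
                              intensity_means = c(extracellular = 200,
                                                  nucleus = 50,
                                                  mitochondrion = 110,
                                                  myofibril = 80,
                                                  cytoplasm = 140),
                              noise_sd = 10,
                              slice_offset_sd = 0,
                              slice_jitter_sd = 0,
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory for phantom generation")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be 3 positive voxel counts (nx, ny, nz)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (!is.numeric(ec_fraction_target) || ec_fraction_target < 0 ||
      ec_fraction_target >= 1)
    stop("`ec_fraction_target` must lie in [0, 1)")
  if (n_myofibrils > 0 && fibril_radius < min(spacing[1:2]))
    stop("`fibril_radius` must be at least one lateral voxel (",
         min(spacing[1:2]), " nm)")
  need <- c("extracellular", "nucleus", "mitochondrion", "myofibril", "cytoplasm")
  if (!all(need %in% names(intensity_means)))
    stop("`intensity_means` must name all of: ", paste(need, collapse = ", "))
  if (anyDuplicated(intensity_means[need]))
    stop("class intensity means must be pairwise distinct")
  stopifnot(n_myofibrils >= 0, n_nuclei >= 0, n_mitochondria >= 0,
            fibril_radius > 0, fibril_length > 0, noise_sd >= 0,
            slice_offset_sd >= 0, slice_jitter_sd >= 0,
            length(nucleus_semiaxes) == 3L, all(nucleus_semiaxes > 0),
            length(mito_semiaxes) == 3L, all(mito_semiaxes > 0))
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 n_myofibrils = as.integer(n_myofibrils),
                 fibril_radius = fibril_radius, fibril_length = fibril_length,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 phi_mean = phi_mean, phi_sd = phi_sd,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_semiaxes = as.numeric(nucleus_semiaxes),
                 n_mitochondria = as.integer(n_mitochondria),
                 mito_semiaxes = as.numeric(mito_semiaxes),
                 ec_fraction_target = ec_fraction_target,
                 intensity_means = intensity_means[need],
                 noise_sd = noise_sd, slice_offset_sd = slice_offset_sd,
                 slice_jitter_sd = slice_jitter_sd,
                 seed = as.integer(seed)),
            class = "em_phantom_params")
}

#' Fold an angle (degrees) into the axial range [0, 180)
#'
#' Axial folding: 175 and -5 denote the same unoriented axis. Guarded
#' against floating-point `%%` returning exactly 180 for tiny negative
#' inputs.
#'
#' @param a numeric vector of angles in degrees.
#' @export
fold180 <- function(a) {
  r <- a %% 180
  r[r >= 180] <- 0
  r
}

#' Unit axis vector from transmural and elliptical angles
#'
#' Inverts the angle definitions: for an axis `(ax, ay, az)` with `ax > 0`,
#' `theta = atan2(ay, ax)` and `phi = atan2(az, ax)`, so the axis is
#' proportional to `(1, tan(theta), tan(phi))`. Angles at exactly 90 degrees
#' give an axis orthogonal to x (handled through the tangent blow-up; the
#' realized folded angles still equal the requested ones).
#'
#' @param theta_deg,phi_deg angles in degrees, folded into `[0, 180)`.
#' @return unit length-3 vector with `x >= 0`.
#' @export
axis_from_angles <- function(theta_deg, phi_deg) {
  tt <- tan(fold180(theta_deg) * pi / 180)
  tp <- tan(fold180(phi_deg) * pi / 180)
  cap <- 1e12
  tt <- max(min(tt, cap), -cap)
  tp <- max(min(tp, cap), -cap)
  v <- c(1, tt, tp)
  v / sqrt(sum(v^2))
}

# 1-based voxel index range covering physical interval [lo, hi] on an axis
# with spacing s and n voxels; integer(0) when the interval misses the grid.
.idx_range <- function(lo, hi, s, n) {
  a <- max(1L, as.integer(floor(lo / s)) + 1L)
  b <- min(n, as.integer(ceiling(hi / s)) + 1L)
  if (a > b) integer(0) else a:b
}

# Voxels of a cylinder in physical coordinates; returns integer index matrix
# plus axial/radial coordinates so callers can take sub-cylinders (core vs
# core + clearance margin) from one rasterization.
.cylinder_voxels <- function(axis, center, radius, half_len, spacing, dims) {
  p0 <- center - axis * half_len
  p1 <- center + axis * half_len
  lo <- pmin(p0, p1) - radius
  hi <- pmax(p0, p1) + radius
  # physical (x, y, z) -> voxel 1-based (j, i, k)
  jr <- .idx_range(lo[1], hi[1], spacing[1], dims[2])
  ir <- .idx_range(lo[2], hi[2], spacing[2], dims[1])
  kr <- .idx_range(lo[3], hi[3], spacing[3], dims[3])
  if (!length(jr) || !length(ir) || !length(kr))
    return(list(ijk = matrix(integer(0), 0, 3,
                             dimnames = list(NULL, c("i", "j", "k"))),
                t = numeric(0), r = numeric(0)))
  g <- expand.grid(i = ir, j = jr, k = kr, KEEP.OUT.ATTRS = FALSE)
  px <- (g$j - 1) * spacing[1] - center[1]
  py <- (g$i - 1) * spacing[2] - center[2]
  pz <- (g$k - 1) * spacing[3] - center[3]
  t <- px * axis[1] + py * axis[2] + pz * axis[3]
  r2 <- px^2 + py^2 + pz^2 - t^2
  keep <- abs(t) <= half_len & r2 <= radius^2
  list(ijk = cbind(i = g$i[keep], j = g$j[keep], k = g$k[keep]),
       t = t[keep], r = sqrt(pmax(r2[keep], 0)))
}

#' Rasterize a cylinder onto an anisotropic voxel grid
#'
#' Returns the voxels whose centres lie strictly within `radius` of the axis
#' segment and whose axial coordinate falls in the half-open interval
#' `[-length/2, length/2)`, all measured in physical coordinates (the
#' anisotropic spacing is respected). The half-open axial interval makes a
#' cylinder of length `n * spacing` along a grid axis span exactly `n`
#' voxels. A cylinder entirely outside the grid yields an empty set.
#'
#' @param axis unit direction vector (any nonzero vector is normalized).
#' @param center physical (x, y, z) of the cylinder centre.
#' @param radius,length cylinder radius and length, physical units.
#' @param geometry a [volume_geometry()].
#' @param dims target array dims `(ny, nx, nz)`.
#' @return integer matrix of 1-based voxel indices, columns (i, j, k).
#' @export
rasterize_cylinder <- function(axis, center, radius, length, geometry, dims) {
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm == 0) stop("`axis` must be a nonzero vector")
  if (radius <= 0 || length <= 0) stop("`radius` and `length` must be positive")
  axis <- axis / nrm
  s <- as.numeric(geometry$spacing)
  cv <- .cylinder_voxels(axis, as.numeric(center), radius, length / 2, s, dims)
  keep <- cv$r < radius & cv$t >= -length / 2 & cv$t < length / 2
  cv$ijk[keep, , drop = FALSE]
}

# Ellipsoid voxels (axis-aligned), 1-based indices.
.ellipsoid_voxels <- function(center, semiaxes, spacing, dims) {
  lo <- center - semiaxes
  hi <- center + semiaxes
  jr <- .idx_range(lo[1], hi[1], spacing[1], dims[2])
  ir <- .idx_range(lo[2], hi[2], spacing[2], dims[1])
  kr <- .idx_range(lo[3], hi[3], spacing[3], dims[3])
  if (!length(jr) || !length(ir) || !length(kr))
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "k"))))
  g <- expand.grid(i = ir, j = jr, k = kr, KEEP.OUT.ATTRS = FALSE)
  q <- (((g$j - 1) * spacing[1] - center[1]) / semiaxes[1])^2 +
       (((g$i - 1) * spacing[2] - center[2]) / semiaxes[2])^2 +
       (((g$k - 1) * spacing[3] - center[3]) / semiaxes[3])^2
  keep <- q <= 1
  cbind(i = g$i[keep], j = g$j[keep], k = g$k[keep])
}

.linind <- function(ijk, dims) {
  (ijk[, 3] - 1) * (dims[1] * dims[2]) + (ijk[, 2] - 1) * dims[1] + ijk[, 1]
}

# integer 2D content shift with constant fill
.shift2d <- function(m, dy, dx, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_i <- seq_len(nr) - dy; src_j <- seq_len(nc) - dx
  oi <- which(src_i >= 1 & src_i <= nr); oj <- which(src_j >= 1 & src_j <= nc)
  if (length(oi) && length(oj)) out[oi, oj] <- m[src_i[oi], src_j[oj]]
  out
}

# integer 2D circular (torus) content shift; exactly invertible, so shifted
# phantom slices carry no border artefacts that would bias correlation
.cshift2d <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

#' Generate a synthetic EM phantom volume with ground truth
#'
#' Places nuclei, then myofibril cylinders, then mitochondria (largest
#' objects first) by bounded rejection
#' sampling (default 100 retries per object; later objects never overwrite
#' earlier ones and keep a clearance of one maximal voxel spacing so that
#' distinct fibrils never touch under 26-connectivity), carves an
#' extracellular phase of the requested volume fraction out of the remaining
#' cytoplasm using a thresholded blocky random field, and renders grayscale
#' intensities as per-class means plus Gaussian noise, optional per-slice
#' brightness offsets, and optional per-slice translation jitter (intensity
#' stack only; labels stay in the specimen frame).
#'
#' Identical parameters and seed give bit-identical output; the caller's RNG
#' state is left untouched.
#'
#' @param params an [em_phantom_params()].
#' @param max_retries placement retries per object before failing.
#' @return list of class `em_phantom` with elements `intensity`
#'   ([voxel_volume()]), `labels` ([label_volume()]), `angles` (data.frame
#'   `fibril_id, theta_true_deg, phi_true_deg, n_voxels` of true per-fibril
#'   angles), `jitter` (data.frame `slice, dx, dy` of applied displacements)
#'   and `ec_fraction_realized`.
#' @export
generate_em_volume <- function(params, max_retries = 100L) {
  stopifnot(inherits(params, "em_phantom_params"))
  with_seed(params$seed, .generate_em_volume(params, max_retries))
}

.generate_em_volume <- function(p, max_retries) {
  dims <- c(p$grid_shape[2], p$grid_shape[1], p$grid_shape[3])  # (ny, nx, nz)
  sp <- p$spacing
  extent <- (p$grid_shape - 1) * sp  # physical extent along (x, y, z)
  geom <- volume_geometry(spacing = sp, unit = "nm")
  cm <- em_class_map()
  labels <- array(cm[["cytoplasm"]], dim = dims)
  fib_id <- array(0L, dim = dims)
  margin <- max(sp)

  if (p$n_myofibrils > 0 &&
      p$fibril_length + 2 * p$fibril_radius > sqrt(sum(extent^2)))
    stop("infeasible packing: grid too small to hold a myofibril")

  sample_center <- function(inset) {
    lo <- inset
    hi <- extent - inset
    if (any(hi <= lo)) return(NULL)
    c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]),
      stats::runif(1, lo[3], hi[3]))
  }

  place_ellipsoids <- function(labels, n, semiaxes_fun, class_value, what) {
    for (e in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        sa <- semiaxes_fun()
        ctr <- sample_center(sa + margin)
        if (is.null(ctr)) next
        vox <- .ellipsoid_voxels(ctr, sa + margin, sp, dims)
        if (nrow(vox) == 0L) next
        lin <- .linind(vox, dims)
        if (any(labels[lin] != cm[["cytoplasm"]])) next
        core <- .ellipsoid_voxels(ctr, sa, sp, dims)
        if (nrow(core) == 0L) next
        labels[.linind(core, dims)] <- class_value
        placed <- TRUE
        break
      }
      if (!placed)
        stop("infeasible packing: could not place ", what, " ", e,
             " after ", max_retries, " retries")
    }
    labels
  }

  # largest objects first: nuclei, then fibrils, then mitochondria
  labels <- place_ellipsoids(labels, p$n_nuclei, function() p$nucleus_semiaxes,
                             cm[["nucleus"]], "nucleus")

  ang <- data.frame(fibril_id = integer(0), theta_true_deg = numeric(0),
                    phi_true_deg = numeric(0), n_voxels = integer(0))
  half_len <- p$fibril_length / 2
  for (f in seq_len(p$n_myofibrils)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      th <- fold180(stats::rnorm(1, p$theta_mean, p$theta_sd))
      ph <- fold180(stats::rnorm(1, p$phi_mean, p$phi_sd))
      a <- axis_from_angles(th, ph)
      inset <- abs(a) * (half_len + margin) + p$fibril_radius + margin
      ctr <- sample_center(inset)
      if (is.null(ctr)) next
      cv <- .cylinder_voxels(a, ctr, p$fibril_radius + margin,
                             half_len + margin, sp, dims)
      if (nrow(cv$ijk) == 0L) next
      lin <- .linind(cv$ijk, dims)
      if (any(labels[lin] != cm[["cytoplasm"]])) next
      core <- cv$r < p$fibril_radius & cv$t >= -half_len & cv$t < half_len
      lin_core <- lin[core]
      if (length(lin_core) < 2L) next
      labels[lin_core] <- cm[["myofibril"]]
      fib_id[lin_core] <- f
      ang <- rbind(ang, data.frame(
        fibril_id = f,
        theta_true_deg = fold180(atan2(a[2], a[1]) * 180 / pi),
        phi_true_deg = fold180(atan2(a[3], a[1]) * 180 / pi),
        n_voxels = length(lin_core)))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible packing: could not place myofibril ", f,
           " after ", max_retries, " retries")
  }

  labels <- place_ellipsoids(labels, p$n_mitochondria,
                             function() p$mito_semiaxes * stats::runif(3, 0.7, 1.3),
                             cm[["mitochondrion"]], "mitochondrion")

  # extracellular phase: threshold a blocky random field over the remaining
  # cytoplasm so the realized fraction matches the target voxel-exactly
  total <- prod(dims)
  n_ec <- round(p$ec_fraction_target * total)
  if (n_ec > 0) {
    rem <- which(labels == cm[["cytoplasm"]])
    if (length(rem) < n_ec)
      stop("infeasible packing: extracellular target unreachable, only ",
           length(rem), " unoccupied voxels for ", n_ec, " needed")
    # smooth random field: coarse Gaussian grid (cells ~80 nm laterally,
    # ~320 nm axially at default spacing) upsampled trilinearly, so the
    # extracellular phase forms smooth blobs that stay correlated between
    # adjacent sections
    fl <- c(8L, 8L, 8L)
    cd <- pmax(2L, ceiling(dims / fl) + 1L)
    cf <- array(stats::rnorm(prod(cd)), dim = cd)
    k <- (rem - 1L) %/% (dims[1] * dims[2])
    r2 <- (rem - 1L) %% (dims[1] * dims[2])
    j <- r2 %/% dims[1]
    i <- r2 %% dims[1]
    gather <- function(u, v, w) cf[cbind(u, v, w)]
    u <- pmin(i / fl[1], cd[1] - 1 - 1e-9); u0 <- floor(u); fu <- u - u0
    v <- pmin(j / fl[2], cd[2] - 1 - 1e-9); v0 <- floor(v); fv <- v - v0
    w <- pmin(k / fl[3], cd[3] - 1 - 1e-9); w0 <- floor(w); fw <- w - w0
    u0 <- u0 + 1L; v0 <- v0 + 1L; w0 <- w0 + 1L
    vals <-
      gather(u0,     v0,     w0)     * (1 - fu) * (1 - fv) * (1 - fw) +
      gather(u0 + 1L, v0,     w0)     * fu       * (1 - fv) * (1 - fw) +
      gather(u0,     v0 + 1L, w0)     * (1 - fu) * fv       * (1 - fw) +
      gather(u0 + 1L, v0 + 1L, w0)    * fu       * fv       * (1 - fw) +
      gather(u0,     v0,     w0 + 1L) * (1 - fu) * (1 - fv) * fw +
      gather(u0 + 1L, v0,     w0 + 1L) * fu      * (1 - fv) * fw +
      gather(u0,     v0 + 1L, w0 + 1L) * (1 - fu) * fv      * fw +
      gather(u0 + 1L, v0 + 1L, w0 + 1L) * fu     * fv       * fw +
      stats::rnorm(length(rem)) * 1e-6
    thr <- sort(vals, partial = n_ec)[n_ec]
    sel <- which(vals <= thr)[seq_len(n_ec)]
    labels[rem[sel]] <- cm[["extracellular"]]
  }

  lut <- numeric(max(cm) + 1)
  lut[cm[["extracellular"]] + 1] <- p$intensity_means[["extracellular"]]
  lut[cm[["nucleus"]] + 1] <- p$intensity_means[["nucleus"]]
  lut[cm[["mitochondrion"]] + 1] <- p$intensity_means[["mitochondrion"]]
  lut[cm[["myofibril"]] + 1] <- p$intensity_means[["myofibril"]]
  lut[cm[["cytoplasm"]] + 1] <- p$intensity_means[["cytoplasm"]]
  intens <- array(lut[labels + 1L], dim = dims)
  if (p$noise_sd > 0) intens <- intens + stats::rnorm(total, 0, p$noise_sd)
  nz <- dims[3]
  if (p$slice_offset_sd > 0) {
    off <- stats::rnorm(nz, 0, p$slice_offset_sd)
    intens <- intens + rep(off, each = dims[1] * dims[2])
  }

  jit <- data.frame(slice = seq_len(nz), dx = 0L, dy = 0L)
  if (p$slice_jitter_sd > 0) {
    jit$dx <- as.integer(round(stats::rnorm(nz, 0, p$slice_jitter_sd)))
    jit$dy <- as.integer(round(stats::rnorm(nz, 0, p$slice_jitter_sd)))
    jit$dx[1] <- 0L; jit$dy[1] <- 0L
    for (k in which(jit$dx != 0L | jit$dy != 0L)) {
      intens[, , k] <- .cshift2d(intens[, , k], jit$dy[k], jit$dx[k])
    }
  }

  out <- list(
    intensity = voxel_volume(intens, geom),
    labels = label_volume(labels, geom, em_class_map()),
    angles = ang,
    jitter = jit,
    ec_fraction_realized = n_ec / total,
    fibril_ids = fib_id)
  class(out) <- "em_phantom"
  out
}

#' @export
print.em_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<em_phantom> %d x %d x %d voxels; %d fibrils; EC fraction %.3f\n",
              d[1], d[2], d[3], nrow(x$angles), x$ec_fraction_realized))
  invisible(x)
}

# ---- whole-heart label phantom ----------------------------------------------

#' Parameters for a two-chamber heart label phantom
#'
#' A micro-CT-scale stand-in: two ellipsoidal ventricular lumens (LV, RV)
#' wrapped in a tissue shell of constant thickness, side by side along x with
#' the septum between them. A deliberate simplification of ventricular shape
#' (the RV is crescent-shaped in reality) so analytic lumen volumes
#' `4/3*pi*abc` exist for validation.
#'
#' @param lv_semiaxes,rv_semiaxes lumen ellipsoid semiaxes `(a, b, c)`, µm.
#' @param wall_thickness tissue shell / septum half-separation, µm (> 0).
#' @param spacing voxel size, µm.
#' @param grid_shape voxel counts `(nx, ny, nz)`; `NULL` auto-sizes the grid
#'   to fit both shells plus a 2-voxel border.
#' @param seed RNG seed (accepted for interface uniformity; rasterization is
#'   deterministic).
#' @return object of class `heart_phantom_params`.
#' @export
heart_phantom_params <- function(lv_semiaxes = c(800, 600, 1100),
                                 rv_semiaxes = lv_semiaxes * 0.6^(1 / 3),
                                 wall_thickness = 250,
                                 spacing = c(20, 20, 20),
                                 grid_shape = NULL,
                                 seed = 1L) {
  if (!is.numeric(wall_thickness) || wall_thickness <= 0)
    stop("`wall_thickness` must be > 0")
  stopifnot(length(lv_semiaxes) == 3L, all(lv_semiaxes > 0),
            length(rv_semiaxes) == 3L, all(rv_semiaxes > 0),
            length(spacing) == 3L, all(spacing > 0))
  if (is.null(grid_shape)) {
    pad <- 2 * spacing
    w <- wall_thickness
    ext_x <- 2 * (lv_semiaxes[1] + w) + 2 * (rv_semiaxes[1] + w) + 2 * pad[1]
    ext_y <- 2 * (max(lv_semiaxes[2], rv_semiaxes[2]) + w) + 2 * pad[2]
    ext_z <- 2 * (max(lv_semiaxes[3], rv_semiaxes[3]) + w) + 2 * pad[3]
    grid_shape <- ceiling(c(ext_x, ext_y, ext_z) / spacing) + 1
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 lv_semiaxes = as.numeric(lv_semiaxes),
                 rv_semiaxes = as.numeric(rv_semiaxes),
                 wall_thickness = wall_thickness, seed = as.integer(seed)),
            class = "heart_phantom_params")
}

#' Heart phantom parameters for a target RV/LV lumen volume ratio
#'
#' Scales the RV semiaxes isotropically so the analytic lumen volume ratio
#' equals `ratio` exactly.
#'
#' @param ratio target RV volume / LV volume.
#' @param ... passed to [heart_phantom_params()].
#' @export
heart_phantom_for_ratio <- function(ratio, ...) {
  stopifnot(is.numeric(ratio), ratio > 0)
  base <- heart_phantom_params(...)
  heart_phantom_params(lv_semiaxes = base$lv_semiaxes,
                       rv_semiaxes = base$lv_semiaxes * ratio^(1 / 3),
                       wall_thickness = base$wall_thickness,
                       spacing = base$spacing, seed = base$seed)
}

#' Generate a two-chamber heart label phantom
#'
#' @param params a [heart_phantom_params()].
#' @return a [label_volume()] with classes background / tissue / lv_lumen /
#'   rv_lumen (see [heart_class_map()]); attribute `analytic_volumes` holds
#'   the exact ellipsoid lumen volumes.
#' @export
generate_heart_phantom <- function(params) {
  stopifnot(inherits(params, "heart_phantom_params"))
  p <- params
  dims <- c(p$grid_shape[2], p$grid_shape[1], p$grid_shape[3])
  sp <- p$spacing
  extent <- (p$grid_shape - 1) * sp
  w <- p$wall_thickness
  cyz <- extent[2:3] / 2
  cx_l <- sp[1] * 2 + p$lv_semiaxes[1] + w
  cx_r <- cx_l + p$lv_semiaxes[1] + 2 * w + p$rv_semiaxes[1]
  if (cx_r + p$rv_semiaxes[1] + w > extent[1] ||
      any(c(p$lv_semiaxes[2:3], p$rv_semiaxes[2:3]) + w > cyz))
    stop("grid too small for the requested lumens and wall")
  c_lv <- c(cx_l, cyz)
  c_rv <- c(cx_r, cyz)
  cm <- heart_class_map()
  labels <- array(cm[["background"]], dim = dims)
  X <- matrix((seq_len(dims[2]) - 1) * sp[1], dims[1], dims[2], byrow = TRUE)
  Y <- matrix((seq_len(dims[1]) - 1) * sp[2], dims[1], dims[2])
  ell <- function(cc, sa, zk) {
    ((X - cc[1]) / sa[1])^2 + ((Y - cc[2]) / sa[2])^2 + ((zk - cc[3]) / sa[3])^2
  }
  overlap <- FALSE
  for (k in seq_len(dims[3])) {
    zk <- (k - 1) * sp[3]
    q_lv <- ell(c_lv, p$lv_semiaxes, zk)
    q_rv <- ell(c_rv, p$rv_semiaxes, zk)
    q_lvo <- ell(c_lv, p$lv_semiaxes + w, zk)
    q_rvo <- ell(c_rv, p$rv_semiaxes + w, zk)
    sl <- matrix(cm[["background"]], dims[1], dims[2])
    sl[q_lvo <= 1 | q_rvo <= 1] <- cm[["tissue"]]
    in_lv <- q_lv <= 1
    in_rv <- q_rv <= 1
    if (any(in_lv & in_rv)) overlap <- TRUE
    sl[in_lv] <- cm[["lv_lumen"]]
    sl[in_rv] <- cm[["rv_lumen"]]
    labels[, , k] <- sl
  }
  if (overlap) stop("overlapping lumens: LV and RV ellipsoids intersect")
  lv <- label_volume(labels, volume_geometry(spacing = sp, unit = "um"),
                     heart_class_map())
  attr(lv, "analytic_volumes") <- c(
    lv = 4 / 3 * pi * prod(p$lv_semiaxes),
    rv = 4 / 3 * pi * prod(p$rv_semiaxes))
  lv
}
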