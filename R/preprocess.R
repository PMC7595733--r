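# Stack registration, per-slice denoising, and cross-sample intensity
# matching: the three post-acquisition steps applied to SBF-SEM stacks
# before segmentation.

# 2D circular cross-correlation via FFT; returns the translation (dy, dx)
# of `cur` relative to `prev` (content of cur appears at prev + (dy, dx)),
# with optional parabolic subvoxel refinement, plus the correlation score.
.slice_shift <- function(prev, cur, subpixel = TRUE) {
  sp <- stats::sd(prev); sc <- stats::sd(cur)
  if (!is.finite(sp) || !is.finite(sc) || sp == 0 || sc == 0)
    return(list(dy = 0, dx = 0, score = NA_real_))
  a <- prev - mean(prev); b <- cur - mean(cur)
  fa <- stats::fft(a); fb <- stats::fft(b)
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE))
  pk <- which.max(cc)
  nr <- nrow(a); nc <- ncol(a)
  pi0 <- (pk - 1) %% nr
  pj0 <- (pk - 1) %/% nr
  dy <- if (pi0 > nr / 2) pi0 - nr else pi0
  dx <- if (pj0 > nc / 2) pj0 - nc else pj0
  # fft(inverse = TRUE) is unnormalized (factor N); rescale to a correlation
  score <- cc[pk] / (length(a) * sp * sc * (length(a) - 1))
  dy_s <- dy; dx_s <- dx
  if (subpixel) {
    wrap <- function(v, n) ((v %% n) + n) %% n + 1
    para <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (den >= 0) 0 else 0.5 * (cm - cp) / den
    }
    c0 <- cc[pk]
    cym <- cc[wrap(pi0 - 1, nr) + nr * pj0]
    cyp <- cc[wrap(pi0 + 1, nr) + nr * pj0]
    cxm <- cc[pi0 + 1 + nr * (wrap(pj0 - 1, nc) - 1)]
    cxp <- cc[pi0 + 1 + nr * (wrap(pj0 + 1, nc) - 1)]
    dy_s <- dy + para(cym, c0, cyp)
    dx_s <- dx + para(cxm, c0, cxp)
  }
  list(dy = dy_s, dx = dx_s, score = score)
}

#' Align a stack by chained translation registration
#'
#' Each slice is registered to its predecessor by normalized
#' cross-correlation (translation only; SBF-SEM slices differ by stage
#' drift, not rotation), shifts are chained into the frame of the first
#' slice, and the rounded integer corrections are applied. Subvoxel peak
#' positions (parabolic interpolation of the correlation surface) are
#' reported in the shift table; applying the rounded table shifts to the raw
#' stack with [apply_shifts()] reproduces the aligned stack.
#'
#' An all-constant slice has no defined correlation; it gets shift (0, 0)
#' and an `NA` score.
#'
#' @param volume a [voxel_volume()] with at least 2 slices.
#' @param subpixel refine the correlation peak by parabolic interpolation?
#' @param fill value for voxels shifted in from outside; default per-slice
#'   median.
#' @return list with `volume` (aligned) and `shifts` (data.frame
#'   `slice, dx, dy, score`; dx/dy are the corrections applied, reference
#'   slice is (0, 0)).
#' @export
align_stack <- function(volume, subpixel = TRUE, fill = NULL) {
  d <- dim(volume)
  if (length(d) != 3L || d[3] < 2L) stop("need a stack with >= 2 slices")
  nz <- d[3]
  rel <- matrix(0, nz, 2)
  score <- rep(NA_real_, nz)
  for (k in 2:nz) {
    s <- .slice_shift(volume[, , k - 1], volume[, , k], subpixel = subpixel)
    rel[k, ] <- c(s$dy, s$dx)
    score[k] <- s$score
  }
  cum <- apply(rel, 2, cumsum)
  shifts <- data.frame(slice = seq_len(nz),
                       dx = -cum[, 2], dy = -cum[, 1], score = score)
  aligned <- apply_shifts(volume, shifts, fill = fill)
  list(volume = aligned, shifts = shifts)
}

#' Apply a per-slice shift table to a stack
#'
#' @param volume a [voxel_volume()] (or 3D array).
#' @param shifts data.frame with `slice, dx, dy` (voxels; rounded to integer
#'   before application).
#' @param fill fill value for exposed borders; default per-slice median.
#' @return shifted volume of the same class.
#' @export
apply_shifts <- function(volume, shifts, fill = NULL) {
  d <- dim(volume)
  if (nrow(shifts) != d[3]) stop("one shift row per slice required")
  out <- volume
  for (r in seq_len(nrow(shifts))) {
    k <- shifts$slice[r]
    dy <- as.integer(round(shifts$dy[r])); dx <- as.integer(round(shifts$dx[r]))
    if (dy == 0L && dx == 0L) next
    f <- if (is.null(fill)) stats::median(volume[, , k]) else fill
    out[, , k] <- .shift2d(volume[, , k], dy, dx, fill = f)
  }
  out
}

#' Non-local means denoising, slice by slice
#'
#' The classic non-local means filter applied independently to every 2D
#' slice (no cross-slice mixing), improving the signal-to-noise ratio while
#' preserving edges. `strength` is the filtering parameter `h` in grayscale
#' units; 0 is the identity.
#'
#' @param volume a [voxel_volume()].
#' @param patch_radius patch half-width in pixels (patch is
#'   `(2r+1) x (2r+1)`).
#' @param search_radius search window half-width in pixels.
#' @param strength filter strength `h` (grayscale units, >= 0).
#' @return denoised volume; shape and geometry unchanged.
#' @export
denoise_slices <- function(volume, patch_radius = 1L, search_radius = 5L,
                           strength = 10) {
  if (strength < 0) stop("`strength` must be >= 0")
  d <- dim(volume)
  if (2 * patch_radius + 1 > min(d[1], d[2]) ||
      2 * search_radius + 1 > min(d[1], d[2]))
    stop("patch or search window larger than slice")
  if (strength == 0) return(volume)
  out <- volume
  for (k in seq_len(d[3]))
    out[, , k] <- .nlm_slice(volume[, , k, drop = TRUE],
                             as.integer(patch_radius),
                             as.integer(search_radius), strength)
  out
}

#' Match a volume's intensity distribution to a reference
#'
#' Global affine grayscale map `a*I + b` chosen so the output mean and SD
#' equal the reference mean and SD; used to match sections from one sample
#' to another acquired at different brightness. Invertible and logged via
#' the returned coefficients.
#'
#' @param volume a [voxel_volume()] (label volumes are rejected: class codes
#'   are not intensities).
#' @param reference a nonempty [voxel_volume()] or numeric array.
#' @return the matched volume, with attribute `intensity_map = c(a, b)`.
#' @export
match_intensity <- function(volume, reference) {
  if (inherits(volume, "label_volume") || inherits(reference, "label_volume"))
    stop("label volumes carry class codes, not intensities; refusing to match")
  if (length(reference) == 0) stop("`reference` must be nonempty")
  m_in <- mean(volume); s_in <- stats::sd(volume)
  m_ref <- mean(reference); s_ref <- stats::sd(reference)
  if (s_in == 0 && s_ref > 0)
    stop("zero-variance input cannot be matched to a varying reference")
  a <- if (s_in == 0) 1 else s_ref / s_in
  b <- m_ref - a * m_in
  out <- volume * a + b
  attr(out, "geometry") <- attr(volume, "geometry")
  class(out) <- class(volume)
  attr(out, "intensity_map") <- c(a = a, b = b)
  out
}
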