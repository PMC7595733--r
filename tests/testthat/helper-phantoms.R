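# Shared phantom configurations, built in code at test time.

# Small, fast EM phantom for unit tests.
tiny_em_params <- function(..., seed = 1) {
  defaults <- list(grid_shape = c(96, 96, 48), n_myofibrils = 10,
                   fibril_radius = 40, fibril_length = 600,
                   theta_mean = 45, theta_sd = 20, phi_mean = 30, phi_sd = 20,
                   n_nuclei = 0, nucleus_semiaxes = c(250, 200, 200),
                   n_mitochondria = 5, mito_semiaxes = c(150, 120, 120),
                   ec_fraction_target = 0.25, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(em_phantom_params, args)
}

# Desk-scale recovery phantom: 200 fibrils with the angle distribution of a
# given heart condition (normal-like 45/32, 70/36; TOF-like 7/20, 15/15).
recovery_em_params <- function(theta_mean, theta_sd, phi_mean, phi_sd, seed) {
  em_phantom_params(grid_shape = c(320, 320, 80), n_myofibrils = 200,
                    fibril_radius = 40, fibril_length = 800,
                    theta_mean = theta_mean, theta_sd = theta_sd,
                    phi_mean = phi_mean, phi_sd = phi_sd,
                    n_nuclei = 1, nucleus_semiaxes = c(600, 400, 400),
                    n_mitochondria = 30, mito_semiaxes = c(150, 120, 120),
                    ec_fraction_target = 0.15, seed = seed)
}

# A two-level intensity phantom (bright extracellular vs dark tissue) with
# its ground-truth EC mask.
two_level_volume <- function(dims = c(32, 32, 8), ec_level = 200,
                             tissue_level = 80, noise_sd = 0, seed = 1,
                             ec_fraction = 0.3) {
  set.seed(seed)
  n <- prod(dims)
  truth <- array(FALSE, dims)
  truth[seq_len(round(ec_fraction * n))] <- TRUE
  vol <- array(tissue_level, dims)
  vol[truth] <- ec_level
  if (noise_sd > 0) vol <- vol + rnorm(n, 0, noise_sd)
  list(volume = voxel_volume(vol), truth = truth)
}

# angular distance between two folded axial angles (degrees)
axial_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# angle in degrees between two unit axes (sign-insensitive)
axis_angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)))) * 180 / pi
}
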