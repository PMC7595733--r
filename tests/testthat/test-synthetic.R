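test_that("phantom parameters are validated", {
  expect_error(tiny_em_params(ec_fraction_target = 1), "\\[0, 1\\)")
  expect_error(tiny_em_params(spacing = c(10, -1, 40)), "positive")
  expect_error(tiny_em_params(fibril_radius = 2), "lateral voxel")
  expect_error(tiny_em_params(intensity_means = c(extracellular = 100,
                                                  nucleus = 100,
                                                  mitochondrion = 110,
                                                  myofibril = 80,
                                                  cytoplasm = 140)),
               "distinct")
  expect_error(em_phantom_params(), "seed")
})

test_that("empty phantom contains only extracellular and cytoplasm", {
  ph <- generate_em_volume(tiny_em_params(n_myofibrils = 0, n_nuclei = 0,
                                          n_mitochondria = 0, seed = 5))
  cnt <- label_counts(ph$labels)
  expect_equal(unname(cnt[["myofibril"]]), 0L)
  expect_equal(unname(cnt[["nucleus"]]), 0L)
  expect_equal(unname(cnt[["mitochondrion"]]), 0L)
  expect_equal(sum(cnt[c("extracellular", "cytoplasm")]), length(ph$labels))
  expect_equal(nrow(ph$angles), 0L)
})

test_that("identical parameters and seed give bit-identical phantoms", {
  p <- tiny_em_params(seed = 99, slice_offset_sd = 2, slice_jitter_sd = 1)
  a <- generate_em_volume(p)
  b <- generate_em_volume(p)
  expect_identical(unclass(a$labels), unclass(b$labels))
  expect_identical(unclass(a$intensity), unclass(b$intensity))
  expect_identical(a$angles, b$angles)
  # and a different seed changes the output
  c <- generate_em_volume(tiny_em_params(seed = 100))
  expect_false(identical(unclass(a$labels), unclass(c$labels)))
})

test_that("phantom generation leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_em_volume(tiny_em_params(seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("class voxel counts always sum to the grid size", {
  for (s in c(2, 3)) {
    ph <- generate_em_volume(tiny_em_params(n_nuclei = 1, seed = s))
    expect_equal(sum(label_counts(ph$labels)), length(ph$labels))
  }
})

test_that("realized extracellular fraction matches the target", {
  for (tgt in c(0.1, 0.3)) {
    ph <- generate_em_volume(tiny_em_params(ec_fraction_target = tgt, seed = 4))
    cnt <- label_counts(ph$labels)
    expect_lt(abs(cnt[["extracellular"]] / length(ph$labels) - tgt), 0.05)
  }
})

test_that("zero-spread angle distributions yield fibrils on the requested axis", {
  p <- tiny_em_params(grid_shape = c(160, 160, 60), n_myofibrils = 50,
                      theta_mean = 45, theta_sd = 0, phi_mean = 0, phi_sd = 0,
                      n_mitochondria = 0, ec_fraction_target = 0.1, seed = 21)
  ph <- generate_em_volume(p)
  expect_equal(nrow(ph$angles), 50L)
  expect_true(all(abs(ph$angles$theta_true_deg - 45) < 1e-9))
  tab <- compute_angle_table(ph$labels, min_object_voxels = 50)
  expect_equal(nrow(tab), 50L)
  expect_true(all(axial_dist(tab$theta_deg, 45) < 2))
})

test_that("infeasible packing fails naming the object class", {
  p <- tiny_em_params(grid_shape = c(24, 24, 8), n_myofibrils = 3,
                      fibril_radius = 100, fibril_length = 5000, seed = 1)
  expect_error(generate_em_volume(p), "infeasible packing")
  p2 <- tiny_em_params(n_nuclei = 2, nucleus_semiaxes = c(460, 460, 900),
                       seed = 1)
  expect_error(generate_em_volume(p2), "infeasible packing.*nucleus")
})

test_that("per-slice jitter displaces intensity slices and is recorded", {
  p <- tiny_em_params(slice_jitter_sd = 1.5, seed = 31)
  ph <- generate_em_volume(p)
  expect_equal(nrow(ph$jitter), dim(ph$intensity)[3])
  expect_equal(ph$jitter$dx[1], 0L)
  expect_true(any(ph$jitter$dx != 0L | ph$jitter$dy != 0L))
})

test_that("cylinder rasterization respects anisotropic physical geometry", {
  g <- volume_geometry(spacing = c(10, 10, 40))
  dims <- c(40, 40, 12)
  # radius one lateral spacing along x: a one-voxel-thick row
  vox <- rasterize_cylinder(c(1, 0, 0), c(200, 200, 200), 10, 300, g, dims)
  expect_gt(nrow(vox), 0)
  expect_equal(length(unique(vox[, "i"])), 1L)
  expect_equal(length(unique(vox[, "k"])), 1L)
  expect_equal(nrow(vox), 30L)  # 300 nm / 10 nm
  # along z: 400 nm length over 40 nm sections spans 10 slices
  voz <- rasterize_cylinder(c(0, 0, 1), c(200, 200, 200), 15, 400, g, dims)
  expect_equal(length(unique(voz[, "k"])), 10L)
  # oblique in-plane axis: voxel set symmetric under swapping x and y
  vod <- rasterize_cylinder(c(1, 1, 0) / sqrt(2), c(200, 200, 200), 25, 200,
                            g, dims)
  swapped <- vod[, c("j", "i", "k"), drop = FALSE]
  colnames(swapped) <- c("i", "j", "k")
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_equal(key(vod), key(swapped))
  # entirely outside the grid: empty set, not an error
  out <- rasterize_cylinder(c(1, 0, 0), c(-5000, -5000, -5000), 20, 100, g, dims)
  expect_equal(nrow(out), 0L)
  expect_error(rasterize_cylinder(c(0, 0, 0), c(0, 0, 0), 10, 10, g, dims),
               "nonzero")
})

test_that("heart phantom reproduces analytic lumen volumes and ratios", {
  hp13 <- generate_heart_phantom(heart_phantom_for_ratio(1.3))
  vr <- ventricle_volume_ratio(hp13)
  expect_gt(vr$rv_over_lv, 1.26)
  expect_lt(vr$rv_over_lv, 1.34)
  av <- attr(hp13, "analytic_volumes")
  expect_lt(abs(vr$lv_volume - av[["lv"]]) / av[["lv"]], 0.03)
  expect_lt(abs(vr$rv_volume - av[["rv"]]) / av[["rv"]], 0.03)
  # identical lumens: ratio 1 up to rasterization
  hp1 <- generate_heart_phantom(heart_phantom_for_ratio(1))
  expect_lt(abs(ventricle_volume_ratio(hp1)$rv_over_lv - 1), 0.02)
})

test_that("degenerate heart phantom parameters are rejected", {
  expect_error(heart_phantom_params(wall_thickness = 0), "wall_thickness")
  p <- heart_phantom_params(grid_shape = c(50, 50, 50))
  expect_error(generate_heart_phantom(p), "too small")
})
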