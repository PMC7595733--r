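test_that("connected-component splitting honours connectivity semantics", {
  m <- array(FALSE, c(10, 10, 4))
  m[2:4, 2, 2] <- TRUE
  m[7:9, 8, 3] <- TRUE
  objs <- split_objects(m, min_object_voxels = 1)
  expect_length(objs, 2)
  # corner-touching voxels: one object under 26-connectivity, two under 6
  t2 <- array(FALSE, c(4, 4, 2))
  t2[1, 1, 1] <- TRUE; t2[2, 2, 2] <- TRUE
  expect_length(split_objects(t2, connectivity = 26, min_object_voxels = 1), 1)
  expect_length(split_objects(t2, connectivity = 6, min_object_voxels = 1), 2)
  # below-minimum objects are discarded and counted
  one <- array(FALSE, c(4, 4, 2)); one[1, 1, 1] <- TRUE
  objs0 <- split_objects(one, min_object_voxels = 10)
  expect_length(objs0, 0)
  expect_equal(attr(objs0, "n_discarded"), 1L)
  expect_length(split_objects(array(FALSE, c(3, 3, 3)), min_object_voxels = 1), 0)
})

test_that("principal axis recovers canonical directions in physical space", {
  g <- volume_geometry(spacing = c(10, 10, 40))
  row_x <- cbind(i = rep(3L, 10), j = 1:10, k = rep(2L, 10))
  expect_equal(unname(object_orientation(row_x, g)), c(1, 0, 0))
  col_y <- cbind(i = 1:10, j = rep(3L, 10), k = rep(2L, 10))
  expect_equal(unname(object_orientation(col_y, g)), c(0, 1, 0))
  # a symmetric cube has no preferred axis: flagged indeterminate
  cube <- as.matrix(expand.grid(i = 1:4, j = 1:4, k = 1:4))
  colnames(cube) <- c("i", "j", "k")
  g_iso <- volume_geometry(spacing = c(10, 10, 10))
  expect_true(all(is.na(object_orientation(cube, g_iso))))
  expect_error(object_orientation(cbind(i = 1L, j = 1L, k = 1L), g), ">= 2")
})

test_that("principal axis of a rasterized cylinder matches the generating axis", {
  g <- volume_geometry()
  a <- axis_from_angles(30, 0)
  vox <- rasterize_cylinder(a, c(600, 600, 400), 30, 1000, g, c(120, 120, 20))
  est <- object_orientation(vox, g)
  expect_lt(axis_angle_deg(est, a), 2)
  expect_lt(axial_dist(transmural_angle(est), 30), 2)
})

test_that("transmural and elliptical angles follow the plane conventions", {
  expect_equal(transmural_angle(c(1, 0, 0)), 0)
  expect_equal(transmural_angle(c(0, 1, 0)), 90)
  expect_equal(transmural_angle(c(1, 1, 0) / sqrt(2)), 45)
  expect_equal(transmural_angle(c(-1, 1, 0) / sqrt(2)), 135)
  expect_true(is.na(transmural_angle(c(0, 0, 1))))  # parallel to z
  expect_equal(elliptical_angle(c(1, 0, 0)), 0)
  expect_equal(elliptical_angle(c(0, 0, 1)), 90)
  expect_equal(elliptical_angle(c(1, 0, 1) / sqrt(2)), 45)
  expect_true(is.na(elliptical_angle(c(0, 1, 0))))  # parallel to y
})

test_that("the 18-bin histogram covers 0-180 with folding", {
  h <- angle_histogram(c(0, 5, 15, 175))
  expect_length(h, 18)
  expect_equal(unname(h[1]), 2L)
  expect_equal(unname(h[2]), 1L)
  expect_equal(unname(h[18]), 1L)
  expect_equal(sum(h), 4L)
  expect_equal(sum(angle_histogram(numeric(0))), 0L)
  # 180 folds to 0 and lands in the first bin
  expect_equal(unname(angle_histogram(180)[1]), 1L)
  expect_equal(unname(angle_histogram(185)[1]), 1L)
  expect_error(angle_histogram(c(10, 400)), "\\[0, 360\\)")
})

test_that("angle summaries: linear vs circular-axial statistics", {
  s45 <- angle_summary(rep(45, 10), mode = "linear")
  expect_equal(s45$mean_deg, 45); expect_equal(s45$sd_deg, 0)
  c45 <- angle_summary(rep(45, 10), mode = "circular-axial")
  expect_equal(c45$mean_deg, 45, tolerance = 1e-9)
  expect_equal(c45$sd_deg, 0, tolerance = 1e-6)
  lin <- angle_summary(c(10, 20), mode = "linear")
  expect_equal(lin$mean_deg, 15)
  expect_equal(lin$sd_deg, sd(c(10, 20)))
  # a sample straddling the wrap: axial mean 0, linear mean 90
  wrap <- c(5, 175)
  expect_equal(angle_summary(wrap, mode = "linear")$mean_deg, 90)
  cw <- angle_summary(wrap, mode = "circular-axial")
  expect_lt(axial_dist(cw$mean_deg, 0), 1e-9)
  expect_equal(sum(angle_summary(c(1, 44, 91))$histogram), 3L)
  expect_error(angle_summary(numeric(0)), "at least one")
})

test_that("x-z resampling upsamples z to lateral spacing and keeps labels", {
  ph <- generate_em_volume(tiny_em_params(seed = 3))
  rs <- resample_to_xz(ph$labels)
  d <- dim(ph$labels)
  expect_equal(dim(rs), c(d[3] * 4L, d[2], d[1]))  # sz/sx = 40/10 = 4
  expect_setequal(unique(as.vector(rs)), unique(as.vector(ph$labels)))
  expect_equal(attr(rs, "axis_order"), c("z", "x", "y"))
})

test_that("a fibril along z has elliptical angle 90 via the resampling route", {
  g <- volume_geometry()
  m <- array(FALSE, c(30, 30, 20))
  vox <- rasterize_cylinder(c(0, 0, 1), c(150, 150, 400), 25, 720, g,
                            dim(m))
  m[vox] <- TRUE
  attr(m, "geometry") <- g
  tab <- angles_via_resample(m, min_object_voxels = 20)
  expect_equal(nrow(tab), 1L)
  expect_lt(axial_dist(tab$phi_deg, 90), 2)
  # the 3D projection route agrees
  est <- object_orientation(vox, g)
  expect_lt(axial_dist(elliptical_angle(est), 90), 2)
})

test_that("recovered transmural angle is equivariant under in-plane rotation", {
  g <- volume_geometry()
  dims <- c(140, 140, 20)
  for (th0 in c(10, 25)) {
    est <- sapply(c(th0, th0 + 30), function(th) {
      vox <- rasterize_cylinder(axis_from_angles(th, 0), c(700, 700, 400),
                                30, 900, g, dims)
      transmural_angle(object_orientation(vox, g))
    })
    expect_lt(abs(axial_dist(est[2], est[1]) - 30), 1)
  }
})

test_that("the full angle table pipeline attaches counts and drops speckle", {
  ph <- generate_em_volume(tiny_em_params(n_myofibrils = 6, seed = 12))
  tab <- compute_angle_table(ph$labels, min_object_voxels = 50)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$theta_deg >= 0 & tab$theta_deg < 180, na.rm = TRUE))
  expect_true(all(tab$phi_deg >= 0 & tab$phi_deg < 180, na.rm = TRUE))
  expect_setequal(sort(tab$n_voxels), sort(ph$angles$n_voxels))
})
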