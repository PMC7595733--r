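rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

test_that("identical landmark sets give the identity map with zero residual", {
  pts <- matrix(rnorm(20), 10, 2)
  m <- estimate_similarity(pts, pts)
  expect_equal(m$scale, 1, tolerance = 1e-12)
  expect_equal(m$rotation, diag(2), tolerance = 1e-12)
  expect_equal(m$translation, c(0, 0), tolerance = 1e-12)
  expect_lt(m$rms, 1e-12)
})

test_that("rotation 30 deg, scale 2, translation (5, 7) is recovered to 1e-6", {
  set.seed(10)
  src <- matrix(rnorm(24), 12, 2)
  dst <- t(2 * rot2(30) %*% t(src) + c(5, 7))
  m <- estimate_similarity(src, dst)
  expect_lt(abs(m$scale - 2), 1e-6)
  expect_lt(max(abs(m$rotation - rot2(30))), 1e-6)
  expect_lt(max(abs(m$translation - c(5, 7))), 1e-6)
  expect_lt(m$rms, 1e-9)
})

test_that("the estimator agrees with an independent Procrustes fit", {
  skip_if_not_installed("vegan")
  set.seed(11)
  src <- matrix(rnorm(30), 15, 2)
  dst <- t(1.7 * rot2(-40) %*% t(src) + c(-3, 2)) +
    matrix(rnorm(30, 0, 0.05), 15, 2)
  m <- estimate_similarity(src, dst)
  pr <- vegan::procrustes(dst, src, scale = TRUE, symmetric = FALSE)
  fitted_pr <- pr$scale * src %*% pr$rotation +
    matrix(pr$translation, nrow(src), 2, byrow = TRUE)
  expect_equal(map_points(m, src), fitted_pr, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(m$scale, pr$scale, tolerance = 1e-8)
})

test_that("noisy landmarks give the expected residual RMS", {
  # least-squares residual absorbs 4 of the 2n coordinate dofs (2D
  # similarity): RMS per point ~ sigma * sqrt(2 - 4/n)
  set.seed(12)
  n <- 50; sigma <- 0.1
  rms <- replicate(20, {
    src <- matrix(rnorm(2 * n, 0, 3), n, 2)
    dst <- t(1.5 * rot2(20) %*% t(src) + c(1, -2)) +
      matrix(rnorm(2 * n, 0, sigma), n, 2)
    estimate_similarity(src, dst)$rms
  })
  expect_equal(mean(rms), sigma * sqrt(2 - 4 / n), tolerance = 0.1)
})

test_that("degenerate configurations fail with a named degeneracy", {
  same <- matrix(1, 4, 2)
  expect_error(estimate_similarity(same, same + 1), "coincide")
  line3d <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(estimate_similarity(line3d, line3d), "collinear")
  expect_error(estimate_similarity(matrix(1, 1, 2), matrix(1, 1, 2)),
               "at least 2")
})

test_that("nanometre-to-micrometre scale ratios are recovered exactly", {
  set.seed(13)
  src <- matrix(rnorm(20, 0, 1000), 10, 2)   # nm-scale frame
  s_true <- 1 / 2000
  dst <- t(s_true * rot2(15) %*% t(src) + c(0.5, 0.25))
  m <- estimate_similarity(src, dst)
  expect_lt(abs(m$scale - s_true) / s_true, 1e-6)
})

test_that("point mapping, inversion and composition are exact", {
  # translation-only map applied to the origin
  tr <- structure(list(scale = 1, rotation = diag(2), translation = c(1, 2),
                       source_frame = "a", target_frame = "b", rms = 0,
                       model = "similarity"), class = "similarity_map")
  expect_equal(map_points(tr, cbind(0, 0)), cbind(1, 2), ignore_attr = TRUE)
  # inverse round trip to 1e-9
  set.seed(14)
  src <- matrix(rnorm(16), 8, 2)
  dst <- t(0.5 * rot2(70) %*% t(src) + c(3, -1))
  map <- estimate_similarity(src, dst, "em", "ct")
  inv <- invert_similarity(map)
  pts <- matrix(rnorm(10), 5, 2)
  back <- map_points(inv, map_points(map, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  # frame mismatch is refused
  wrong <- pts; attr(wrong, "frame") <- "ct"
  expect_error(map_points(map, wrong), "frame mismatch")
  # composed transform equals sequential mapping
  m2 <- estimate_similarity(dst, t(3 * rot2(-10) %*% t(dst) + c(0, 4)),
                            "ct", "world")
  comp <- compose_similarity(map, m2)
  expect_lt(max(abs(map_points(comp, pts) -
                    map_points(m2, map_points(map, pts)))), 1e-9)
  # scale 2 then scale 0.5 is the identity
  half <- structure(list(scale = 0.5, rotation = diag(2), translation = c(0, 0),
                         source_frame = "b", target_frame = "c", rms = 0,
                         model = "similarity"), class = "similarity_map")
  dbl <- structure(list(scale = 2, rotation = diag(2), translation = c(0, 0),
                        source_frame = "a", target_frame = "b", rms = 0,
                        model = "similarity"), class = "similarity_map")
  ident <- compose_similarity(dbl, half)
  expect_equal(ident$scale, 1)
  expect_equal(map_points(ident, pts), pts, ignore_attr = TRUE)
})

test_that("sub-ROI corners map through a frame chain; broken chains fail", {
  tr1 <- structure(list(scale = 1, rotation = diag(2), translation = c(1, 0),
                        source_frame = "subroi", target_frame = "section",
                        rms = 0, model = "similarity"), class = "similarity_map")
  tr2 <- structure(list(scale = 1, rotation = diag(2), translation = c(0, 2),
                        source_frame = "section", target_frame = "ct",
                        rms = 0, model = "similarity"), class = "similarity_map")
  rect <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  out <- locate_subroi(list(tr1, tr2), rect)
  expect_equal(out, sweep(rect, 2, c(-1, -2)), ignore_attr = TRUE)
  expect_equal(attr(out, "frame"), "ct")
  bad <- structure(list(scale = 1, rotation = diag(2), translation = c(0, 0),
                        source_frame = "other", target_frame = "ct",
                        rms = 0, model = "similarity"), class = "similarity_map")
  expect_error(locate_subroi(list(tr1, bad), rect), "broken chain")
})

test_that("3D similarity transforms are recovered", {
  set.seed(15)
  src <- matrix(rnorm(30), 10, 3)
  th <- 25 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  dst <- t(1.2 * Rz %*% t(src) + c(1, 2, 3))
  m <- estimate_similarity(src, dst)
  expect_lt(abs(m$scale - 1.2), 1e-9)
  expect_lt(max(abs(m$rotation - Rz)), 1e-9)
  expect_lt(max(abs(m$translation - c(1, 2, 3))), 1e-9)
})
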