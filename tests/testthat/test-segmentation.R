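test_that("a clean two-level phantom segments exactly at any valley threshold", {
  tl <- two_level_volume(noise_sd = 0)
  m_fixed <- segment_extracellular(tl$volume, method = "fixed", threshold = 140)
  expect_equal(as.vector(m_fixed), as.vector(tl$truth))
  m_valley <- segment_extracellular(tl$volume, method = "bimodal-valley")
  expect_equal(as.vector(m_valley), as.vector(tl$truth))
  t_used <- attr(m_valley, "threshold")
  expect_gt(t_used, 80); expect_lt(t_used, 200)
})

test_that("quantile method with q = 0 selects nothing", {
  tissue <- voxel_volume(array(80, c(8, 8, 4)))
  m <- segment_extracellular(tissue, method = "quantile", q = 0)
  expect_false(any(m))
})

test_that("noisy two-level phantom segments with >= 99% pixel accuracy", {
  tl <- two_level_volume(dims = c(48, 48, 8), noise_sd = 10, seed = 8)
  m <- segment_extracellular(tl$volume, method = "bimodal-valley")
  acc <- mean(m == tl$truth)
  expect_gte(acc, 0.99)
})

test_that("unimodal histograms are rejected with advice to use a fixed threshold", {
  uni <- voxel_volume(array(rnorm(4096, 100, 5), c(16, 16, 16)))
  expect_error(segment_extracellular(uni, method = "bimodal-valley"),
               "unimodal.*fixed")
})

test_that("fixed-threshold segmentation is an exact deterministic function", {
  vol <- voxel_volume(array(runif(512, 0, 255), c(8, 8, 8)))
  m1 <- segment_extracellular(vol, method = "fixed", threshold = 97.5)
  expect_identical(as.vector(m1), as.vector(vol >= 97.5))
})

test_that("cleanup removes specks, fills holes, and is idempotent", {
  m <- array(FALSE, c(12, 12, 6))
  m[2:3, 2:3, 2] <- TRUE            # 8-voxel speck
  m[6:10, 6:10, 3:5] <- TRUE        # solid block
  m[8, 8, 4] <- FALSE               # interior hole
  out <- cleanup_mask(m, min_object_voxels = 10, fill_holes = TRUE)
  expect_false(any(out[2:3, 2:3, 2]))   # speck gone
  expect_true(out[8, 8, 4])             # hole filled
  expect_true(all(out[6:10, 6:10, 3:5]))
  expect_equal(sum(out), 75)            # exactly the block
  # empty in, empty out
  expect_false(any(cleanup_mask(array(FALSE, c(4, 4, 4)), 10)))
  expect_error(cleanup_mask(m, min_object_voxels = -1), ">= 0")
})

test_that("cleanup is idempotent on a phantom-derived extracellular mask", {
  ph <- generate_em_volume(tiny_em_params(noise_sd = 12, seed = 14))
  m <- segment_extracellular(ph$intensity, method = "fixed", threshold = 170)
  c1 <- cleanup_mask(m, min_object_voxels = 30, closing_radius = 1,
                     fill_holes = TRUE)
  c2 <- cleanup_mask(c1, min_object_voxels = 30, closing_radius = 1,
                     fill_holes = TRUE)
  expect_identical(as.vector(c1), as.vector(c2))
})

test_that("pixelwise accuracy is truth-class recall with exact confusion counts", {
  g <- volume_geometry()
  truth <- label_volume(array(c(rep(3L, 100), rep(0L, 100)), c(10, 10, 2)), g)
  pred_arr <- array(c(rep(3L, 90), rep(0L, 10), rep(0L, 100)), c(10, 10, 2))
  pred <- label_volume(pred_arr, g)
  acc <- evaluate_segmentation(pred, truth)
  expect_equal(unname(acc$per_class[["myofibril"]]), 90)
  expect_equal(unname(acc$per_class[["extracellular"]]), 100)
  expect_true(is.na(acc$per_class[["nucleus"]]))  # absent from truth
  expect_equal(sum(acc$confusion), acc$n_pixels)
  expect_equal(acc$n_pixels, 200)
  # identity prediction scores 100% on every present class
  same <- evaluate_segmentation(truth, truth)
  expect_equal(unname(same$per_class[["myofibril"]]), 100)
  expect_equal(same$overall, 100)
  # fully disjoint prediction scores 0
  flip <- label_volume(array(ifelse(truth == 3L, 0L, 3L), dim(truth)), g)
  dis <- evaluate_segmentation(flip, truth)
  expect_equal(unname(dis$per_class[["myofibril"]]), 0)
  expect_equal(dis$overall, 0)
})

test_that("accuracy evaluation excludes ignore-class voxels and checks shape", {
  g <- volume_geometry()
  t_arr <- array(3L, c(4, 4, 2)); t_arr[, , 2] <- 255L
  truth <- label_volume(t_arr, g)
  pred <- label_volume(array(3L, c(4, 4, 2)), g)
  acc <- evaluate_segmentation(pred, truth)
  expect_equal(acc$n_pixels, 16)
  expect_error(evaluate_segmentation(label_volume(array(0L, c(2, 2, 2)), g),
                                     truth), "shapes differ")
})

test_that("phantom extracellular segmentation meets the derived accuracy bound", {
  # 6-sigma class separation: threshold midway between cytoplasm (140) and
  # extracellular (200) with noise SD 10
  ph <- generate_em_volume(tiny_em_params(noise_sd = 10, seed = 16))
  m <- segment_extracellular(ph$intensity, method = "fixed", threshold = 170)
  truth_ec <- array(ph$labels == 0L, dim(ph$labels))
  cm <- em_class_map()
  pred <- label_volume(array(ifelse(m, cm[["extracellular"]], cm[["cytoplasm"]]),
                             dim(m)), volume_geom(ph$labels))
  acc <- evaluate_segmentation(pred, ph$labels)
  expect_gte(unname(acc$per_class[["extracellular"]]), 99)
})
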