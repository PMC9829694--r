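test_that("resize at scale 1 is the identity and constants stay constant", {
  set.seed(7)
  v <- volume(array(runif(20^3), dim = c(20, 20, 20)), spacing = c(1, 1, 1))
  same <- resize_volume(v, 1, mode = "linear")
  expect_equal(same$data, v$data, tolerance = 1e-12)
  const <- volume(array(3.5, dim = c(20, 20, 20)), spacing = c(1, 1, 1))
  half <- resize_volume(const, 1 / 2, mode = "linear")
  expect_equal(dim(half$data), c(10L, 10L, 10L))
  expect_equal(half$spacing, c(2, 2, 2))
  expect_true(all(abs(half$data - 3.5) < 1e-12))
  expect_error(resize_volume(v, 0.01), "zero-length")
  expect_error(resize_volume(v, 1.5), "\\(0, 1\\]")
})

test_that("resizing preserves world extent to within one output voxel", {
  v <- volume(array(runif(40^3), dim = c(40, 40, 40)), spacing = c(0.5, 0.5, 0.5))
  r <- resize_volume(v, 1 / 4)
  extent_in <- vol_dim(v) * v$spacing
  extent_out <- vol_dim(r) * r$spacing
  expect_true(all(abs(extent_in - extent_out) < r$spacing))
  # voxel-edge world positions coincide: first output centre sits half an
  # output voxel inside the first input voxel's leading edge
  first_in_edge <- v$affine[1:3, 4] - v$spacing / 2
  first_out_center <- r$affine[1:3, 4]
  expect_equal(as.numeric(first_out_center - first_in_edge), r$spacing / 2,
               tolerance = 1e-9)
})

test_that("nearest-mode resizing never invents labels", {
  set.seed(8)
  lab <- array(sample(c(0L, 1L, 4L, 7L), 24^3, replace = TRUE), dim = rep(24, 3))
  v <- volume(lab, spacing = c(1, 1, 1))
  r <- resize_volume(v, 1 / 3, mode = "nearest")
  expect_true(all(unique(as.vector(r$data)) %in% unique(as.vector(lab))))
})

test_that("reciprocal resize recovers constants exactly, smooth fields to <1%", {
  const <- volume(array(2, dim = c(24, 24, 24)), spacing = c(1, 1, 1))
  down <- resize_volume(const, 1 / 4)
  # going back up to the original grid by pull-back through the identity
  up <- resample_volume(down, identity_affine(), const)
  expect_true(all(abs(up$data[!up$oof] - 2) < 1e-12))

  g <- seq(0, 1, length.out = 32)
  smooth <- volume(outer(outer(sin(2 * pi * g), cos(pi * g)), g + 1),
                   spacing = c(1, 1, 1))
  down <- resize_volume(smooth, 1 / 2)
  up <- resample_volume(down, identity_affine(), smooth)
  err <- abs(up$data - smooth$data)[!up$oof]
  expect_lt(mean(err), 0.01 * diff(range(smooth$data)))
})

test_that("resampling honours the pull-back transform and flags out-of-field", {
  set.seed(9)
  v <- volume(array(runif(16^3), dim = rep(16, 3)), spacing = c(1, 1, 1))
  out <- resample_volume(v, identity_affine(), v)
  expect_lt(max(abs(out$data - v$data)), 1e-9)
  expect_false(any(out$oof))

  # integer-voxel translation of a delta image relocates it exactly
  delta <- array(0, dim = rep(16, 3)); delta[8, 8, 8] <- 1
  dv <- volume(delta, spacing = c(1, 1, 1))
  shift <- affine_from_params(translation = c(2, -3, 1))  # ref -> source
  moved <- resample_volume(dv, shift, dv)
  expect_equal(unname(which(moved$data == 1, arr.ind = TRUE)[1, ]),
               c(6, 11, 7))
  expect_equal(sum(moved$data), 1)

  # transform pushing all content out of the field
  far <- affine_from_params(translation = c(1000, 0, 0))
  gone <- resample_volume(v, far, v)
  expect_true(all(gone$data == 0))
  expect_true(all(gone$oof))

  sing <- identity_affine(); sing$matrix[1, 1] <- 0
  expect_error(resample_volume(v, sing, v), "singular")
})

test_that("gaussian blur preserves constants and total mass approximately", {
  const <- volume(array(1.7, dim = rep(16, 3)), spacing = c(1, 1, 1))
  b <- urpet:::blur_volume(const, 1.2)
  expect_true(all(abs(b$data - 1.7) < 1e-9))
  delta <- array(0, dim = rep(33, 3)); delta[17, 17, 17] <- 1
  db <- urpet:::blur_volume(volume(delta, spacing = c(1, 1, 1)), 1.5)
  expect_equal(sum(db$data), 1, tolerance = 1e-6)
  expect_lt(max(db$data), 0.05)
})
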