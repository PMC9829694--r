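test_that("self-registration recovers the identity", {
  v <- reg_phantom()$vol
  res <- register_affine(v, v)
  expect_true(res$converged)
  expect_lt(max(abs(res$transform$matrix[1:3, 4])), 1e-3)   # mm
  expect_lt(max(abs(res$transform$matrix[1:3, 1:3] - diag(3))), 1e-3)
  expect_lte(res$final_cost, res$initial_cost)
})

test_that("a known two-voxel world shift is recovered within half a voxel", {
  v <- reg_phantom()$vol
  shift <- affine_from_params(translation = 2 * v$spacing)
  moved <- resample_volume(v, shift, v)
  moved$oof <- NULL
  res <- register_affine(moved, v)
  expect_lt(landmark_error_vox(res$transform, invert_affine(shift), v), 0.5)
})

test_that("rotation plus shift is recovered within tolerance", {
  v <- reg_phantom()$vol
  gen <- affine_from_params(translation = c(1.0, -1.5, 0.8),
                            rotation = c(0, 0, 5 * pi / 180),
                            center = world_center(v))
  moved <- resample_volume(v, gen, v)
  moved$oof <- NULL
  res <- register_affine(moved, v)
  expect_lt(landmark_error_vox(res$transform, invert_affine(gen), v), 0.5)
  # rotation angle about z recovered within 1 degree
  ang <- atan2(res$transform$matrix[2, 1], res$transform$matrix[1, 1])
  expect_lt(abs(ang - (-5 * pi / 180)), pi / 180)
})

test_that("registration refuses degenerate inputs", {
  flat <- volume(array(1, dim = rep(16, 3)), spacing = c(1, 1, 1))
  v <- volume(array(runif(16^3), dim = rep(16, 3)), spacing = c(1, 1, 1))
  expect_error(register_affine(flat, v), "flat")
  expect_error(register_affine(v, flat), "flat")
  sparse <- array(0, dim = rep(24, 3)); sparse[12, 12, 12] <- 1
  expect_error(register_affine(volume(sparse, spacing = c(1, 1, 1)), v),
               "support")
})

test_that("registration is exactly reproducible", {
  v <- reg_phantom()$vol
  shift <- affine_from_params(translation = c(1.1, 0.7, -0.9))
  moved <- resample_volume(v, shift, v)
  moved$oof <- NULL
  r1 <- register_affine(moved, v)
  r2 <- register_affine(moved, v)
  expect_identical(r1$transform$matrix, r2$transform$matrix)
  expect_identical(r1$final_cost, r2$final_cost)
})

test_that("two-pass co-registration never increases the dissimilarity", {
  rp <- reg_phantom()
  v <- rp$vol
  mrv <- resize_volume(rp$aset$mr, 1 / rp$spec$mr_upsample)
  gen <- affine_from_params(translation = c(0.9, -0.7, 0.5))
  moved <- resample_volume(v, gen, v)
  moved$oof <- NULL
  nmi <- reg_settings(metric = "nmi", dof = "similarity",
                      pyramid = c(4L, 2L), stride = c(1L, 2L), max_iter = 40L,
                      reltol = 1e-5)
  res <- coregister_template_to_mr(moved, mrv, passes = 2L, settings = nmi)
  expect_length(res$pass_costs, 2L)
  expect_lte(res$pass_costs[2], res$pass_costs[1] + 1e-12)
  res1 <- coregister_template_to_mr(moved, mrv, passes = 1L, settings = nmi)
  expect_lte(res$final_cost, res1$final_cost + 1e-12)
  expect_error(coregister_template_to_mr(moved, mrv, passes = 0L))
})

test_that("small random affine perturbations are recovered reliably", {
  v <- reg_phantom()$vol
  set.seed(77)
  hits <- 0L
  n <- 6L
  for (i in seq_len(n)) {
    gen <- random_perturbation(v, max_trans_vox = 3, max_rot_deg = 8)
    moved <- resample_volume(v, gen, v)
    moved$oof <- NULL
    res <- register_affine(moved, v, reg_settings(dof = "affine",
                                                  max_iter = 100L))
    if (landmark_error_vox(res$transform, invert_affine(gen), v) < 0.5)
      hits <- hits + 1L
  }
  expect_gte(hits, n - 1L)
})
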