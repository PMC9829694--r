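test_that("template of identical inputs equals the normalized input", {
  aset <- tiny_atlas_set()
  study <- simulate_study(aset, tiny_spec())
  scans <- study$volumes[1:3]
  tpl <- build_template(scans, iterations = 1L)
  expect_equal(tpl$data, scans[[1]]$data / mean(scans[[1]]$data),
               tolerance = 1e-9)
  expect_equal(mean(tpl$data), 1, tolerance = 1e-6)
  expect_error(build_template(scans[1]), "at least 2")
})

test_that("the initial voxel-wise mean is invariant to input scan order", {
  spec <- tiny_spec(counts_scale = 40, seed = 9L)
  aset <- tiny_atlas_set()
  study <- simulate_study(aset, spec)
  scans <- study$volumes[c("r01_t1", "r02_t1", "r03_t1")]
  t1 <- build_template(scans, iterations = 0L)
  t2 <- build_template(rev(scans), iterations = 0L)
  expect_lt(max(abs(t1$data - t2$data)), 1e-9)
})

test_that("refinement improves a template built from one shifted copy", {
  v <- reg_phantom()$vol
  gen <- affine_from_params(translation = c(2.0, -1.5, 1.0))
  shifted <- resample_volume(v, gen, v)
  shifted$oof <- NULL
  scans <- list(a = v, b = shifted)
  fast <- reg_settings(metric = "ncc", dof = "similarity",
                       pyramid = c(4L, 2L), stride = 2L, max_iter = 30L,
                       reltol = 1e-5, centroid_init = TRUE)
  t0 <- build_template(scans, iterations = 0L, settings = fast)
  t2 <- build_template(scans, iterations = 2L, settings = fast)
  # dissimilarity of the template to the unshifted original, by the same metric
  ranges <- list(flo = 0, fhi = 1, mlo = 0, mhi = 1)
  cost <- function(tpl) urpet:::metric_cost(
    tpl, volume(v$data / mean(v$data), spacing = v$spacing, affine = v$affine),
    diag(4), fast, ranges, 1L)
  expect_lt(cost(t2), cost(t0))
})

test_that("align_study returns identity composites for a self-aligned study", {
  aset <- tiny_atlas_set()
  study <- simulate_study(aset, tiny_spec())
  vols <- study$volumes[1:4]
  tpl <- build_template(vols[1:2], iterations = 1L)
  al <- align_study(vols, tpl, aset$mr, aset$atlas)
  expect_length(al$volumes, 4L)
  expect_length(al$flagged, 0L)
  for (tr in al$transforms)
    expect_lt(max(abs(tr$matrix - diag(4))), 0.5)   # mm; < 1/3 voxel here
})

test_that("corrupted scans are flagged and excluded, not fatal", {
  aset <- tiny_atlas_set()
  study <- simulate_study(aset, tiny_spec())
  vols <- study$volumes[1:4]
  vols[["r02_t2"]] <- volume(array(0, dim = vol_dim(vols[[1]])),
                             spacing = vols[[1]]$spacing,
                             affine = vols[[1]]$affine)
  tpl <- build_template(vols[c("r01_t1", "r01_t2")], iterations = 1L)
  al <- align_study(vols, tpl, aset$mr, aset$atlas)
  expect_identical(al$flagged, "r02_t2")
  expect_length(al$volumes, 3L)
  expect_match(al$flag_reasons, "flat")
})

test_that("aligned whole-brain activity matches truth for noise-free input", {
  spec <- phantom_spec(seed = 31L, n_per_group = 2L, timepoints_h = 3,
                       biological_cv = 0, global_scale_cv = 0,
                       counts_scale = 0, max_translation_mm = 0,
                       max_rotation_deg = 0, scale_range = c(1, 1))
  aset <- make_atlas(spec)
  study <- simulate_study(aset, spec)
  fit <- run_study(study$manifest, study$volumes, aset$mr, aset$atlas,
                   template_timepoint = 3, template_iterations = 1L)
  lab <- fit$atlas$labels$data
  for (sid in study$manifest$scan_id) {
    v <- fit$alignment$volumes[[sid]]
    use <- lab %in% fit$atlas$whole_brain_labels & !v$oof
    got <- mean(v$data[use]) / study$ground_truth[[sid]]$global_scale
    # voxel-weighted ground-truth whole-brain mean over the same voxels
    truth_map <- study$ground_truth[[sid]]$region_means
    want <- mean(truth_map[fit$atlas$region_map[as.character(lab[use])]])
    expect_lt(abs(got / want - 1), 0.05)
  }
})
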