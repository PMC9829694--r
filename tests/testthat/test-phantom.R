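test_that("phantom atlas has the expected label structure", {
  aset <- tiny_atlas_set()
  lab <- aset$atlas$labels$data
  expect_setequal(unique(as.integer(lab)), 0:6)
  expect_setequal(unname(aset$atlas$region_map),
                  c(atlas_regions(), "brain_tissue"))
  # each analysis region is a minority share of the brain
  brain <- sum(lab > 0)
  for (id in 1:5) expect_lt(sum(lab == id) / brain, 0.30)
  expect_error(phantom_spec(dims = c(16, 16, 16)), "at least 32")
  expect_error(phantom_spec(n_per_group = 1), "at least 2")
})

test_that("the same seed reproduces the study bit for bit", {
  aset <- tiny_atlas_set()
  s1 <- simulate_study(aset, tiny_spec(counts_scale = 25, biological_cv = 0.1,
                                       max_translation_mm = 1,
                                       max_rotation_deg = 3, seed = 77L))
  s2 <- simulate_study(aset, tiny_spec(counts_scale = 25, biological_cv = 0.1,
                                       max_translation_mm = 1,
                                       max_rotation_deg = 3, seed = 77L))
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(lapply(s1$volumes, `[[`, "data"),
                   lapply(s2$volumes, `[[`, "data"))
  s3 <- simulate_study(aset, tiny_spec(counts_scale = 25, seed = 78L))
  expect_false(identical(s1$volumes[[1]]$data, s3$volumes[[1]]$data))
})

test_that("noiseless identity-PSF study closes exactly through compute_ur", {
  aset <- tiny_atlas_set()
  study <- simulate_study(aset, tiny_spec())   # psf 0, no noise, no shift
  for (sid in study$manifest$scan_id[1:3]) {
    for (r in c(atlas_regions(), "whole_brain")) {
      got <- compute_ur(study$volumes[[sid]], study$atlas_pet, r)$ur
      expect_equal(got, unname(study$ground_truth[[sid]]$ur[[r]]),
                   tolerance = 1e-6)
    }
  }
})

test_that("ground-truth URs satisfy partition conservation over the brain", {
  aset <- tiny_atlas_set()
  study <- simulate_study(aset, tiny_spec(biological_cv = 0.1, seed = 5L))
  lab <- study$atlas_pet$labels$data
  n_brain <- sum(lab > 0)
  regions <- c(atlas_regions(), "brain_tissue")
  for (sid in study$manifest$scan_id[1:4]) {
    gt <- study$ground_truth[[sid]]
    w <- vapply(seq_along(regions), function(i) sum(lab == i), numeric(1))
    expect_equal(sum(w / n_brain * gt$ur[regions]), 1, tolerance = 1e-9)
    expect_equal(unname(gt$ur[["whole_brain"]]), 1)
  }
})

test_that("averaging Poisson replicates converges to the noise-free map", {
  aset <- tiny_atlas_set()
  clean <- simulate_study(aset, tiny_spec(psf_fwhm_mm = 1.5))$volumes[[1]]
  err_at <- function(nrep) {
    acc <- 0
    for (k in seq_len(nrep)) {
      s <- simulate_study(aset, tiny_spec(psf_fwhm_mm = 1.5,
                                          counts_scale = 20,
                                          seed = 9000L + k))
      acc <- acc + s$volumes[[1]]$data
    }
    mean(abs(acc / nrep - clean$data))
  }
  ladder <- c(err_at(1), err_at(4), err_at(16))
  expect_true(all(diff(ladder) < 0))   # monotone shrinkage with replicates
})

test_that("misaligned scans record the transform a perfect alignment recovers", {
  aset <- tiny_atlas_set()
  study <- simulate_study(aset, tiny_spec(max_translation_mm = 2,
                                          max_rotation_deg = 5, seed = 12L))
  ref <- study$atlas_pet$labels
  sid <- study$manifest$scan_id[1]
  gt <- study$ground_truth[[sid]]
  realigned <- resample_volume(study$volumes[[sid]], gt$transform, ref)
  clean <- simulate_study(aset, tiny_spec(seed = 12L))$volumes[[sid]]
  ok <- !realigned$oof
  # interpolation smooths edges; interior agreement is what matters
  expect_lt(mean(abs(realigned$data[ok] - clean$data[ok])),
            0.05 * max(clean$data))
})
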