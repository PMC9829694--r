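# two-region toy atlas: region A (label 1) mean 2, rest (label 2) scaled so
# the whole-brain mean is a known value
toy_quant <- function() {
  lab <- array(0L, dim = c(10, 10, 10))
  lab[2:5, 2:9, 2:9] <- 1L
  lab[6:9, 2:9, 2:9] <- 2L
  atlas <- label_atlas(lab, c(`1` = "gray_matter", `2` = "white_matter"),
                       spacing = c(1, 1, 1))
  act <- array(0, dim = dim(lab))
  act[lab == 1L] <- 2
  act[lab == 2L] <- 0.5
  scan <- volume(act, spacing = c(1, 1, 1))
  list(atlas = atlas, scan = scan, lab = lab)
}

test_that("UR satisfies its defining contracts", {
  tq <- toy_quant()
  expect_equal(compute_ur(tq$scan, tq$atlas, "whole_brain")$ur, 1)
  # uniform field: every region has UR 1
  uni <- volume(array(4.2, dim = dim(tq$lab)), spacing = c(1, 1, 1))
  for (r in c("gray_matter", "white_matter", "whole_brain"))
    expect_equal(compute_ur(uni, tq$atlas, r)$ur, 1)
  # two-region phantom: direct formula
  wb_mean <- mean(tq$scan$data[tq$lab > 0])
  expect_equal(compute_ur(tq$scan, tq$atlas, "gray_matter")$ur, 2 / wb_mean)
  # global rescaling leaves UR untouched
  scaled <- tq$scan; scaled$data <- scaled$data * 37.5
  expect_equal(compute_ur(scaled, tq$atlas, "gray_matter")$ur,
               compute_ur(tq$scan, tq$atlas, "gray_matter")$ur,
               tolerance = 1e-12)
  # voxel volume does not enter the mean-based definition
  coarse <- volume(tq$scan$data, spacing = c(2, 3, 4))
  atl2 <- label_atlas(volume(tq$lab, spacing = c(2, 3, 4)),
                      tq$atlas$region_map)
  expect_equal(compute_ur(coarse, atl2, "gray_matter")$ur,
               compute_ur(tq$scan, tq$atlas, "gray_matter")$ur)
})

test_that("partition conservation holds to 1e-9 on a synthetic partition", {
  set.seed(21)
  lab <- array(sample(0:4, 12^3, replace = TRUE), dim = rep(12, 3))
  atlas <- label_atlas(lab, c(`1` = "a", `2` = "b", `3` = "c", `4` = "d"),
                       spacing = c(1, 1, 1))
  scan <- volume(array(rexp(12^3) + 0.1, dim = rep(12, 3)),
                 spacing = c(1, 1, 1))
  n_brain <- sum(lab > 0)
  total <- 0
  for (r in c("a", "b", "c", "d")) {
    rec <- compute_ur(scan, atlas, r)
    total <- total + rec$voxels_used / n_brain * rec$ur
  }
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("out-of-field voxels are excluded and empty regions are errors", {
  tq <- toy_quant()
  scan <- tq$scan
  scan$oof <- array(FALSE, dim = dim(scan$data))
  scan$oof[tq$lab == 1L] <- TRUE   # whole gray matter out of field
  expect_error(compute_ur(scan, tq$atlas, "gray_matter"), "no usable voxels")
  rec <- compute_ur(scan, tq$atlas, "white_matter")
  expect_equal(rec$ur, 1)          # brain reduces to white matter only
  # the sum reading weights by region size
  rec_sum <- compute_ur(tq$scan, tq$atlas, "gray_matter", ur_mode = "sum")
  expect_equal(rec_sum$ur, sum(tq$scan$data[tq$lab == 1L]) /
                 sum(tq$scan$data[tq$lab > 0]))
})

test_that("SUV follows its formula, scales with weight and dose", {
  tq <- toy_quant()
  uni <- volume(array(1, dim = dim(tq$lab)), spacing = c(1, 1, 1))
  rec <- compute_suv(uni, tq$atlas, "gray_matter", injected_MBq = 10,
                     weight_g = 300)
  expect_equal(rec$suv, 30)
  rec2 <- compute_suv(uni, tq$atlas, "gray_matter", 10, 600)
  expect_equal(rec2$suv, 60)   # doubling weight doubles SUV
  rec3 <- compute_suv(tq$scan, tq$atlas, "white_matter", 25, 280)
  expect_equal(rec3$suv, 0.5 / (25 / 280), tolerance = 1e-6)
  expect_error(compute_suv(uni, tq$atlas, "gray_matter", -1, 300), "positive")
  expect_error(compute_suv(uni, tq$atlas, "gray_matter", 10, 0), "positive")
})

test_that("study tabulation has the right cardinality and handles dropouts", {
  aset <- tiny_atlas_set()
  study <- simulate_study(aset, tiny_spec())
  al <- list(volumes = study$volumes, flagged = character())
  tab <- tabulate_study(al, study$atlas_pet, study$manifest)
  # 4 animals x 2 timepoints x (5 regions + whole brain)
  expect_equal(nrow(tab), 4 * 2 * 6)
  expect_true(all(!is.na(tab$ur)))
  expect_true(all(abs(tab$ur[tab$region == "whole_brain"] - 1) < 1e-12))

  al2 <- list(volumes = study$volumes[-1], flagged = names(study$volumes)[1])
  tab2 <- tabulate_study(al2, study$atlas_pet, study$manifest)
  expect_equal(nrow(tab2), 48)
  expect_equal(sum(is.na(tab2$ur)), 6)   # explicit absent rows, no zeros
  expect_identical(attr(tab2, "flagged"), names(study$volumes)[1])

  bad <- list(volumes = study$volumes[-1], flagged = character())
  expect_error(tabulate_study(bad, study$atlas_pet, study$manifest),
               "mismatch")
})

test_that("vectorized tabulation agrees with compute_ur row by row", {
  aset <- tiny_atlas_set()
  study <- simulate_study(aset, tiny_spec(counts_scale = 30, seed = 14L))
  al <- list(volumes = study$volumes[1:3], flagged = character())
  man <- study$manifest[study$manifest$scan_id %in% names(al$volumes), ]
  tab <- tabulate_study(al, study$atlas_pet, man)
  for (i in sample(nrow(tab), 8)) {
    rec <- compute_ur(al$volumes[[tab$scan_id[i]]], study$atlas_pet,
                      tab$region[i])
    expect_equal(tab$ur[i], rec$ur, tolerance = 1e-12)
    expect_equal(tab$voxels_used[i], rec$voxels_used)
  }
})
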