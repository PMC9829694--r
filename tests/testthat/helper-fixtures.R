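# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# small phantom spec for unit tests: 32^3 grid, atlas at PET resolution,
# noise and misalignment off unless a test overrides them
tiny_spec <- function(...) {
  args <- list(dims = c(32L, 32L, 32L), spacing_mm = c(1.6, 1.6, 1.6),
               n_per_group = 2L, timepoints_h = c(3, 24), mr_upsample = 1L,
               counts_scale = 0, biological_cv = 0, global_scale_cv = 0,
               max_translation_mm = 0, max_rotation_deg = 0,
               scale_range = c(1, 1), psf_fwhm_mm = 0, seed = 42L)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

tiny_atlas_set <- function() cached("tiny_atlas", make_atlas(tiny_spec()))

# one clean, PSF-blurred 64^3 phantom image for registration tests
reg_phantom <- function() {
  cached("reg_phantom", {
    spec <- phantom_spec(seed = 402L, biological_cv = 0, global_scale_cv = 0,
                         counts_scale = 0, max_translation_mm = 0,
                         max_rotation_deg = 0, scale_range = c(1, 1))
    aset <- make_atlas(spec)
    study <- simulate_study(aset, spec)
    list(vol = study$volumes[[1L]], aset = aset, spec = spec)
  })
}

# independent brute-force oracle: exact two-sided Mann-Whitney p by full
# enumeration of all group assignments of the pooled sample
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- utils::combn(n, n1, u_of)
  lower <- mean(us <= u_obs + 1e-12)
  upper <- mean(us >= u_obs - 1e-12)
  min(1, 2 * min(lower, upper))
}

# random small affine perturbation within given ranges (voxel units -> mm)
random_perturbation <- function(vol, max_trans_vox = 4, max_rot_deg = 10,
                                scale_range = c(0.95, 1.05)) {
  sp <- mean(vol$spacing)
  affine_from_params(
    translation = stats::runif(3, -max_trans_vox, max_trans_vox) * sp,
    rotation = stats::runif(3, -max_rot_deg, max_rot_deg) * pi / 180,
    log_scale = log(stats::runif(3, scale_range[1], scale_range[2])),
    center = world_center(vol))
}

# mean landmark error (in voxels) between two transforms over brain points
landmark_error_vox <- function(t1, t2, vol) {
  d <- vol_dim(vol) * vol$spacing
  pts <- cbind(stats::runif(200, 0.25 * d[1], 0.75 * d[1]),
               stats::runif(200, 0.25 * d[2], 0.75 * d[2]),
               stats::runif(200, 0.25 * d[3], 0.75 * d[3]))
  mean(sqrt(rowSums((apply_affine(t1, pts) - apply_affine(t2, pts))^2))) /
    mean(vol$spacing)
}
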