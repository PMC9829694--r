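#' Digital phantom study specification
#'
#' Parameters of the synthetic rat-brain FDG-PET study used to exercise the
#' pipeline end to end. The defaults emulate the experimental design the
#' analysis assumes: two groups (SAH and sham-operated controls) of 7
#' animals, serial scans at 3 h, 1 day, 4 days and 7 days post-operation,
#' region-wise multiplicative group effects (gray matter, neocortex and
#' olfactory system elevated in SAH; white matter and basal forebrain
#' reduced), a Gaussian point-spread blur, voxel-wise Poisson count noise,
#' and a random per-scan affine misalignment.
#'
#' @param dims PET grid dimensions (>= 32 per axis).
#' @param spacing_mm PET voxel size in mm.
#' @param n_per_group animals per group (>= 2).
#' @param timepoints_h scan times in hours post-operation.
#' @param baseline named baseline activity concentration (arbitrary units)
#'   for the five analysis regions plus `brain_tissue`, the unlabelled
#'   remainder of the brain that completes the whole-brain VOI; gray matter
#'   is the reference at 1. FDG-like contrast: gray structures high, white
#'   matter low.
#' @param sah_effects named per-region multiplicative uptake factors applied
#'   to the SAH group at every timepoint (sham is 1 everywhere). May also be
#'   a regions x timepoints matrix for time-varying effects. The default
#'   directions follow the disease biology the study design assumes:
#'   gray matter, neocortex and olfactory system elevated, white matter and
#'   basal forebrain reduced — opposite-direction effects that largely
#'   cancel in the whole-brain denominator, as each analysis region is a
#'   minority share of whole-brain activity.
#' @param background_activity activity outside the brain (body background).
#' @param biological_cv lognormal coefficient of variation of per-scan,
#'   per-region uptake around its expected value (animal-to-animal biology).
#'   The default is calibrated so that the between-group separations the
#'   study design reports (p at or below 0.01-0.001 in exact rank tests with
#'   7 animals per group) are reproduced at the default effect sizes; such
#'   p-values at n = 7 require near-complete separation of the group UR
#'   distributions.
#' @param global_scale_cv lognormal CV of a per-scan global intensity factor
#'   (dose/uptake variability; cancels in UR, visible in SUV).
#' @param psf_fwhm_mm full width at half maximum of the scanner point-spread
#'   function; 0 disables blur.
#' @param counts_scale expected Poisson counts per voxel at unit
#'   concentration; 0 or `Inf` disables count noise.
#' @param max_translation_mm,max_rotation_deg,scale_range per-scan
#'   misalignment ranges (uniform draws); set the first two to 0 and
#'   `scale_range = c(1, 1)` for perfectly aligned scans.
#' @param mr_upsample integer factor by which the MR/atlas grid refines the
#'   PET grid (the pipeline resizes it back down by `1/mr_upsample`).
#' @param seed RNG seed making the whole study reproducible.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64L, 64L, 64L),
                         spacing_mm = c(0.8, 0.8, 0.8),
                         n_per_group = 7L,
                         timepoints_h = c(3, 24, 96, 168),
                         baseline = c(gray_matter = 1.0, white_matter = 0.55,
                                      neocortex = 1.15, basal_forebrain = 0.75,
                                      olfactory_system = 0.95,
                                      brain_tissue = 0.85),
                         sah_effects = c(gray_matter = 1.3, white_matter = 0.8,
                                         neocortex = 1.25, basal_forebrain = 0.85,
                                         olfactory_system = 1.15,
                                         brain_tissue = 1.0),
                         background_activity = 0.02,
                         biological_cv = 0.05,
                         global_scale_cv = 0.15,
                         psf_fwhm_mm = 1.5,
                         counts_scale = 60,
                         max_translation_mm = 1.6,
                         max_rotation_deg = 5,
                         scale_range = c(0.97, 1.03),
                         mr_upsample = 2L,
                         seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 32L))
    stop("phantom grid must be at least 32 voxels per axis")
  if (n_per_group < 2L) stop("need at least 2 animals per group")
  regions <- c(atlas_regions(), "brain_tissue")
  if (!"brain_tissue" %in% names(baseline))
    baseline <- c(baseline, brain_tissue = unname(baseline["gray_matter"]) * 0.85)
  if (!is.matrix(sah_effects) && !"brain_tissue" %in% names(sah_effects))
    sah_effects <- c(sah_effects, brain_tissue = 1.0)
  stopifnot(all(regions %in% names(baseline)), all(baseline > 0))
  ntp <- length(timepoints_h)
  if (is.matrix(sah_effects)) {
    stopifnot(all(regions %in% rownames(sah_effects)),
              ncol(sah_effects) == ntp, all(sah_effects > 0))
    eff <- sah_effects[regions, , drop = FALSE]
  } else {
    stopifnot(all(regions %in% names(sah_effects)), all(sah_effects > 0))
    eff <- matrix(sah_effects[regions], nrow = length(regions), ncol = ntp,
                  dimnames = list(regions, NULL))
  }
  stopifnot(psf_fwhm_mm >= 0, biological_cv >= 0, global_scale_cv >= 0,
            counts_scale >= 0, max_translation_mm >= 0, max_rotation_deg >= 0,
            length(scale_range) == 2L, all(scale_range > 0),
            mr_upsample >= 1L)
  structure(list(dims = dims, spacing_mm = spacing_mm,
                 n_per_group = as.integer(n_per_group),
                 timepoints_h = timepoints_h, baseline = baseline[regions],
                 sah_effects = eff, background_activity = background_activity,
                 biological_cv = biological_cv,
                 global_scale_cv = global_scale_cv,
                 psf_fwhm_mm = psf_fwhm_mm, counts_scale = counts_scale,
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 scale_range = scale_range,
                 mr_upsample = as.integer(mr_upsample),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build the phantom label atlas and MR-like volume
#'
#' Constructs nested geometric brain regions on a grid refined by
#' `mr_upsample` relative to the PET grid (standing in for a high-resolution
#' MR atlas): an ellipsoidal brain whose core is white matter, surrounded by
#' a gray-matter band, a dorsal outer shell of neocortex, a ventral-anterior
#' basal forebrain band, an anterior olfactory bulb, and unlabelled brain
#' tissue completing the whole-brain VOI, so that each analysis region is a
#' minority share of whole-brain activity as in a real labelled atlas.
#' The MR-like volume maps each label to a distinct smooth intensity
#' — deliberately not monotone in the PET activity, so that cross-modality
#' alignment genuinely requires an information-based metric.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `atlas` (a [label_atlas()]), `mr` (a [volume()]), both on
#'   the refined grid; `pet_geometry` (an empty [volume()] carrying the PET
#'   grid geometry).
#' @export
make_atlas <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- spec$mr_upsample
  d <- spec$dims * f
  sp <- spec$spacing_mm / f
  # normalized coordinates in [-1, 1] over the grid (voxel centres)
  cx <- (seq_len(d[1]) - 1) / (d[1] - 1) * 2 - 1
  cy <- (seq_len(d[2]) - 1) / (d[2] - 1) * 2 - 1
  cz <- (seq_len(d[3]) - 1) / (d[3] - 1) * 2 - 1
  X <- array(rep(cx, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)
  # main brain ellipsoid, centred slightly posterior to leave room for the
  # olfactory bulb anteriorly (+y anterior, +z dorsal); r2 is the squared
  # normalized ellipsoidal radius, so a ball r2 <= a holds a^(3/2) of the
  # brain volume. Each analysis region is deliberately a minority share of
  # the whole-brain VOI (as in a real atlas, where most tissue belongs to
  # none of the five largest labelled regions).
  r2 <- (X / 0.62)^2 + ((Y + 0.08) / 0.55)^2 + (Z / 0.52)^2
  lab <- array(0L, dim = d)
  brain <- r2 <= 1
  lab[brain] <- 6L                                       # unlabelled tissue
  # compact structures (low surface-to-volume, as in a real atlas, so the
  # point-spread blur does not wash regional means out): a central white
  # matter core, two lateral gray matter lobes, a ventral basal forebrain
  # blob; the neocortex is genuinely a thin dorsal shell and the olfactory
  # system an anterior bulb
  ell <- function(cx, cy, cz, ax, ay, az)
    ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2 <= 1
  lab[brain & ell(0, -0.08, -0.02, 0.30, 0.32, 0.26)] <- 2L   # white matter
  lab[brain & (ell(0.36, -0.02, 0.05, 0.18, 0.34, 0.27) |
                 ell(-0.36, -0.02, 0.05, 0.18, 0.34, 0.27))] <- 1L  # gray
  lab[brain & ell(0, 0.18, -0.30, 0.20, 0.22, 0.14)] <- 4L    # basal foreb.
  lab[brain & r2 > 0.78 & Z > 0.15] <- 3L                     # neocortex
  bulb <- (X / 0.20)^2 + ((Y - 0.62) / 0.22)^2 + ((Z + 0.05) / 0.18)^2
  lab[bulb <= 1] <- 5L                                        # olfactory
  region_map <- stats::setNames(c(atlas_regions(), "brain_tissue"),
                                as.character(1:6))
  atlas <- label_atlas(lab, region_map, spacing = sp)
  mr_levels <- c(0.35, 0.95, 0.55, 0.75, 0.25, 0.45)     # nonmonotone vs uptake
  mr <- array(0.05, dim = d)
  for (id in 1:6) mr[lab == id] <- mr_levels[id]
  mr <- volume(mr, spacing = sp)
  mr <- blur_volume(mr, sigma_mm = 0.6 * sp[1] * f)
  pet_geometry <- volume(array(0, dim = spec$dims), spacing = spec$spacing_mm)
  list(atlas = atlas, mr = mr, pet_geometry = pet_geometry)
}

# uniform draw helper for misalignment parameters
runif_pm <- function(n, max) if (max == 0) rep(0, n) else stats::runif(n, -max, max)

#' Simulate the phantom study
#'
#' Generates the full serial study: for every animal and timepoint, the
#' expected activity map (region baseline x group effect x per-scan
#' biological factor, plus body background) is blurred with the Gaussian
#' PSF, repositioned by a random per-scan affine misalignment, and Poisson
#' count noise is drawn at the configured expected-count scale. Everything
#' needed to score the pipeline is recorded as ground truth: the generating
#' transforms, the true regional mean concentrations of the blurred
#' noise-free map, and the true uptake ratios.
#'
#' @param atlas_set result of [make_atlas()].
#' @param spec the same [phantom_spec()].
#' @return A list of class `phantom_study`: `manifest` (data frame with
#'   `scan_id`, `animal_id`, `group`, `timepoint_h`, `frame_window`,
#'   `injected_MBq`, `weight_g`), `volumes` (named list of PET scans),
#'   `ground_truth` (per scan: `transform` — the atlas-world to scan-world
#'   map a perfect alignment should recover — `applied`, `global_scale`,
#'   `region_means`, `ur`), and `atlas_pet` (the atlas resized to the PET
#'   grid).
#' @export
simulate_study <- function(atlas_set, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  atlas_pet <- if (spec$mr_upsample > 1L)
    resize_atlas(atlas_set$atlas, 1 / spec$mr_upsample) else atlas_set$atlas
  ref <- atlas_pet$labels
  lab <- ref$data
  regions <- c(atlas_regions(), "brain_tissue")
  region_ids <- stats::setNames(1:6, regions)
  ntp <- length(spec$timepoints_h)
  groups <- c(rep("sham", spec$n_per_group), rep("SAH", spec$n_per_group))
  animals <- sprintf("r%02d", seq_along(groups))
  weights <- stats::runif(length(animals), 250, 300)

  manifest <- list(); volumes <- list(); truth <- list()
  for (a in seq_along(animals)) {
    for (t in seq_len(ntp)) {
      sid <- sprintf("%s_t%d", animals[a], t)
      eff <- if (groups[a] == "SAH") spec$sah_effects[, t] else
        rep(1, length(regions))
      bio <- exp(stats::rnorm(length(regions), 0, spec$biological_cv))
      gscale <- exp(stats::rnorm(1, 0, spec$global_scale_cv))
      conc <- array(spec$background_activity, dim = dim(lab))
      region_true <- stats::setNames(spec$baseline * eff * bio, regions)
      for (r in regions) conc[lab == region_ids[[r]]] <- region_true[[r]]
      vol <- volume(conc, spacing = ref$spacing, affine = ref$affine)
      if (spec$psf_fwhm_mm > 0)
        vol <- blur_volume(vol, spec$psf_fwhm_mm / (2 * sqrt(2 * log(2))))

      # ground-truth regional means of the blurred, noise-free, unshifted map
      means <- vapply(regions, function(r) mean(vol$data[lab == region_ids[[r]]]),
                      numeric(1))
      brain_mean <- mean(vol$data[lab %in% atlas_pet$whole_brain_labels])
      true_ur <- c(means / brain_mean, whole_brain = 1)

      # per-scan misalignment: scan = phantom pulled through T_mis
      tr <- runif_pm(3, spec$max_translation_mm)
      rot <- runif_pm(3, spec$max_rotation_deg * pi / 180)
      scl <- if (all(spec$scale_range == 1)) c(0, 0, 0) else
        log(stats::runif(3, spec$scale_range[1], spec$scale_range[2]))
      t_mis <- affine_from_params(translation = tr, rotation = rot,
                                  log_scale = scl, center = world_center(ref))
      scan <- vol
      scan$data <- scan$data * gscale
      if (any(tr != 0) || any(rot != 0) || any(scl != 0))
        scan <- resample_volume(scan, t_mis, ref, mode = "linear")
      if (spec$counts_scale > 0 && is.finite(spec$counts_scale)) {
        lambda <- pmax(scan$data, 0) * spec$counts_scale
        scan$data <- array(stats::rpois(length(lambda), lambda) / spec$counts_scale,
                           dim = dim(lambda))
      }
      scan$oof <- NULL   # an acquired scan has no resampling provenance

      manifest[[sid]] <- data.frame(
        scan_id = sid, animal_id = animals[a], group = groups[a],
        timepoint_h = spec$timepoints_h[t], frame_window = "50-60min",
        injected_MBq = stats::rnorm(1, 31.4, 3.4),
        weight_g = weights[a], stringsAsFactors = FALSE)
      volumes[[sid]] <- scan
      truth[[sid]] <- list(transform = invert_affine(t_mis),
                           applied = t_mis, global_scale = gscale,
                           region_means = means, ur = true_ur)
    }
  }
  structure(list(manifest = do.call(rbind, manifest), volumes = volumes,
                 ground_truth = truth, atlas_pet = atlas_pet, spec = spec),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic FDG-PET study: %d scans (%d animals x %d timepoints), grid %s\n",
              nrow(m), length(unique(m$animal_id)),
              length(unique(m$timepoint_h)),
              paste(x$spec$dims, collapse = " x ")))
  invisible(x)
}
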