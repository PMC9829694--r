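#' Registration settings
#'
#' Configuration for intensity-based affine registration. The defaults follow
#' standard practice for small-animal PET: normalized cross-correlation
#' within a modality, mutual information (32-bin joint histogram) across
#' modalities, a 3-level coarse-to-fine pyramid, and a deterministic
#' quasi-Newton descent over the affine parameters.
#'
#' @param metric `"ncc"` (same modality); `"cr"` (Roche's correlation
#'   ratio, the default cross-modality choice here: it measures how far PET
#'   intensity is a function of the anatomical intensity, needs no binning
#'   of the moving image and therefore has a smooth surface); or `"mi"` /
#'   `"nmi"` ((normalized) mutual information; NMI is Studholme's
#'   overlap-invariant form).
#' @param dof degrees of freedom: `"rigid"` (6), `"similarity"` (9:
#'   translation, rotation, anisotropic scale) or `"affine"` (12: + shear).
#' @param pyramid integer downsampling factors, coarse to fine.
#' @param max_iter optimizer iteration cap per pyramid level.
#' @param reltol relative cost-change convergence tolerance.
#' @param nbins joint-histogram bins for the MI metric.
#' @param stride metric subsampling stride per pyramid level (recycled):
#'   evaluate the similarity on every `stride`-th voxel along each axis.
#'   The default samples fully at the coarse levels and every second voxel
#'   at the finest level, the usual speed/accuracy compromise.
#' @param crop when `TRUE` (default) the fixed image is cropped to the
#'   bounding box of its support (plus a margin) before optimization, so the
#'   metric is not dominated by empty background.
#' @param coarse_search_mm half-width in mm of a deterministic translation
#'   grid search run at the coarsest pyramid level before gradient descent
#'   (step: half a coarse voxel). 0 disables it; useful for histogram-based
#'   metrics whose surface is locally flat.
#' @param centroid_init when `TRUE`, initialize the translation from the
#'   difference of the two images' intensity centroids before descending —
#'   the standard guard against coarse-level traps at large offsets. The
#'   default enables it for the same-modality NCC metric and disables it
#'   across modalities, where the two centroids need not correspond.
#' @return A list of class `reg_settings`.
#' @export
reg_settings <- function(metric = c("ncc", "cr", "nmi", "mi"),
                         dof = c("affine", "similarity", "rigid"),
                         pyramid = c(4L, 2L, 1L),
                         max_iter = 200L,
                         reltol = 1e-6,
                         nbins = 32L,
                         stride = c(1L, 1L, 2L),
                         crop = TRUE,
                         coarse_search_mm = 0,
                         centroid_init = NULL) {
  metric <- match.arg(metric)
  dof <- match.arg(dof)
  if (is.null(centroid_init)) centroid_init <- metric == "ncc"
  stopifnot(all(pyramid >= 1L), max_iter >= 1L, reltol > 0, nbins >= 4L,
            all(stride >= 1L))
  pyramid <- as.integer(sort(unique(pyramid), decreasing = TRUE))
  stride <- as.integer(rep_len(stride, length(pyramid)))
  structure(list(metric = metric, dof = dof, pyramid = pyramid,
                 max_iter = as.integer(max_iter), reltol = reltol,
                 nbins = as.integer(nbins), stride = stride,
                 crop = isTRUE(crop), coarse_search_mm = coarse_search_mm,
                 centroid_init = isTRUE(centroid_init)),
            class = "reg_settings")
}

# crop a volume to the bounding box of voxels above frac * max, plus margin;
# world geometry is preserved by shifting the affine origin. The origin is
# snapped to a multiple of `align` (the coarsest pyramid factor) so that
# block-mean pyramid grids of cropped and uncropped images coincide.
crop_to_support <- function(vol, frac = 0.02, margin = 3L, align = 1L) {
  keep <- vol$data > frac * max(vol$data)
  if (!any(keep)) return(vol)
  idx <- which(keep, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  lo <- lo - (lo - 1L) %% align
  hi <- pmin(apply(idx, 2, max) + margin, vol_dim(vol))
  if (all(lo == 1L) && all(hi == vol_dim(vol))) return(vol)
  sub <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  shift <- diag(4)
  shift[1:3, 4] <- lo - 1L
  volume(sub, spacing = vol$spacing, affine = vol$affine %*% shift)
}

n_params_for_dof <- function(dof) {
  switch(dof, rigid = 6L, similarity = 9L, affine = 12L)
}

params_to_affine <- function(p, center) {
  affine_transform(params_to_matrix(p, center))
}

# same map as affine_from_params, without object construction or validation
# (this sits in the optimizer's innermost loop)
params_to_matrix <- function(p, center) {
  full <- numeric(12L)
  full[seq_along(p)] <- p
  A <- rotation_matrix(full[4], full[5], full[6])
  A[, 2] <- A[, 2] + A[, 1] * full[10]
  A[, 3] <- A[, 3] + A[, 1] * full[11] + A[, 2] * full[12]
  A <- A * rep(exp(full[7:9]), each = 3)
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- full[1:3] + center - A %*% center
  m
}

metric_cost <- function(moving, fixed, A, settings, ranges, stride = 1L) {
  metric_cost_idx(moving, fixed, solve(moving$affine) %*% A %*% fixed$affine,
                  settings, ranges, stride)
}

metric_cost_idx <- function(moving, fixed, M, settings, ranges, stride) {
  M <- M[1:3, , drop = FALSE]
  if (settings$metric == "ncc") {
    cpp_cost_ncc(moving$data, vol_dim(moving), fixed$data, vol_dim(fixed), M,
                 stride)
  } else if (settings$metric == "cr") {
    cpp_cost_cr(moving$data, vol_dim(moving), fixed$data, vol_dim(fixed), M,
                settings$nbins, ranges$flo, ranges$fhi, stride)
  } else {
    cpp_cost_mi(moving$data, vol_dim(moving), fixed$data, vol_dim(fixed), M,
                settings$nbins, ranges$flo, ranges$fhi, ranges$mlo, ranges$mhi,
                stride, as.integer(settings$metric == "nmi"))
  }
}

# intensity-centroid world coordinates, for translation initialization
intensity_centroid <- function(vol) {
  d <- vol_dim(vol)
  w <- vol$data
  tot <- sum(w)
  if (tot <= 0) return(world_center(vol))
  ix <- sum(w * rep(seq_len(d[1]) - 1, times = d[2] * d[3])) / tot
  iy <- sum(w * rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])) / tot
  iz <- sum(w * rep(seq_len(d[3]) - 1, each = d[1] * d[2])) / tot
  as.numeric(apply_affine(affine_transform(vol$affine), c(ix, iy, iz)))
}

#' Intensity-based affine registration
#'
#' Estimates the affine transform aligning `moving` to `fixed` by minimizing
#' an intensity dissimilarity (1 - NCC, or negative mutual information) over
#' a coarse-to-fine resolution pyramid with a deterministic BFGS descent.
#' The parameterization (translation mm, Euler rotation, log-scale, shear) is
#' centred on the fixed image's world centroid. The returned transform maps
#' fixed-space world coordinates into moving-space world coordinates, i.e. it
#' is directly usable to pull `moving` onto the `fixed` grid with
#' [resample_volume()].
#'
#' @param moving,fixed [volume()] objects with nonzero dynamic range.
#' @param settings a [reg_settings()] list.
#' @param init optional initial [affine_transform()] (fixed world -> moving
#'   world); defaults to the identity.
#' @return A list of class `registration_result`: `transform`, `final_cost`,
#'   `initial_cost` (cost at `init` on the finest level), `iterations`,
#'   `converged`, `settings`.
#' @export
register_affine <- function(moving, fixed, settings = reg_settings(),
                            init = identity_affine()) {
  stopifnot(inherits(moving, "pet_volume"), inherits(fixed, "pet_volume"))
  if (stats::sd(fixed$data) == 0 || stats::sd(moving$data) == 0)
    stop("cannot register a flat (zero-variance) image")
  support <- mean(moving$data > 0.02 * max(moving$data))
  if (support < 0.05)
    stop(sprintf(paste0("moving image support (%.1f%% of field of view) is ",
                        "below 5%%; refusing to fit background"),
                 100 * support))
  np <- n_params_for_dof(settings$dof)
  center <- world_center(fixed)
  if (settings$crop)
    fixed <- crop_to_support(fixed, align = max(settings$pyramid))
  ranges <- list(flo = min(fixed$data), fhi = max(fixed$data),
                 mlo = min(moving$data), mhi = max(moving$data))
  sp <- mean(fixed$spacing)
  parscale <- c(rep(sp, 3L), rep(0.02, 3L), rep(0.02, 3L), rep(0.02, 3L))[1:np]

  p <- numeric(np)
  if (settings$centroid_init)
    p[1:3] <- as.numeric(solve(init$matrix) %*%
                           c(intensity_centroid(moving), 1))[1:3] -
      intensity_centroid(fixed)
  iterations <- 0L
  converged <- TRUE
  for (li in seq_along(settings$pyramid)) {
    f <- settings$pyramid[li]
    stride <- settings$stride[li]
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    pre <- solve(mv$affine) %*% init$matrix
    post <- fx$affine
    cost_f <- function(q) {
      # out-of-overlap and degenerate parameter vectors land on the metric's
      # sentinel plateau (2); add a pull-back penalty so the line search
      # cannot wander off across the flat region
      if (any(!is.finite(q))) return(4)
      v <- metric_cost_idx(mv, fx, pre %*% params_to_matrix(q, center) %*% post,
                           settings, ranges, stride)
      if (v >= 2) v <- 2 + 1e-3 * sum((q / parscale)^2)
      v
    }
    if (li == 1L && settings$coarse_search_mm > 0) {
      step <- mean(fx$spacing) / 2
      offs <- seq(-settings$coarse_search_mm, settings$coarse_search_mm, by = step)
      grid <- as.matrix(expand.grid(offs, offs, offs))
      costs <- apply(grid, 1L, function(tr) {
        q <- p; q[1:3] <- p[1:3] + tr; cost_f(q)
      })
      p[1:3] <- p[1:3] + grid[which.min(costs), ]
    }
    cost_before <- cost_f(p)
    opt <- stats::optim(p, cost_f, method = "BFGS",
                        control = list(maxit = settings$max_iter,
                                       reltol = settings$reltol,
                                       parscale = parscale,
                                       ndeps = rep(5e-3, np)))
    p <- opt$par
    iterations <- iterations + as.integer(opt$counts[["function"]])
    if (li == length(settings$pyramid)) {
      # BFGS runs to its iteration cap when started on a flat optimum; call
      # the fit converged when the optimizer said so or when the level had
      # nothing left to improve
      improved <- cost_before - opt$value
      converged <- opt$convergence == 0L ||
        improved <= max(settings$reltol, settings$reltol * abs(cost_before))
    }
  }

  # guarantee the final cost never exceeds the cost of the initialization,
  # evaluated on the finest level actually optimized
  li <- length(settings$pyramid)
  mv <- downsample_volume(moving, settings$pyramid[li])
  fx <- downsample_volume(fixed, settings$pyramid[li])
  initial_cost <- metric_cost(mv, fx, init$matrix, settings, ranges,
                              settings$stride[li])
  A_fit <- init$matrix %*% params_to_affine(p, center)$matrix
  final_cost <- metric_cost(mv, fx, A_fit, settings, ranges,
                            settings$stride[li])
  if (final_cost > initial_cost) {
    # never return a solution worse than its own starting point
    A_fit <- init$matrix
    final_cost <- initial_cost
  }
  structure(list(transform = affine_transform(A_fit),
                 final_cost = final_cost, initial_cost = initial_cost,
                 iterations = iterations, converged = converged,
                 settings = settings),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("Affine registration (%s, %s): cost %.6g (start %.6g), %d evaluations%s\n",
              x$settings$metric, x$settings$dof, x$final_cost, x$initial_cost,
              x$iterations, if (x$converged) "" else " [not converged]"))
  print(x$transform)
  invisible(x)
}

#' Co-register the PET template with the MR dataset
#'
#' Runs the cross-modality registration repeatedly (default two passes, each
#' pass restarting the optimizer from the previous pass's solution), so the
#' dissimilarity is non-increasing across passes. The MR volume is the fixed
#' image: the returned transform maps MR/atlas world coordinates into
#' template world coordinates and therefore carries template-aligned PET data
#' onto the atlas grid by pull-back.
#'
#' @param template control-group PET template [volume()].
#' @param mr MR volume already resized to PET resolution.
#' @param passes number of refinement passes (>= 1).
#' @param settings [reg_settings()]; defaults to mutual information.
#' @return A `registration_result` whose `pass_costs` field records the final
#'   cost after each pass.
#' @export
coregister_template_to_mr <- function(template, mr, passes = 2L,
                                      settings = reg_settings(metric = "mi")) {
  stopifnot(passes >= 1L)
  init <- identity_affine()
  pass_costs <- numeric(passes)
  res <- NULL
  for (k in seq_len(passes)) {
    res <- register_affine(template, mr, settings = settings, init = init)
    init <- res$transform
    pass_costs[k] <- res$final_cost
  }
  res$pass_costs <- pass_costs
  res
}
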