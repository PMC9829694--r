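#' Resize a volume by per-axis scale factors
#'
#' Adapts a high-resolution volume (MR image or label atlas) to a lower
#' target resolution, e.g. by the study's default scale factor of 1/20.
#' Output dimensions are `round(dims * scale)`, output spacing is
#' `spacing / scale`, and the world extent of the grid is preserved to within
#' one output voxel. Linear mode evaluates trilinear interpolation at output
#' voxel centres; nearest mode is mandatory for integer label grids so that
#' no new labels are invented.
#'
#' @param vol a [volume()].
#' @param scale scalar or length-3 per-axis factor in (0, 1].
#' @param mode `"linear"` (intensity images) or `"nearest"` (label grids).
#' @return A [volume()] on the resized grid.
#' @export
resize_volume <- function(vol, scale, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "pet_volume"))
  if (length(scale) == 1L) scale <- rep(scale, 3L)
  if (any(!is.finite(scale)) || any(scale <= 0) || any(scale > 1))
    stop("scale factors must lie in (0, 1]")
  d <- vol_dim(vol)
  od <- as.integer(round(d * scale))
  if (any(od < 1L))
    stop("scale produces a zero-length axis: output dims ",
         paste(od, collapse = " x "))
  # out voxel index -> in voxel index, aligning voxel-edge world extents
  f <- d / od
  idx_map <- diag(c(f, 1))
  idx_map[1:3, 4] <- (f - 1) / 2
  r <- cpp_resample_affine(vol$data, d, od, idx_map[1:3, , drop = FALSE],
                           as.integer(mode == "nearest"))
  out_affine <- vol$affine %*% idx_map
  volume(array(r$data, dim = od), spacing = vol$spacing * f,
         affine = out_affine)
}

#' @rdname resize_volume
#' @param atlas a [label_atlas()].
#' @export
resize_atlas <- function(atlas, scale) {
  lab <- resize_volume(atlas$labels, scale, mode = "nearest")
  lab$data <- round(lab$data)
  label_atlas(lab, atlas$region_map, atlas$whole_brain_labels)
}

#' Resample a volume through an affine transform onto a reference geometry
#'
#' Pull-back convention: `transform` maps world coordinates of the
#' *reference* grid into world coordinates of `vol`. Every output voxel
#' centre is mapped into `vol`; voxels landing outside the source field of
#' view are set to 0 and flagged in the returned volume's `oof` mask, which
#' downstream VOI statistics exclude.
#'
#' @param vol source [volume()].
#' @param transform an [affine_transform()] (reference world -> source world).
#' @param reference a [volume()] providing the output geometry.
#' @param mode `"linear"` or `"nearest"`.
#' @return A [volume()] on the reference geometry with an `oof` mask.
#' @export
resample_volume <- function(vol, transform, reference,
                            mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "pet_volume"), inherits(reference, "pet_volume"),
            inherits(transform, "affine_transform"))
  if (abs(det(transform$matrix[1:3, 1:3])) < 1e-12)
    stop("singular transform")
  M <- solve(vol$affine) %*% transform$matrix %*% reference$affine
  od <- vol_dim(reference)
  r <- cpp_resample_affine(vol$data, vol_dim(vol), od,
                           M[1:3, , drop = FALSE],
                           as.integer(mode == "nearest"))
  volume(array(r$data, dim = od), spacing = reference$spacing,
         affine = reference$affine, oof = array(r$oof, dim = od))
}

# Gaussian blur with sigma given in mm (isotropic or per-axis).
blur_volume <- function(vol, sigma_mm) {
  if (length(sigma_mm) == 1L) sigma_mm <- rep(sigma_mm, 3L)
  if (all(sigma_mm <= 0)) return(vol)
  out <- cpp_blur3d(vol$data, vol_dim(vol), sigma_mm / vol$spacing)
  volume(array(out, dim = vol_dim(vol)), spacing = vol$spacing,
         affine = vol$affine, oof = vol$oof)
}

# Block-mean pyramid downsampling by an integer factor; world geometry kept.
downsample_volume <- function(vol, factor) {
  if (factor == 1L) return(vol)
  f <- as.integer(rep(factor, 3L))
  r <- cpp_block_mean(vol$data, vol_dim(vol), f)
  od <- attr(r, "odim")
  idx_map <- diag(c(f, 1))
  idx_map[1:3, 4] <- (f - 1) / 2
  volume(array(as.numeric(r), dim = od), spacing = vol$spacing * f,
         affine = vol$affine %*% idx_map)
}
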