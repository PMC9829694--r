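#' 3-D image volume
#'
#' The basic data container: a 3-D scalar grid (PET activity in arbitrary
#' units or MBq/cm^3, or MR intensity) together with its voxel spacing and a
#' 4x4 affine mapping 0-based voxel indices, evaluated at voxel centres, to
#' world coordinates in mm.
#'
#' @param data 3-D numeric array; must be free of NaN/Inf.
#' @param spacing length-3 positive voxel size in mm. Defaults to 1 mm
#'   isotropic, or is derived from `affine` when that is given.
#' @param affine optional 4x4 voxel-index-to-world matrix; defaults to a
#'   diagonal map built from `spacing` with the first voxel centre at the
#'   world origin.
#' @param oof optional logical array of the same dimension flagging
#'   out-of-field voxels (produced by resampling; excluded from VOI
#'   statistics downstream).
#' @return An object of class `pet_volume`.
#' @export
volume <- function(data, spacing = NULL, affine = NULL, oof = NULL) {
  if (length(dim(data)) == 4L && dim(data)[4L] == 1L)
    data <- array(data, dim = dim(data)[1:3])
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array")
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    stop(sprintf("volume contains %d non-finite (NaN/Inf) voxels", nbad))
  if (is.null(affine)) {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    affine <- diag(c(spacing, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)) || any(abs(affine[4, ] - c(0, 0, 0, 1)) > 1e-9))
      stop("volume affine must be a 4x4 homogeneous matrix")
    if (is.null(spacing))
      spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel sizes in mm")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("volume affine is singular")
  if (!is.null(oof)) {
    stopifnot(is.logical(oof), all(dim(oof) == dim(data)))
  }
  structure(list(data = data, spacing = spacing, affine = affine, oof = oof),
            class = "pet_volume")
}

vol_dim <- function(vol) dim(vol$data)

# Index->world transform as an affine_transform object.
index_affine <- function(vol) affine_transform(vol$affine)

#' World coordinates of the geometric centre of a volume's field of view
#' @param vol a `pet_volume`.
#' @return length-3 world coordinates (mm).
#' @export
world_center <- function(vol) {
  d <- vol_dim(vol)
  as.numeric(apply_affine(index_affine(vol), (d - 1) / 2))
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(vol_dim(a) == vol_dim(b)) && max(abs(a$affine - b$affine)) < tol
}

#' Read a NIfTI volume
#'
#' Loads a 3-D (or single-frame 4-D) NIfTI-1 image. Spacing and the
#' voxel-to-world affine are taken from the header (sform/qform); data are
#' cast to double. Volumes containing NaN/Inf voxels are rejected with an
#' error naming the offending voxel count.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))   # drop RNifti's image pointer attrs
  storage.mode(a) <- "double"
  nd <- length(dim(a))
  if (nd == 4L) {
    if (dim(a)[4L] != 1L)
      stop("multi-frame 4-D NIfTI needs explicit frame selection: ", path)
    a <- array(a, dim = dim(a)[1:3])
  } else if (nd != 3L) {
    stop("expected a 3-D NIfTI payload, got ", nd, "-D: ", path)
  }
  xf <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  xf <- matrix(as.numeric(xf), 4L, 4L)
  # RNifti's world map is evaluated at 1-based indices minus one, i.e. it is
  # already the 0-based voxel-centre map used here.
  volume(a, spacing = RNifti::pixdim(img)[1:3], affine = xf)
}

#' Write a volume as NIfTI
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, `"float"` (default) or `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  stopifnot(inherits(vol, "pet_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- vol_dim(x)
  cat(sprintf("PET/MR volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]", min(x$data), max(x$data)))
  if (!is.null(x$oof)) cat(sprintf(", %d out-of-field voxels", sum(x$oof)))
  cat("\n")
  invisible(x)
}

#' Atlas region names used throughout the package
#'
#' The five largest atlas regions retained for analysis at PET resolution.
#' @return Character vector of the five region names.
#' @export
atlas_regions <- function() {
  c("gray_matter", "white_matter", "neocortex", "basal_forebrain",
    "olfactory_system")
}

#' Integer label atlas
#'
#' An integer-labelled grid on the [volume()] geometry contract plus the
#' label-to-region-name map. Label 0 is reserved for background and excluded
#' from the whole-brain VOI.
#'
#' @param labels a `pet_volume` whose data are non-negative integers, or a
#'   3-D integer array.
#' @param region_map named character vector mapping label ids (names) to
#'   region names; must cover every nonzero label present in the grid.
#' @param whole_brain_labels integer vector of labels forming the whole-brain
#'   VOI; defaults to all mapped labels. Must not contain 0.
#' @param spacing,affine forwarded to [volume()] when `labels` is an array.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, region_map, whole_brain_labels = NULL,
                        spacing = NULL, affine = NULL) {
  if (!inherits(labels, "pet_volume"))
    labels <- volume(labels, spacing = spacing, affine = affine)
  lab <- labels$data
  if (max(abs(lab - round(lab))) > 0 || min(lab) < 0)
    stop("atlas labels must be non-negative integers")
  present <- sort(unique(as.integer(lab)))
  present <- present[present != 0L]
  ids <- as.integer(names(region_map))
  if (anyNA(ids)) stop("region_map must be named by integer label ids")
  missing <- setdiff(present, ids)
  if (length(missing))
    stop("labels present in grid but absent from region_map: ",
         paste(missing, collapse = ", "))
  if (is.null(whole_brain_labels)) whole_brain_labels <- ids
  whole_brain_labels <- as.integer(whole_brain_labels)
  if (0L %in% whole_brain_labels)
    stop("background label 0 cannot be part of the whole-brain VOI")
  structure(list(labels = labels, region_map = region_map,
                 whole_brain_labels = whole_brain_labels),
            class = "label_atlas")
}

# label ids for a region name ("whole_brain" means the whole-brain set)
region_label_ids <- function(atlas, region) {
  if (identical(region, "whole_brain")) return(atlas$whole_brain_labels)
  ids <- as.integer(names(atlas$region_map)[atlas$region_map == region])
  if (!length(ids)) stop("unknown atlas region: ", region)
  ids
}

#' @export
print.label_atlas <- function(x, ...) {
  d <- vol_dim(x$labels)
  cat(sprintf("Label atlas: %d x %d x %d voxels, %d regions\n",
              d[1], d[2], d[3], length(x$region_map)))
  for (id in names(x$region_map)) {
    n <- sum(x$labels$data == as.integer(id))
    cat(sprintf("  %2s %-18s %7d voxels\n", id, x$region_map[[id]], n))
  }
  invisible(x)
}
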