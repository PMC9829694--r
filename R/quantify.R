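#' Regional uptake ratio (UR)
#'
#' The study's primary semi-quantitative readout: the measured radioactivity
#' in a target VOI divided by the measured radioactivity in the whole-brain
#' VOI. "Measured radioactivity" is read as the mean activity concentration
#' over the VOI's usable voxels (see `ur_mode = "sum"` for the literal
#' summed-counts reading, which depends on region volume). Voxels flagged
#' out-of-field by resampling are excluded from both numerator and
#' denominator. Because numerator and denominator share the scan's global
#' scale, UR is invariant to injected activity and body weight.
#'
#' @param scan atlas-space PET [volume()] (with an `oof` mask if resampled).
#' @param atlas the [label_atlas()] on the same geometry.
#' @param region one of the atlas region names, or `"whole_brain"`.
#' @param ur_mode `"mean"` (concentration ratio, default) or `"sum"` (total
#'   activity ratio).
#' @return A list of class `ur_record`: `region`, `ur`, `voxels_used`,
#'   `voxels_region`.
#' @export
compute_ur <- function(scan, atlas, region, ur_mode = c("mean", "sum")) {
  ur_mode <- match.arg(ur_mode)
  stopifnot(inherits(scan, "pet_volume"), inherits(atlas, "label_atlas"))
  if (!same_geometry(scan, atlas$labels))
    stop("scan and atlas are not on the same geometry")
  lab <- atlas$labels$data
  usable <- if (is.null(scan$oof)) rep(TRUE, length(lab)) else !scan$oof
  in_region <- array(lab %in% region_label_ids(atlas, region), dim = dim(lab))
  in_brain <- array(lab %in% atlas$whole_brain_labels, dim = dim(lab))
  reg_use <- in_region & usable
  brain_use <- in_brain & usable
  if (!any(brain_use)) stop("whole-brain VOI has no usable voxels")
  if (!any(reg_use))
    stop(sprintf("region '%s' has no usable voxels in this scan", region))
  agg <- if (ur_mode == "mean") mean else sum
  ur <- agg(scan$data[reg_use]) / agg(scan$data[brain_use])
  structure(list(region = region, ur = ur, voxels_used = sum(reg_use),
                 voxels_region = sum(in_region)),
            class = "ur_record")
}

#' Standardized uptake value (SUV)
#'
#' Radiotracer concentration (MBq/cm^3, equivalently per gram of tissue)
#' divided by the ratio of injected radioactivity (MBq) to body weight (g).
#' Computed alongside UR for comparison; unlike UR it inherits the variance
#' of dose and weight.
#'
#' @param scan atlas-space PET [volume()] in MBq/cm^3.
#' @param atlas the [label_atlas()].
#' @param region region name or `"whole_brain"`.
#' @param injected_MBq injected activity, MBq (> 0).
#' @param weight_g body weight, g (> 0).
#' @return A list of class `suv_record`: `region`, `suv`, `voxels_used`.
#' @export
compute_suv <- function(scan, atlas, region, injected_MBq, weight_g) {
  if (!is.finite(injected_MBq) || injected_MBq <= 0)
    stop("injected activity must be positive")
  if (!is.finite(weight_g) || weight_g <= 0)
    stop("body weight must be positive")
  rec <- compute_ur(scan, atlas, region, ur_mode = "mean")
  lab <- atlas$labels$data
  usable <- if (is.null(scan$oof)) rep(TRUE, length(lab)) else !scan$oof
  reg_use <- array(lab %in% region_label_ids(atlas, region), dim = dim(lab)) & usable
  conc <- mean(scan$data[reg_use])
  structure(list(region = region, suv = conc / (injected_MBq / weight_g),
                 voxels_used = rec$voxels_used),
            class = "suv_record")
}

#' Tabulate uptake ratios for a whole study
#'
#' Builds the long-format UR table for all animals, timepoints and regions
#' from the atlas-space scans produced by [align_study()]. Scans flagged by
#' the alignment (failed registration, corrupted input) yield explicit rows
#' with `ur = NA`, never silent zeros.
#'
#' @param aligned result of [align_study()] (or a named list of atlas-space
#'   volumes keyed by `scan_id` plus a `flagged` character vector).
#' @param atlas the [label_atlas()].
#' @param manifest study manifest data frame with columns `scan_id`,
#'   `animal_id`, `group`, `timepoint_h` (and optionally `injected_MBq`,
#'   `weight_g`).
#' @param regions regions to tabulate; whole brain is appended as a contract
#'   check (its UR is identically 1).
#' @param ur_mode forwarded to [compute_ur()].
#' @return Data frame: `scan_id`, `animal_id`, `group`, `timepoint_h`,
#'   `region`, `ur`, `voxels_used`. The per-scan regional mean concentrations
#'   it is built from are attached as attribute `"region_means"` (reused for
#'   SUV computation).
#' @export
tabulate_study <- function(aligned, atlas, manifest,
                           regions = c(atlas_regions(), "whole_brain"),
                           ur_mode = "mean") {
  vols <- if (!is.null(aligned$volumes)) aligned$volumes else aligned
  flagged <- if (!is.null(aligned$flagged)) aligned$flagged else character()
  orphans <- setdiff(manifest$scan_id, c(names(vols), flagged))
  extra <- setdiff(names(vols), manifest$scan_id)
  if (length(orphans) || length(extra))
    stop("manifest/scan mismatch; orphans: ",
         paste(c(orphans, extra), collapse = ", "))
  idx <- voi_indices(atlas, regions)
  nr <- length(regions)
  nrow_out <- nrow(manifest) * nr
  ur_col <- rep(NA_real_, nrow_out); vu_col <- rep(NA_integer_, nrow_out)
  mean_col <- rep(NA_real_, nrow_out)
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$scan_id[i]
    if (sid %in% flagged) next
    v <- vols[[sid]]
    usable <- if (is.null(v$oof)) NULL else !v$oof
    bidx <- idx$whole_brain
    if (!is.null(usable)) bidx <- bidx[usable[bidx]]
    if (!length(bidx)) stop("whole-brain VOI has no usable voxels: ", sid)
    bden <- if (ur_mode == "mean") mean(v$data[bidx]) else sum(v$data[bidx])
    for (j in seq_len(nr)) {
      ri <- idx[[regions[j]]]
      if (!is.null(usable)) ri <- ri[usable[ri]]
      if (!length(ri))
        stop(sprintf("region '%s' has no usable voxels in scan %s",
                     regions[j], sid))
      k <- (i - 1L) * nr + j
      rm <- mean(v$data[ri])
      mean_col[k] <- rm
      rnum <- if (ur_mode == "mean") rm else sum(v$data[ri])
      ur_col[k] <- rnum / bden
      vu_col[k] <- length(ri)
    }
  }
  out <- data.frame(
    scan_id = rep(manifest$scan_id, each = nr),
    animal_id = rep(manifest$animal_id, each = nr),
    group = rep(manifest$group, each = nr),
    timepoint_h = rep(manifest$timepoint_h, each = nr),
    region = rep(regions, times = nrow(manifest)),
    ur = ur_col, voxels_used = vu_col, stringsAsFactors = FALSE)
  attr(out, "flagged") <- flagged
  attr(out, "region_means") <- mean_col
  out
}

# voxel index vectors for each region VOI plus the whole-brain VOI
voi_indices <- function(atlas, regions) {
  lab <- as.integer(atlas$labels$data)
  idx <- lapply(stats::setNames(regions, regions), function(r)
    which(lab %in% region_label_ids(atlas, r)))
  idx$whole_brain <- which(lab %in% atlas$whole_brain_labels)
  idx
}
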