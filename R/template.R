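#' Build the control-group PET template
#'
#' Iterative group-average template construction from the sham control scans.
#' Each scan is first intensity-normalized by its whole-field mean. Iteration
#' 0 is the voxel-wise mean of the normalized scans resampled onto the first
#' scan's geometry; each subsequent iteration registers every scan to the
#' previous template ([register_affine()]), pulls it onto the template grid,
#' and re-averages. The template pose is anchored to the first scan: every
#' warp is composed with the inverse of the first scan's transform, so
#' iterating sharpens the average instead of drifting to a consensus pose.
#' Averaging is out-of-field aware: each voxel averages only the scans that
#' actually cover it. The result is renormalized so its voxel mean is 1.
#' The procedure is deterministic; the initial voxel-wise mean is invariant
#' to the order of the input scans.
#'
#' @param control_scans list of at least two [volume()] PET scans.
#' @param iterations number of register-and-average refinement iterations
#'   after the initial mean (default 2).
#' @param settings [reg_settings()] for the scan-to-template registrations
#'   (same-modality NCC by default).
#' @return The template [volume()], with the per-iteration scan transforms in
#'   attribute `"transforms"`.
#' @export
build_template <- function(control_scans, iterations = 2L,
                           settings = reg_settings(metric = "ncc")) {
  if (length(control_scans) < 2L)
    stop("template construction needs at least 2 control scans")
  stopifnot(all(vapply(control_scans, inherits, logical(1), "pet_volume")))
  norm <- lapply(control_scans, function(v) {
    m <- mean(v$data)
    if (m <= 0) stop("cannot normalize a scan with non-positive mean")
    v$data <- v$data / m
    v
  })
  ref <- norm[[1L]]
  onto_ref <- lapply(norm, function(v) {
    if (same_geometry(v, ref)) v
    else resample_volume(v, identity_affine(), ref, mode = "linear")
  })
  template <- average_volumes(onto_ref, ref)
  transforms <- NULL
  for (k in seq_len(iterations)) {
    transforms <- lapply(norm, function(v)
      register_affine(v, template, settings = settings)$transform)
    anchor <- invert_affine(transforms[[1L]])
    warped <- mapply(function(v, tr)
      resample_volume(v, compose_affine(tr, anchor), template, "linear"),
      norm, transforms, SIMPLIFY = FALSE)
    template <- average_volumes(warped, template)
  }
  template$data <- template$data / mean(template$data)
  attr(template, "transforms") <- transforms
  template
}

# voxel-wise mean over the scans covering each voxel (out-of-field aware)
average_volumes <- function(vols, ref) {
  acc <- array(0, dim = vol_dim(ref))
  cnt <- array(0, dim = vol_dim(ref))
  for (v in vols) {
    usable <- if (is.null(v$oof)) 1 else !v$oof
    acc <- acc + v$data * usable
    cnt <- cnt + usable
  }
  out <- acc / pmax(cnt, 1)
  volume(out, spacing = ref$spacing, affine = ref$affine)
}

#' Align every study scan into atlas space
#'
#' The two-stage alignment chain: every PET scan is registered to the
#' control-group template (same-modality NCC); the template is co-registered
#' with the MR dataset once ([coregister_template_to_mr()], two passes by
#' default); and the composed transform carries each scan into atlas space by
#' pull-back, emitting a per-scan out-of-field mask. A scan whose
#' registration fails (e.g. an all-zero corrupted volume) is flagged and
#' excluded from quantification rather than aborting the study.
#'
#' @param volumes named list of PET [volume()]s keyed by `scan_id`.
#' @param template the [build_template()] output.
#' @param mr MR volume at PET resolution.
#' @param atlas [label_atlas()] on the MR geometry; provides the output grid.
#' @param settings [reg_settings()] for scan-to-template registration.
#' @param mr_settings [reg_settings()] for the cross-modality stage.
#' @param passes template-to-MR refinement passes.
#' @return A list of class `study_alignment`: `volumes` (atlas-space scans
#'   with `oof` masks), `transforms` (per-scan composite atlas-world to
#'   scan-world maps), `scan_to_template`, `template_to_mr`, `flagged`
#'   (scan ids excluded, with reasons in `flag_reasons`).
#' @export
align_study <- function(volumes, template, mr, atlas,
                        settings = reg_settings(metric = "ncc"),
                        mr_settings = reg_settings(metric = "nmi"),
                        passes = 2L) {
  stopifnot(inherits(atlas, "label_atlas"))
  t_mr <- coregister_template_to_mr(template, mr, passes = passes,
                                    settings = mr_settings)
  ref <- atlas$labels
  out_vols <- list(); scan_tr <- list(); comp_tr <- list()
  flagged <- character(); reasons <- character()
  for (sid in names(volumes)) {
    res <- tryCatch(register_affine(volumes[[sid]], template,
                                    settings = settings),
                    error = function(e) e)
    if (inherits(res, "error")) {
      flagged <- c(flagged, sid)
      reasons <- c(reasons, conditionMessage(res))
      next
    }
    composite <- compose_affine(res$transform, t_mr$transform)
    scan_tr[[sid]] <- res$transform
    comp_tr[[sid]] <- composite
    out_vols[[sid]] <- resample_volume(volumes[[sid]], composite, ref,
                                       mode = "linear")
  }
  structure(list(volumes = out_vols, transforms = comp_tr,
                 scan_to_template = scan_tr, template_to_mr = t_mr$transform,
                 flagged = flagged, flag_reasons = reasons),
            class = "study_alignment")
}

#' @export
print.study_alignment <- function(x, ...) {
  cat(sprintf("Study alignment: %d scans in atlas space, %d flagged\n",
              length(x$volumes), length(x$flagged)))
  if (length(x$flagged))
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
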