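#' Run the full uptake-ratio analysis on a study
#'
#' The end-to-end pipeline: resize the MR/atlas pair to PET resolution (when
#' it is finer), build the control-group PET template from the sham scans at
#' the first timepoint, align every scan into atlas space via the template,
#' tabulate regional uptake ratios, and run the serial Mann-Whitney
#' comparisons. Returns a single classed result object with print, summary
#' and plot methods.
#'
#' @param manifest study manifest data frame (`scan_id`, `animal_id`,
#'   `group`, `timepoint_h`, optionally `injected_MBq`, `weight_g`).
#' @param volumes named list of PET [volume()]s keyed by `scan_id`.
#' @param mr structural MR [volume()].
#' @param atlas [label_atlas()] on the MR geometry.
#' @param mr_scale factor by which to resize the MR/atlas pair to PET
#'   resolution (e.g. 1/20 for the production atlas); `NULL` derives it from
#'   the MR-to-PET spacing ratio, 1 leaves the pair untouched.
#' @param template_iterations refinement iterations for [build_template()].
#' @param template_group,template_timepoint which scans feed the template:
#'   by default the sham group at the earliest timepoint.
#' @param alpha significance level for adjusted p-values.
#' @param m_between,m_within Bonferroni family sizes (serial measurements).
#' @param ur_mode UR aggregation, `"mean"` or `"sum"`.
#' @param settings,mr_settings,passes forwarded to [align_study()]. The
#'   pipeline defaults are the desk-scale profile: same-modality NCC with a
#'   two-level pyramid, stride-2 metric sampling, centroid initialization
#'   and nine degrees of freedom (the scanner repositioning a registration
#'   has to undo is rigid plus a modest scale); the cross-modality stage
#'   uses overlap-invariant NMI.
#' @return An object of class `ur_study`: fields `template`, `alignment`,
#'   `ur_table`, `comparisons`, `suv_table`, `atlas`, `manifest`.
#' @export
run_study <- function(manifest, volumes, mr, atlas,
                      mr_scale = NULL,
                      template_iterations = 2L,
                      template_group = "sham",
                      template_timepoint = NULL,
                      alpha = 0.05, m_between = 4, m_within = 6,
                      ur_mode = "mean",
                      settings = reg_settings(metric = "ncc",
                                              dof = "similarity",
                                              pyramid = c(4L, 2L),
                                              stride = 2L,
                                              max_iter = 30L,
                                              reltol = 1e-5,
                                              centroid_init = TRUE),
                      mr_settings = reg_settings(metric = "nmi",
                                                 dof = "similarity",
                                                 pyramid = c(4L, 2L),
                                                 stride = c(1L, 2L),
                                                 max_iter = 40L,
                                                 reltol = 1e-5),
                      passes = 2L) {
  stopifnot(is.data.frame(manifest),
            all(c("scan_id", "animal_id", "group", "timepoint_h")
                %in% names(manifest)))
  pet_spacing <- volumes[[1L]]$spacing
  if (is.null(mr_scale)) {
    mr_scale <- min(1, mean(mr$spacing / pet_spacing))
  }
  if (mr_scale < 1) {
    mr <- resize_volume(mr, mr_scale, mode = "linear")
    atlas <- resize_atlas(atlas, mr_scale)
  }
  if (is.null(template_timepoint))
    template_timepoint <- min(manifest$timepoint_h)
  ctrl_ids <- manifest$scan_id[manifest$group == template_group &
                                 manifest$timepoint_h == template_timepoint]
  if (length(ctrl_ids) < 2L)
    stop("fewer than 2 control scans available for template construction")
  template <- build_template(volumes[ctrl_ids],
                             iterations = template_iterations,
                             settings = settings)
  alignment <- align_study(volumes, template, mr, atlas,
                           settings = settings, mr_settings = mr_settings,
                           passes = passes)
  ur_table <- tabulate_study(alignment, atlas, manifest, ur_mode = ur_mode)
  comparisons <- run_serial_comparisons(ur_table, alpha = alpha,
                                        m_between = m_between,
                                        m_within = m_within)
  suv_table <- NULL
  if (all(c("injected_MBq", "weight_g") %in% names(manifest))) {
    # SUV from the same regional concentration means the UR table used
    suv_table <- ur_table[ur_table$region != "whole_brain",
                          c("scan_id", "animal_id", "group", "timepoint_h",
                            "region")]
    conc <- attr(ur_table, "region_means")[ur_table$region != "whole_brain"]
    m <- match(suv_table$scan_id, manifest$scan_id)
    suv_table$suv <- conc / (manifest$injected_MBq[m] / manifest$weight_g[m])
    suv_table <- suv_table[!is.na(suv_table$suv), , drop = FALSE]
    rownames(suv_table) <- NULL
  }
  structure(list(template = template, alignment = alignment,
                 ur_table = ur_table, comparisons = comparisons,
                 suv_table = suv_table, atlas = atlas, manifest = manifest,
                 alpha = alpha),
            class = "ur_study")
}

#' @export
print.ur_study <- function(x, ...) {
  cat(sprintf("Uptake-ratio study: %d scans (%d flagged), %d animals, %d timepoints\n",
              nrow(x$manifest), length(x$alignment$flagged),
              length(unique(x$manifest$animal_id)),
              length(unique(x$manifest$timepoint_h))))
  sig <- x$comparisons[x$comparisons$significant &
                         x$comparisons$comparison == "between_groups", ]
  cat(sprintf("%d of %d between-group comparisons significant at adjusted p <= %g\n",
              nrow(sig), sum(x$comparisons$comparison == "between_groups"),
              x$alpha))
  invisible(x)
}

#' @export
summary.ur_study <- function(object, ...) {
  ur <- object$ur_table
  ur <- ur[!is.na(ur$ur) & ur$region != "whole_brain", ]
  agg <- stats::aggregate(ur ~ region + group + timepoint_h, data = ur,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(agg[1:3], ur_mean = agg$ur[, "mean"], ur_sd = agg$ur[, "sd"])
  out <- out[order(out$region, out$timepoint_h, out$group), ]
  rownames(out) <- NULL
  structure(list(group_means = out, comparisons = object$comparisons,
                 flagged = object$alignment$flagged),
            class = "summary.ur_study")
}

#' @export
print.summary.ur_study <- function(x, ...) {
  cat("Group mean uptake ratios:\n")
  print(x$group_means, digits = 4)
  cat("\n")
  print(x$comparisons)
  invisible(x)
}

#' @export
#' @rdname render_ur_plots
plot.ur_study <- function(x, region = atlas_regions()[1], ...) {
  plot_region_ur(x$ur_table, x$comparisons, region, ...)
  invisible(x)
}
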