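#' Run the pipeline from a YAML configuration
#'
#' Configuration-driven end-to-end run: simulate (or load) the study, build
#' the template, align, quantify, test, and write every artifact — template
#' NIfTI, transform JSON sidecars, UR and comparison CSV tables, figures and
#' a log — into the output directory. Reruns with the same configuration and
#' seed are byte-identical in all CSV/JSON outputs.
#'
#' The config has a `study:` section holding either `phantom:` (any
#' [phantom_spec()] argument) or `data:` (paths `manifest`, `mr`, `atlas`,
#' plus `region_map` and optional `mr_scale`), an optional `analysis:`
#' section ([run_study()] arguments: `template_iterations`, `alpha`,
#' `m_between`, `m_within`, `ur_mode`, `passes`), and an optional `report:`
#' section (`overlays`, `plots`, `upscale`).
#'
#' @param config path to the YAML configuration, or an equivalent list.
#' @param seed integer seed for every source of randomness.
#' @param out_dir output directory (created if absent).
#' @return The [run_study()] result, invisibly, with `out_dir` attached.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = "urpet_out") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  bad <- setdiff(names(cfg), c("study", "analysis", "report"))
  if (length(bad) || is.null(cfg$study))
    stop("invalid config: ", if (length(bad))
      paste("unknown keys:", paste(bad, collapse = ", "))
      else "missing 'study' section")
  # full schema validation before any output is created
  if (!is.null(cfg$study$phantom)) {
    bad <- setdiff(names(cfg$study$phantom), names(formals(phantom_spec)))
    if (length(bad))
      stop("invalid config: unknown phantom keys: ", paste(bad, collapse = ", "))
  } else if (!is.null(cfg$study$data)) {
    missing <- setdiff(c("manifest", "mr", "atlas", "region_map"),
                       names(cfg$study$data))
    if (length(missing))
      stop("invalid config: missing data keys: ", paste(missing, collapse = ", "))
  } else {
    stop("invalid config: study section needs either 'phantom' or 'data'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }

  if (!is.null(cfg$study$phantom)) {
    ph <- cfg$study$phantom
    ph$seed <- as.integer(seed)
    if (!is.null(ph$dims)) ph$dims <- as.integer(ph$dims)
    spec <- do.call(phantom_spec, ph)
    log("simulating phantom study (%s grid, %d/group, seed %d)",
        paste(spec$dims, collapse = "x"), spec$n_per_group, seed)
    aset <- make_atlas(spec)
    study <- simulate_study(aset, spec)
    manifest <- study$manifest
    volumes <- study$volumes
    mr <- aset$mr
    atlas <- aset$atlas
    mr_scale <- NULL
    gt_path <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(lapply(study$ground_truth, function(g)
      list(transform = as.vector(t(g$transform$matrix)),
           global_scale = g$global_scale, ur = as.list(g$ur))),
      gt_path, auto_unbox = TRUE, digits = NA)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  } else {
    dat <- cfg$study$data
    manifest <- utils::read.csv(dat$manifest, stringsAsFactors = FALSE)
    if (!"scan_id" %in% names(manifest))
      manifest$scan_id <- sprintf("%s_t%g", manifest$animal_id,
                                  manifest$timepoint_h)
    volumes <- lapply(stats::setNames(manifest$path, manifest$scan_id),
                      read_volume)
    mr <- read_volume(dat$mr)
    labels <- read_volume(dat$atlas)
    rm_map <- unlist(dat$region_map)
    atlas <- label_atlas(labels, stats::setNames(as.character(rm_map),
                                                 names(rm_map)))
    mr_scale <- dat$mr_scale
    log("loaded study: %d scans from %s", nrow(manifest), dat$manifest)
  }

  an <- cfg$analysis
  if (is.null(an)) an <- list()
  log("building template and aligning %d scans", length(volumes))
  fit <- run_study(manifest, volumes, mr, atlas,
                   mr_scale = mr_scale,
                   template_iterations = an$template_iterations %||% 2L,
                   alpha = an$alpha %||% 0.05,
                   m_between = an$m_between %||% 4,
                   m_within = an$m_within %||% 6,
                   ur_mode = an$ur_mode %||% "mean",
                   passes = an$passes %||% 2L)
  log("alignment complete: %d flagged scans", length(fit$alignment$flagged))

  write_volume(fit$template, file.path(out_dir, "template.nii.gz"))
  jsonlite::write_json(
    lapply(fit$alignment$transforms, function(t) as.vector(t(t$matrix))),
    file.path(out_dir, "transforms.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$ur_table, file.path(out_dir, "ur_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$comparisons),
                   file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  if (!is.null(fit$suv_table))
    utils::write.csv(fit$suv_table, file.path(out_dir, "suv_table.csv"),
                     row.names = FALSE)

  rep_cfg <- cfg$report
  if (is.null(rep_cfg)) rep_cfg <- list()
  if (isTRUE(rep_cfg$plots %||% TRUE)) {
    render_ur_plots(fit$ur_table, fit$comparisons,
                    file.path(out_dir, "figures"))
    log("wrote UR figures")
  }
  if (isTRUE(rep_cfg$overlays %||% TRUE)) {
    figdir <- file.path(out_dir, "figures")
    dir.create(figdir, recursive = TRUE, showWarnings = FALSE)
    atlas_tpl <- fit$atlas
    ratio <- vol_dim(fit$template) / vol_dim(mr)
    mr_tpl <- if (all(ratio < 1)) resize_volume(mr, ratio) else mr
    up <- rep_cfg$upscale %||% 20L
    if (all(vol_dim(mr_tpl) == vol_dim(fit$template))) {
      render_overlay(fit$template, mr_tpl,
                     file.path(figdir, "overlay_mr.png"), upscale = up)
      for (r in atlas_regions())
        render_overlay(fit$template, atlas_tpl,
                       file.path(figdir, sprintf("overlay_%s.png", r)),
                       region = r, upscale = up)
      log("wrote fusion overlays")
    }
  }
  log("pipeline finished")
  attr(fit, "out_dir") <- out_dir
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
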