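#' Fusion overlay of the PET template and an anatomical selection
#'
#' Orthogonal-slice montage: the PET template in gray with the selected
#' anatomy (the MR image, or one atlas region) as an intensity-rescaled
#' single-colour highlight, the merged-image display convention of the
#' analysis tool. For display the slices are enlarged by the reciprocal of
#' the analysis scale factor.
#'
#' @param template PET template [volume()].
#' @param anatomy an MR [volume()] on the same geometry, or a
#'   [label_atlas()] together with `region`.
#' @param path output PNG path.
#' @param region when `anatomy` is a [label_atlas()], which region to
#'   highlight (or `"whole_brain"`).
#' @param upscale integer display enlargement factor (reciprocal of the
#'   analysis scale factor; default 20).
#' @param color highlight colour.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(template, anatomy, path, region = NULL,
                           upscale = 20L, color = "red") {
  stopifnot(inherits(template, "pet_volume"))
  if (inherits(anatomy, "label_atlas")) {
    if (is.null(region)) stop("a region must be named for an atlas overlay")
    ids <- region_label_ids(anatomy, region)
    overlay <- array(as.numeric(anatomy$labels$data %in% ids),
                     dim = vol_dim(anatomy$labels))
    overlay <- volume(overlay, spacing = anatomy$labels$spacing,
                      affine = anatomy$labels$affine)
    if (max(overlay$data) == 0)
      stop("empty region selection: ", region)
  } else {
    stopifnot(inherits(anatomy, "pet_volume"))
    overlay <- anatomy
  }
  if (!all(vol_dim(overlay) == vol_dim(template)))
    stop("template and anatomy geometries do not match")
  d <- vol_dim(template)
  mids <- pmax(1L, d %/% 2L)
  rescale <- function(m) {
    rng <- range(m)
    if (diff(rng) == 0) return(m * 0)
    (m - rng[1]) / diff(rng)
  }
  rgb_col <- grDevices::col2rgb(color)[, 1] / 255
  slices <- list(template$data[mids[1], , ], template$data[, mids[2], ],
                 template$data[, , mids[3]])
  oslices <- list(overlay$data[mids[1], , ], overlay$data[, mids[2], ],
                  overlay$data[, , mids[3]])
  panels <- lapply(seq_along(slices), function(i) {
    g <- rescale(slices[[i]])
    o <- rescale(oslices[[i]])
    arr <- array(0, dim = c(dim(g), 3L))
    for (ch in 1:3)
      arr[, , ch] <- pmin(1, g * (1 - 0.6 * o) + rgb_col[ch] * o)
    upscale_panel(arr, upscale)
  })
  h <- max(vapply(panels, function(p) dim(p)[2], integer(1)))
  w <- sum(vapply(panels, function(p) dim(p)[1], integer(1)))
  canvas <- array(0, dim = c(h, w, 3L))
  x0 <- 0L
  for (p in panels) {
    pw <- dim(p)[1]; ph <- dim(p)[2]
    # transpose to raster rows, origin top-left
    for (ch in 1:3)
      canvas[seq_len(ph), x0 + seq_len(pw), ch] <- t(p[, ph:1, ch])
    x0 <- x0 + pw
  }
  png::writePNG(canvas, path)
  invisible(path)
}

# nearest-neighbour integer upscaling of an (x, y, 3) panel for display
upscale_panel <- function(arr, f) {
  f <- max(1L, as.integer(f))
  if (f == 1L) return(arr)
  arr[rep(seq_len(dim(arr)[1]), each = f),
      rep(seq_len(dim(arr)[2]), each = f), , drop = FALSE]
}

# stable per-animal colours across all figures
animal_colors <- function(animal_ids) {
  ids <- sort(unique(animal_ids))
  stats::setNames(grDevices::hcl.colors(length(ids), "Dark 3"), ids)
}

#' Per-region UR scatter plots and group time course
#'
#' `plot_region_ur()` draws the per-animal uptake-ratio values for one region
#' across the serial measurements, each animal in its own stable colour, with
#' the between-group significance stars above each timepoint.
#' `plot_time_course()` draws group-mean UR (test group vs controls) across
#' the measurements. `render_ur_plots()` writes the full figure set (one PNG
#' per region plus the time-course figure) to a directory.
#'
#' @param ur_table UR table from [tabulate_study()].
#' @param comparisons result of [run_serial_comparisons()].
#' @param region region name.
#' @param ... further arguments passed to [graphics::plot()].
#' @return The plotted object or (for `render_ur_plots`) the written paths,
#'   invisibly.
#' @export
plot_region_ur <- function(ur_table, comparisons, region, ...) {
  tab <- ur_table[ur_table$region == region & !is.na(ur_table$ur), ]
  if (!nrow(tab)) stop("no UR values for region ", region)
  tps <- sort(unique(tab$timepoint_h))
  cols <- animal_colors(ur_table$animal_id)
  xpos <- match(tab$timepoint_h, tps)
  pchs <- ifelse(tab$group == "SAH", 17, 16)
  ylim <- range(tab$ur) + c(-0.05, 0.12) * diff(range(tab$ur) + c(0, 1e-9))
  graphics::plot(jitter_group(xpos, tab$group), tab$ur, col = cols[tab$animal_id],
                 pch = pchs, xaxt = "n", xlab = "measurement",
                 ylab = "uptake ratio", ylim = ylim,
                 main = gsub("_", " ", region), ...)
  graphics::axis(1, at = seq_along(tps),
                 labels = sprintf("%g h", tps))
  cmp <- comparisons[comparisons$region == region &
                       comparisons$comparison == "between_groups", ]
  for (i in seq_along(tps)) {
    star <- cmp$stars[cmp$timepoint_a == tps[i]]
    if (length(star) == 1L && nzchar(star))
      graphics::text(i, ylim[2], star, cex = 1.4)
  }
  graphics::legend("bottomright", legend = c("SAH", "sham"), pch = c(17, 16),
                   bty = "n", cex = 0.8)
  invisible(tab)
}

jitter_group <- function(x, group) x + ifelse(group == "SAH", 0.12, -0.12)

#' @rdname plot_region_ur
#' @param regions regions for the time-course panel (default the two largest).
#' @export
plot_time_course <- function(ur_table, comparisons,
                             regions = c("gray_matter", "white_matter"), ...) {
  old <- graphics::par(mfrow = c(length(regions), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (region in regions) {
    tab <- ur_table[ur_table$region == region & !is.na(ur_table$ur), ]
    tps <- sort(unique(tab$timepoint_h))
    agg <- stats::aggregate(ur ~ group + timepoint_h, data = tab, FUN = mean)
    ylim <- range(agg$ur) + c(-0.1, 0.1) * diff(range(agg$ur) + 1e-9)
    graphics::plot(NA, xlim = c(1, length(tps)), ylim = ylim, xaxt = "n",
                   xlab = "measurement", ylab = "mean UR",
                   main = gsub("_", " ", region), ...)
    graphics::axis(1, at = seq_along(tps), labels = sprintf("%g h", tps))
    for (g in unique(agg$group)) {
      a <- agg[agg$group == g, ]
      a <- a[order(a$timepoint_h), ]
      graphics::lines(match(a$timepoint_h, tps), a$ur,
                      col = if (g == "SAH") "red" else "darkgreen",
                      type = "b", pch = 16)
    }
    graphics::legend("topright", legend = c("SAH", "sham"), bty = "n",
                     col = c("red", "darkgreen"), lty = 1, cex = 0.8)
  }
  invisible(NULL)
}

#' @rdname plot_region_ur
#' @param dir output directory for the PNG files.
#' @param regions_set regions to plot (default the five analysis regions).
#' @export
render_ur_plots <- function(ur_table, comparisons, dir,
                            regions_set = atlas_regions()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (region in regions_set) {
    p <- file.path(dir, sprintf("ur_%s.png", region))
    grDevices::png(p, width = 720, height = 540)
    plot_region_ur(ur_table, comparisons, region)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  p <- file.path(dir, "time_course.png")
  grDevices::png(p, width = 720, height = 720)
  plot_time_course(ur_table, comparisons)
  grDevices::dev.off()
  invisible(c(paths, p))
}
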