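#' Between-group and within-group serial comparisons
#'
#' Runs the study's statistical evaluation on a long-format uptake-ratio
#' table: for every region, (a) SAH vs sham at each timepoint, and (b) all
#' pairwise timepoint comparisons within each group. All tests are two-sided
#' Mann-Whitney U tests ([mann_whitney_u()]); p-values are Bonferroni
#' adjusted for the serial measurements — family size `m_between` (default 4,
#' the number of serial between-group tests per region) for (a) and
#' `m_within` (default 6, all timepoint pairs) for (b). Star codes follow the
#' 0.05 / 0.01 / 0.001 convention applied to adjusted p-values.
#'
#' Cells with fewer than two animals are skipped and recorded in the
#' `skipped` attribute rather than tested.
#'
#' @param ur_table data frame with columns `animal_id`, `group`,
#'   `timepoint_h`, `region`, `ur` (as produced by [tabulate_study()]).
#' @param alpha significance threshold applied to adjusted p-values.
#' @param regions regions to test; defaults to the five analysis regions.
#' @param m_between,m_within Bonferroni family sizes; `NULL` means "number of
#'   comparisons actually performed in the family".
#' @param groups the two group labels, test group first.
#' @param mode forwarded to [mann_whitney_u()].
#' @return A data frame of class `ur_comparisons` with one row per test:
#'   `region`, `comparison` (`"between_groups"` or `"within_group"`),
#'   `group`, `timepoint_a`, `timepoint_b`, `n1`, `n2`, `u`, `p_raw`,
#'   `p_adjusted`, `stars`, `significant`.
#' @export
run_serial_comparisons <- function(ur_table, alpha = 0.05,
                                   regions = atlas_regions(),
                                   m_between = 4, m_within = 6,
                                   groups = c("SAH", "sham"),
                                   mode = "auto") {
  stopifnot(all(c("animal_id", "group", "timepoint_h", "region", "ur")
                %in% names(ur_table)))
  ur_table <- ur_table[!is.na(ur_table$ur), , drop = FALSE]
  tps <- sort(unique(ur_table$timepoint_h))
  rows <- list()
  skipped <- character()
  cell <- function(region, group, tp) {
    ur_table$ur[ur_table$region == region & ur_table$group == group &
                  ur_table$timepoint_h == tp]
  }
  mb <- if (is.null(m_between)) length(tps) else m_between
  mw <- if (is.null(m_within)) choose(length(tps), 2) else m_within

  for (region in regions) {
    for (tp in tps) {
      x <- cell(region, groups[1], tp)
      y <- cell(region, groups[2], tp)
      if (length(x) < 2L || length(y) < 2L) {
        skipped <- c(skipped, sprintf("between_groups %s t=%gh (n=%d vs %d)",
                                      region, tp, length(x), length(y)))
        next
      }
      t <- mann_whitney_u(x, y, mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, comparison = "between_groups", group = NA_character_,
        timepoint_a = tp, timepoint_b = NA_real_,
        n1 = t$n1, n2 = t$n2, u = t$u, p_raw = t$p,
        p_adjusted = bonferroni(t$p, mb), stringsAsFactors = FALSE)
    }
    for (g in groups) {
      if (length(tps) < 2L) break
      pairs <- utils::combn(tps, 2L)
      for (j in seq_len(ncol(pairs))) {
        x <- cell(region, g, pairs[1L, j])
        y <- cell(region, g, pairs[2L, j])
        if (length(x) < 2L || length(y) < 2L) {
          skipped <- c(skipped,
                       sprintf("within_group %s %s t=%gh vs t=%gh (n=%d vs %d)",
                               region, g, pairs[1L, j], pairs[2L, j],
                               length(x), length(y)))
          next
        }
        t <- mann_whitney_u(x, y, mode = mode)
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, comparison = "within_group", group = g,
          timepoint_a = pairs[1L, j], timepoint_b = pairs[2L, j],
          n1 = t$n1, n2 = t$n2, u = t$u, p_raw = t$p,
          p_adjusted = bonferroni(t$p, mw), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  if (nrow(out)) {
    out$stars <- p_stars(out$p_adjusted)
    out$significant <- out$p_adjusted <= alpha
  }
  attr(out, "alpha") <- alpha
  attr(out, "skipped") <- skipped
  class(out) <- c("ur_comparisons", "data.frame")
  out
}

#' @export
print.ur_comparisons <- function(x, ...) {
  cat(sprintf("Serial Mann-Whitney comparisons: %d tests, %d significant at adjusted p <= %g\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  sk <- attr(x, "skipped")
  if (length(sk)) cat(sprintf("  (%d comparisons skipped for n < 2)\n", length(sk)))
  print.data.frame(x, digits = 4)
  invisible(x)
}
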