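# synthetic long-format UR table with a controllable group effect
make_ur_table <- function(n = 7, tps = c(3, 24, 96, 168),
                          regions = atlas_regions(), effect = list(),
                          cv = 0.07, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in c("SAH", "sham")) {
    for (a in seq_len(n)) {
      id <- sprintf("%s%02d", g, a)
      for (tp in tps) {
        for (r in regions) {
          mult <- if (g == "SAH" && !is.null(effect[[r]])) effect[[r]] else 1
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = id, group = g, timepoint_h = tp, region = r,
            ur = mult * exp(rnorm(1, 0, cv)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

test_that("comparison cardinality matches the study design", {
  tab <- make_ur_table()
  cmp <- run_serial_comparisons(tab)
  bg <- cmp[cmp$comparison == "between_groups", ]
  expect_equal(nrow(bg), 5 * 4)                       # regions x timepoints
  wg <- cmp[cmp$comparison == "within_group", ]
  expect_equal(nrow(wg), 5 * 2 * choose(4, 2))        # regions x groups x pairs
  expect_true(all(bg$n1 == 7 & bg$n2 == 7))
  # stars must be consistent with the adjusted p-values
  expect_identical(cmp$stars, p_stars(cmp$p_adjusted))
  expect_identical(cmp$significant, cmp$p_adjusted <= 0.05)
})

test_that("a strong region effect is detected and adjusted correctly", {
  tab <- make_ur_table(effect = list(gray_matter = 1.5), seed = 7)
  cmp <- run_serial_comparisons(tab)
  bg <- cmp[cmp$comparison == "between_groups" & cmp$region == "gray_matter", ]
  expect_true(all(bg$significant))
  expect_equal(bg$p_adjusted, pmin(1, 4 * bg$p_raw))
  wg <- cmp[cmp$comparison == "within_group", ]
  expect_equal(wg$p_adjusted, pmin(1, 6 * wg$p_raw))
})

test_that("cells with fewer than two animals are skipped and logged", {
  tab <- make_ur_table(n = 3)
  tab <- tab[!(tab$group == "SAH" & tab$timepoint_h == 96 &
                 tab$animal_id %in% c("SAH01", "SAH02")), ]
  cmp <- run_serial_comparisons(tab)
  sk <- attr(cmp, "skipped")
  expect_true(length(sk) > 0)
  expect_true(any(grepl("t=96h", sk)))
  bg <- cmp[cmp$comparison == "between_groups", ]
  expect_equal(nrow(bg), 5 * 3)      # the 96 h column is gone everywhere
})

test_that("family sizes can be derived from the design", {
  tab <- make_ur_table(tps = c(3, 24))
  cmp <- run_serial_comparisons(tab, m_between = NULL, m_within = NULL)
  bg <- cmp[cmp$comparison == "between_groups", ]
  expect_equal(bg$p_adjusted, pmin(1, 2 * bg$p_raw))   # two timepoints
  wg <- cmp[cmp$comparison == "within_group", ]
  expect_equal(wg$p_adjusted, pmin(1, 1 * wg$p_raw))   # one pair
})

test_that("null tables rarely reach adjusted significance", {
  # small Monte-Carlo of the family-wise error over regions (fixed seeds)
  hits <- 0L
  reps <- 60L
  for (s in seq_len(reps)) {
    tab <- make_ur_table(regions = "gray_matter", seed = 1000 + s)
    cmp <- run_serial_comparisons(tab, regions = "gray_matter")
    bg <- cmp[cmp$comparison == "between_groups", ]
    if (any(bg$significant)) hits <- hits + 1L
  }
  # Bonferroni-adjusted over 4 serial tests: family-wise error stays near
  # or below the nominal 5%
  expect_lte(hits / reps, 0.07)
})
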