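test_that("cell-mode tabulation reconstructs the published cohort staircase exactly", {
  sch <- design_schedule()
  ct <- count_tables(mhas_wave_counts(), sch, mode = "cells")
  ref <- mhas_cohort_counts()
  expect_identical(dim(ct$cohort_by_age), dim(ref))
  expect_true(all(ct$cohort_by_age == ref))
  # headline totals: cohort 9 is the largest, cohort 1 the smallest
  expect_equal(sum(ct$cohort_by_age["9", ]), 10220)
  expect_equal(sum(ct$cohort_by_age["12", ]), 3123)
  expect_equal(ct$cohort_by_age["12", "52"] + ct$cohort_by_age["12", "55"], 1663 + 1460)
  expect_equal(sum(ct$cohort_by_age["1", ]), 11)
  # conservation: both margins tally every observation exactly once
  expect_equal(sum(ct$cohort_by_age), sum(ct$wave_by_age))
  expect_equal(sum(ct$wave_by_age), 52451)
})

test_that("rearrange places wave records on the cohort diagonal", {
  # one person entering 2001 at age 51, observed in all four waves
  panel <- data.frame(person_id = "A", wave_year = c(2001, 2003, 2012, 2015),
                      age = c(51, 53, 62, 65), sex = 1)
  for (j in 1:9) panel[[paste0("marker_", j)]] <- 1
  ald <- rearrange(panel, design_schedule())
  t_obs <- which(colSums(matrix(ald$observed[1, ], nrow = 10)) > 0)
  expect_identical(t_obs, c(1L, 2L, 4L, 5L))
  expect_identical(ald$cohort, 9L)
  expect_identical(ald$group, "G2")
})

test_that("rearrange validates its inputs", {
  panel <- data.frame(person_id = c("A", "A"), wave_year = c(2001, 2001),
                      age = c(51, 51), sex = 1)
  for (j in 1:9) panel[[paste0("marker_", j)]] <- 0
  expect_error(rearrange(panel), "duplicate")
  panel2 <- panel; panel2$wave_year <- c(2001, 2003); panel2$age <- c(49, 51)
  expect_error(rearrange(panel2), "age < 50")
  panel3 <- panel; panel3$wave_year <- c(2001, 2003); panel3$age <- c(51, 58)
  expect_error(rearrange(panel3), "inconsistent ages")
})

test_that("zero-attrition cohort-9 persons get exactly four observed time points", {
  cfg <- synthetic_config(n_baseline = 500, n_refresh = 0, attrition_hazard = 0, seed = 9)
  pop <- generate_population(cfg)
  ald <- rearrange(pop$panel, design_schedule())
  n_t <- apply(ald$observed, 1, function(r) sum(colSums(matrix(r, nrow = 10)) > 0))
  expect_true(all(n_t[ald$cohort == 9] == 4))
  # cohorts 1-4 (baseline columns 6-9) age out before completing four waves
  expect_true(all(n_t[ald$cohort <= 4] < 4))
})

test_that("rearrangement and tabulation agree, and the round trip conserves counts", {
  x <- small_ald()
  sch <- design_schedule()
  ct <- count_tables(x$pop$panel, sch)
  # per-person observed time points re-tabulated from the rearranged array
  obs_t <- apply(x$ald$observed, 1, function(r) colSums(matrix(r, nrow = 10)) > 0)
  cohort_by_col <- matrix(0, 12, 9, dimnames = list(12:1, sch$nominal_ages))
  for (t in 1:9) {
    tab <- table(factor(x$ald$cohort[obs_t[t, ]], levels = 12:1))
    cohort_by_col[, t] <- as.vector(tab)
  }
  expect_equal(unname(cohort_by_col), unname(ct$cohort_by_age))
  # conservation: every in-design record lands in exactly one cell of each table
  # (records whose cohort has advanced beyond the last column are outside the
  # design and tallied by neither margin)
  expect_equal(sum(ct$wave_by_age), sum(x$ald$observed) / 10)
  expect_equal(sum(ct$cohort_by_age), sum(ct$wave_by_age))
  # diagonality: within each wave, occupied cells map to strictly older cohorts
  # as the age column increases
  for (w in rownames(ct$wave_by_age)) {
    occ <- which(ct$wave_by_age[w, ] > 0)
    coh <- cohort_for_cell(rep(as.integer(w), length(occ)), occ, sch)
    expect_true(all(diff(coh) < 0))
  }
})

test_that("empty cell tables and empty panels behave", {
  sch <- design_schedule()
  zero <- matrix(0, 4, 9, dimnames = list(sch$wave_years, sch$nominal_ages))
  ct <- count_tables(zero, sch, mode = "cells")
  expect_true(all(ct$wave_by_age == 0) && all(ct$cohort_by_age == 0))
  expect_error(count_tables(data.frame(), sch, mode = "panel"), "empty")
})

test_that("cohort grouping follows the decade-of-birth default and accepts identity maps", {
  grouping <- default_cohort_grouping()
  expect_identical(unname(grouping["5"]), "G1")
  expect_identical(unname(grouping["9"]), "G2")
  expect_identical(unname(grouping["10"]), "G3")
  x <- small_ald()
  ident <- setNames(as.character(1:12), as.character(1:12))
  ald_id <- group_cohorts(x$ald, ident)
  expect_identical(sort(unique(ald_id$group)), sort(unique(as.character(x$ald$cohort))))
  expect_error(group_cohorts(x$ald, c(`1` = "G1")), "missing cohort")
})

test_that("wave overlap shares reflect retention", {
  # zero attrition, no refreshment: every pairwise overlap is 100%
  cfg0 <- synthetic_config(n_baseline = 300, n_refresh = 0, attrition_hazard = 0, seed = 2)
  pop0 <- generate_population(cfg0)
  ov0 <- overlap_statistics(pop0$panel, design_schedule())
  expect_equal(unname(ov0$pairwise), c(1, 1, 1))
  # flat 20% hazard (no age slope): overlaps near 0.8 within Monte-Carlo error
  cfg <- synthetic_config(n_baseline = 6000, n_refresh = 0, attrition_hazard = 0.2,
                          attrition_age_slope = 0, seed = 4)
  pop <- generate_population(cfg)
  ov <- overlap_statistics(pop$panel, design_schedule())
  expect_true(all(abs(ov$pairwise - 0.8) < 0.03))
  # a person observed only at wave 1 joins no pair's numerator
  solo <- data.frame(person_id = "Z", wave_year = 2001, age = 55, sex = 0)
  for (j in 1:9) solo[[paste0("marker_", j)]] <- 0
  ovs <- overlap_statistics(solo, design_schedule())
  expect_equal(unname(ovs$pairwise[1]), 0)
  # panel-mode and ald-mode agree exactly when no cohort ages out of the grid
  cfg2 <- synthetic_config(n_baseline = 2000, n_refresh = 0, attrition_hazard = 0.2,
                           attrition_age_slope = 0, seed = 6,
                           birth_year_range = c(1936, 1951))
  pop2 <- generate_population(cfg2)
  ov2 <- overlap_statistics(pop2$panel, design_schedule())
  ova <- overlap_statistics(rearrange(pop2$panel, design_schedule()))
  expect_equal(ov2$pairwise, ova$pairwise, tolerance = 1e-12)
})
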