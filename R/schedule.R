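#' Birth-cohort bins of the default cohort-sequential schedule
#'
#' Twelve four-ish-year birth cohorts spanning 1909--1962, as used in the
#' Mexican Health and Aging Study (MHAS) accelerated layout: Cohort 1 is the
#' oldest (born 1909--1919), Cohort 9 the youngest baseline cohort (1948--1951),
#' and Cohorts 10--12 enter with the 2012 refreshment sample. Bins are disjoint
#' and ordered; published bins overlap at 1951, which is resolved here in favour
#' of Cohort 9 so that every birth year maps to exactly one cohort.
#'
#' @return A data frame with columns `cohort`, `from`, `to` (inclusive birth years).
#' @export
default_cohort_bins <- function() {
  data.frame(
    cohort = 1:12,
    from = c(1909L, 1920L, 1924L, 1928L, 1932L, 1936L, 1940L, 1944L, 1948L,
             1952L, 1955L, 1959L),
    to   = c(1919L, 1923L, 1927L, 1931L, 1935L, 1939L, 1943L, 1947L, 1951L,
             1954L, 1958L, 1962L)
  )
}

#' Default cohort-to-group aggregation (decade of birth)
#'
#' Aggregates the twelve cohorts into three birth-decade groups used to balance
#' group sizes in the multigroup model: G1 = cohorts 1--6 (born before 1940),
#' G2 = cohorts 7--9 (born in the 1940s), G3 = cohorts 10--12 (born in the 1950s
#' and early 1960s).
#'
#' @return A named character vector mapping cohort id (as name) to group label.
#' @export
default_cohort_grouping <- function() {
  stats::setNames(c(rep("G1", 6), rep("G2", 3), rep("G3", 3)), as.character(1:12))
}

#' Build an accelerated-longitudinal design schedule
#'
#' A `design_schedule` holds all bookkeeping of the cohort-sequential design:
#' the calendar wave years, the age brackets that define the nine columns of
#' the age axis, their nominal mean ages (used as axis labels and for curve
#' evaluation), the birth-cohort bins, the per-entry-stream wave-to-column
#' offsets, and the anchor cohort occupying column 1 at each entry wave.
#'
#' Under the default schedule a person entering at the 2001 baseline advances
#' by columns \{2001: +0, 2003: +1, 2012: +3, 2015: +4\} relative to their
#' baseline age column, while a refreshment entrant (first seen 2012) advances
#' by \{2012: +0, 2015: +1\}. A cell that would advance beyond column 9 has
#' aged out of the design and is unobserved.
#'
#' @param wave_years Integer vector of calendar interview years, strictly increasing.
#' @param age_breaks Lower bounds of the nine age columns; the last column is
#'   open-ended (82+).
#' @param nominal_ages Nominal mean age of each column.
#' @param cohort_bins Data frame as [default_cohort_bins()].
#' @param wave_offsets Named list: one integer offset vector per entry wave.
#' @param anchor_cohorts Named integer vector: cohort occupying column 1 at each
#'   entry wave.
#' @param grouping Named character vector mapping cohort to aggregated group.
#' @return An object of class `design_schedule`.
#' @examples
#' sch <- design_schedule()
#' assign_cohort(1949, sch)   # 9
#' column_for(2001, 1, 2012, sch)  # 4
#' @export
design_schedule <- function(wave_years = c(2001L, 2003L, 2012L, 2015L),
                            age_breaks = c(50, 54, 58, 62, 66, 70, 74, 78, 82),
                            nominal_ages = c(52, 55, 59, 63, 67, 71, 75, 81, 86),
                            cohort_bins = default_cohort_bins(),
                            wave_offsets = list(
                              `2001` = c(`2001` = 0L, `2003` = 1L, `2012` = 3L, `2015` = 4L),
                              `2012` = c(`2012` = 0L, `2015` = 1L)),
                            anchor_cohorts = c(`2001` = 9L, `2012` = 12L),
                            grouping = default_cohort_grouping()) {
  wave_years <- as.integer(wave_years)
  if (any(diff(wave_years) <= 0)) stopf("wave_years must be strictly increasing")
  if (length(age_breaks) != length(nominal_ages))
    stopf("age_breaks and nominal_ages must have equal length")
  if (any(diff(age_breaks) <= 0)) stopf("age_breaks must be strictly increasing")
  cb <- cohort_bins[order(cohort_bins$from), , drop = FALSE]
  if (any(cb$from > cb$to)) stopf("cohort bins must have from <= to")
  if (nrow(cb) > 1 && any(cb$from[-1] <= cb$to[-nrow(cb)]))
    stopf("cohort bins must be disjoint and ordered")
  for (w in names(wave_offsets)) {
    off <- wave_offsets[[w]]
    if (any(diff(off) <= 0)) stopf("offsets for entry wave %s must be strictly increasing", w)
  }
  missing_groups <- setdiff(as.character(cohort_bins$cohort), names(grouping))
  if (length(missing_groups))
    stopf("grouping is missing cohorts: %s", paste(missing_groups, collapse = ", "))
  structure(list(
    wave_years = wave_years,
    age_breaks = age_breaks,
    nominal_ages = nominal_ages,
    cohort_bins = cohort_bins,
    wave_offsets = wave_offsets,
    anchor_cohorts = anchor_cohorts,
    grouping = grouping,
    n_columns = length(age_breaks)
  ), class = "design_schedule")
}

#' @export
print.design_schedule <- function(x, ...) {
  cat("Accelerated longitudinal design schedule\n")
  cat("  waves:       ", paste(x$wave_years, collapse = ", "), "\n")
  cat("  age columns: ", length(x$age_breaks), " (nominal ages ",
      paste(x$nominal_ages, collapse = ", "), ")\n", sep = "")
  cat("  cohorts:     ", nrow(x$cohort_bins), " (birth years ",
      min(x$cohort_bins$from), "-", max(x$cohort_bins$to), ")\n", sep = "")
  cat("  entry waves: ", paste(names(x$wave_offsets), collapse = ", "), "\n")
  invisible(x)
}

#' Assign a birth year to its cohort
#'
#' @param birth_year Vector of calendar birth years.
#' @param schedule A [design_schedule()].
#' @param strict If `TRUE` (default), a birth year outside every cohort bin is
#'   an error; if `FALSE`, it maps to `NA` (caller may drop the record).
#' @return Integer cohort ids.
#' @export
assign_cohort <- function(birth_year, schedule = design_schedule(), strict = TRUE) {
  cb <- schedule$cohort_bins
  out <- rep(NA_integer_, length(birth_year))
  for (k in seq_len(nrow(cb))) {
    hit <- !is.na(birth_year) & birth_year >= cb$from[k] & birth_year <= cb$to[k]
    out[hit] <- cb$cohort[k]
  }
  if (strict && anyNA(out[!is.na(birth_year)]))
    stopf("birth year(s) outside all cohort bins: %s",
          paste(unique(birth_year[is.na(out) & !is.na(birth_year)]), collapse = ", "))
  out
}

#' Age column containing an age
#'
#' @param age Vector of ages in years.
#' @param schedule A [design_schedule()].
#' @return Integer column index (1-based); `NA` for ages below the first break.
#' @export
age_column <- function(age, schedule = design_schedule()) {
  idx <- findInterval(age, schedule$age_breaks)
  idx[idx == 0L] <- NA_integer_
  as.integer(idx)
}

#' Age column occupied at a follow-up wave
#'
#' Applies the entry-stream column offsets: a cohort anchored at
#' `baseline_column` at its entry wave occupies `baseline_column + offset` at a
#' later wave, or no column at all once it has advanced beyond the last bracket
#' (the cohort has aged out of the design).
#'
#' @param entry_wave Calendar year of first interview (an entry stream of the schedule).
#' @param baseline_column Column occupied at the entry wave (1-based).
#' @param wave Calendar year of the wave being mapped (vectorised).
#' @param schedule A [design_schedule()].
#' @return Integer column index, or `NA` when the cohort has aged out.
#' @export
column_for <- function(entry_wave, baseline_column, wave, schedule = design_schedule()) {
  off <- schedule$wave_offsets[[as.character(entry_wave)]]
  if (is.null(off)) stopf("unknown entry wave: %s", entry_wave)
  if (any(baseline_column < 1L | baseline_column > schedule$n_columns))
    stopf("baseline_column must be in 1..%d", schedule$n_columns)
  if (!all(as.character(wave) %in% names(off)))
    stopf("unknown wave year(s) for entry stream %s: %s", entry_wave,
          paste(setdiff(as.character(wave), names(off)), collapse = ", "))
  col <- as.integer(baseline_column + off[as.character(wave)])
  col[col > schedule$n_columns] <- NA_integer_
  unname(col)
}

#' Cohort occupying a (wave, age-column) cell
#'
#' The staircase rule that reconstructs the cohort-by-age-column table from a
#' wave-by-age-column count table: within a wave, the cohort occupying column
#' `j` is `anchor + 1 + offset(wave) - j` on the baseline entry stream's
#' offsets. Refreshment cohorts fall out of the same formula (values above the
#' baseline anchor cohort).
#'
#' @param wave Calendar wave year (vectorised).
#' @param column Age-column index (vectorised).
#' @param schedule A [design_schedule()].
#' @return Integer cohort id; `NA` for cells no cohort occupies.
#' @export
cohort_for_cell <- function(wave, column, schedule = design_schedule()) {
  base_entry <- names(schedule$wave_offsets)[1L]
  off <- schedule$wave_offsets[[base_entry]]
  if (!all(as.character(wave) %in% names(off)))
    stopf("unknown wave year(s): %s",
          paste(setdiff(as.character(wave), names(off)), collapse = ", "))
  anchor <- schedule$anchor_cohorts[[base_entry]]
  coh <- as.integer(anchor + 1L + off[as.character(wave)] - column)
  coh[coh < min(schedule$cohort_bins$cohort) | coh > max(schedule$cohort_bins$cohort)] <- NA_integer_
  unname(coh)
}
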