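#' Construct a person x time-point x item array for the latent class model
#'
#' The container consumed by the estimator: a binary `values` matrix with one
#' row per person and one column per (item, time-point) cell (items varying
#' fastest, columns named `i<item>_t<time>`), an `observed` mask of the same
#' shape, and per-person cohort and group labels. [rearrange()] builds this
#' from a long panel; the constructor is also usable directly for small
#' hand-made instances with arbitrary dimensions.
#'
#' @param values Numeric matrix (persons x `n_items * n_time`) of 0/1 values,
#'   `NA` where unobserved, or a 3-d array person x time x item.
#' @param n_items,n_time Dimensions of the measurement grid.
#' @param observed Logical mask; defaults to `!is.na(values)`.
#' @param person_id,cohort,group,entry_wave,baseline_column Optional per-person
#'   metadata.
#' @param item_names Optional item labels.
#' @param schedule The [design_schedule()] the layout came from, if any.
#' @return An object of class `ald_matrix`.
#' @export
ald_matrix <- function(values, n_items, n_time, observed = NULL,
                       person_id = NULL, cohort = NULL, group = NULL,
                       entry_wave = NULL, baseline_column = NULL,
                       item_names = NULL, schedule = NULL) {
  if (length(dim(values)) == 3L) {
    n_time <- dim(values)[2L]; n_items <- dim(values)[3L]
    values <- matrix(aperm(values, c(1, 3, 2)), nrow = dim(values)[1L])
  }
  values <- as.matrix(values)
  if (ncol(values) != n_items * n_time) stopf("values must have n_items * n_time columns")
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  if (!all(dim(observed) == dim(values))) stopf("observed mask must match values")
  values[!observed] <- NA_real_
  if (!all(values[observed] %in% c(0, 1))) stopf("observed values must be 0/1")
  n <- nrow(values)
  colnames(values) <- colnames(observed) <- cell_names(n_items, n_time)
  structure(list(
    values = values, observed = observed,
    n_items = as.integer(n_items), n_time = as.integer(n_time),
    person_id = person_id %||% sprintf("P%06d", seq_len(n)),
    cohort = cohort %||% rep(NA_integer_, n),
    group = group %||% rep(NA_character_, n),
    entry_wave = entry_wave %||% rep(NA_integer_, n),
    baseline_column = baseline_column %||% rep(NA_integer_, n),
    item_names = item_names %||% paste0("item_", seq_len(n_items)),
    schedule = schedule
  ), class = "ald_matrix")
}

#' @export
print.ald_matrix <- function(x, ...) {
  cat("ALD measurement array\n")
  cat("  persons:    ", nrow(x$values), "\n", sep = "")
  cat("  grid:       ", x$n_items, " items x ", x$n_time, " time points\n", sep = "")
  cat("  observed:   ", sum(x$observed), " cells (",
      round(100 * mean(x$observed), 1), "% of the grid)\n", sep = "")
  if (!all(is.na(x$cohort)))
    cat("  cohorts:    ", paste(sort(unique(x$cohort)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# values with NA -> 0, plus 0/1 mask, as plain matrices for the EM linear algebra
ald_design_matrices <- function(ald) {
  Y <- ald$values
  Y[is.na(Y)] <- 0
  list(Y = Y, O = ald$observed + 0)
}

#' Rearrange a long panel into the accelerated (cohort-sequential) layout
#'
#' Each person is assigned a cohort from their birth year (entry wave year
#' minus age at first interview) and a baseline age column from their age at
#' first interview; every wave record then maps to the age column given by the
#' entry stream's offsets, or to no column once the person has aged beyond the
#' last bracket. The person keeps their cohort at all follow-ups even when
#' their exact age drifts relative to the column's nominal bracket, so panel
#' members stay on their cohort's diagonal. The nine markers plus respondent
#' sex (replicated at every observed time point as item 10) fill the cells.
#'
#' @param panel Long data frame with columns
#'   `person_id, wave_year, age, sex, marker_1..marker_9`.
#' @param schedule A [design_schedule()].
#' @return An [ald_matrix()] with cohort and group labels. Persons whose birth
#'   year falls outside every cohort bin, or whose entry wave is not an entry
#'   stream of the schedule, are dropped with a message.
#' @export
rearrange <- function(panel, schedule = design_schedule()) {
  req <- c("person_id", "wave_year", "age", "sex", paste0("marker_", 1:9))
  miss <- setdiff(req, names(panel))
  if (length(miss)) stopf("panel is missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(panel[c("person_id", "wave_year")]))
    stopf("duplicate (person, wave) records in panel")

  panel <- panel[order(panel$person_id, panel$wave_year), , drop = FALSE]
  first <- !duplicated(panel$person_id)
  persons <- panel$person_id[first]
  entry_wave <- panel$wave_year[first]
  entry_age <- panel$age[first]
  if (any(entry_age < 50)) stopf("age < 50 at entry for person(s): %s",
                                 paste(utils::head(persons[entry_age < 50], 5), collapse = ", "))
  birth <- entry_wave - entry_age
  # consistency: birth year implied by every record within +/- 1 of entry-implied
  pidx <- match(panel$person_id, persons)
  drift <- abs((panel$wave_year - panel$age) - birth[pidx])
  if (any(drift > 1))
    stopf("inconsistent ages within person(s): %s",
          paste(unique(panel$person_id[drift > 1])[1:min(5, sum(drift > 1))], collapse = ", "))

  cohort <- assign_cohort(birth, schedule, strict = FALSE)
  stream_ok <- as.character(entry_wave) %in% names(schedule$wave_offsets)
  keep <- !is.na(cohort) & stream_ok
  if (!all(keep))
    message(sum(!keep), " person(s) dropped: birth year outside the cohort bins ",
            "or entry wave not an entry stream of the design")
  persons <- persons[keep]; entry_wave <- entry_wave[keep]
  entry_age <- entry_age[keep]; cohort <- cohort[keep]
  panel <- panel[panel$person_id %in% persons, , drop = FALSE]
  if (!nrow(panel)) stopf("no persons left after design filtering")

  baseline_col <- age_column(entry_age, schedule)
  pidx <- match(panel$person_id, persons)
  # per-record column via the entry stream's offsets
  off <- rep(NA_integer_, nrow(panel))
  for (ew in unique(entry_wave)) {
    tab <- schedule$wave_offsets[[as.character(ew)]]
    rows <- entry_wave[pidx] == ew
    o <- tab[as.character(panel$wave_year[rows])]
    if (anyNA(o)) stopf("wave year not defined for entry stream %s", ew)
    off[rows] <- as.integer(o)
  }
  col <- baseline_col[pidx] + off
  in_grid <- col <= schedule$n_columns
  n_items <- 10L; n_time <- schedule$n_columns
  values <- matrix(NA_real_, length(persons), n_items * n_time)
  rows <- pidx[in_grid]
  tcol <- col[in_grid]
  for (j in 1:9)
    values[cbind(rows, cell_index(j, tcol, n_items))] <- panel[[paste0("marker_", j)]][in_grid]
  values[cbind(rows, cell_index(10L, tcol, n_items))] <- panel$sex[in_grid]

  grp <- unname(schedule$grouping[as.character(cohort)])
  ald_matrix(values, n_items, n_time,
             person_id = persons, cohort = cohort, group = grp,
             entry_wave = entry_wave, baseline_column = baseline_col,
             item_names = c(paste0("marker_", 1:9), "sex"),
             schedule = schedule)
}

#' Tabulate observations by wave/cohort and age column
#'
#' In panel mode, tallies the records of a long panel by (wave, mapped age
#' column) and by (assigned cohort, mapped age column); the two tables share
#' identical grand totals since every observation lands in exactly one cohort
#' cell. In cell mode, accepts a pre-tabulated wave x age-column count matrix
#' and redistributes each cell to the cohort occupying it under the schedule's
#' staircase rule ([cohort_for_cell()]); this mode reconstructs the published
#' cohort-by-age-column table exactly from the wave-by-age-column counts.
#'
#' @param x A long panel data frame, or (cell mode) a numeric wave x column
#'   matrix whose rownames are wave years.
#' @param schedule A [design_schedule()].
#' @param mode `"auto"` (data frame -> panel, matrix -> cells), `"panel"`, or
#'   `"cells"`.
#' @return List of class `ald_count_tables` with elements `wave_by_age`
#'   (waves x columns), `cohort_by_age` (cohorts, youngest first, x columns),
#'   both carrying row/column totals as attributes via `rowSums`/`colSums`.
#' @export
count_tables <- function(x, schedule = design_schedule(),
                         mode = c("auto", "panel", "cells")) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (is.data.frame(x)) "panel" else "cells"
  n_col <- schedule$n_columns
  cohorts <- sort(schedule$cohort_bins$cohort, decreasing = TRUE)
  wave_by_age <- matrix(0, length(schedule$wave_years), n_col,
                        dimnames = list(schedule$wave_years, schedule$nominal_ages))
  cohort_by_age <- matrix(0, length(cohorts), n_col,
                          dimnames = list(cohorts, schedule$nominal_ages))

  if (mode == "cells") {
    m <- as.matrix(x)
    if (ncol(m) != n_col) stopf("cell matrix must have %d age columns", n_col)
    if (is.null(rownames(m))) rownames(m) <- schedule$wave_years[seq_len(nrow(m))]
    for (w in rownames(m)) for (j in seq_len(n_col)) {
      cnt <- m[w, j]
      wave_by_age[w, j] <- wave_by_age[w, j] + cnt
      coh <- cohort_for_cell(as.integer(w), j, schedule)
      if (is.na(coh)) {
        if (cnt > 0) warning(sprintf("cell (%s, column %d) maps to no cohort; %g observations dropped", w, j, cnt))
      } else {
        cohort_by_age[as.character(coh), j] <- cohort_by_age[as.character(coh), j] + cnt
      }
    }
  } else {
    if (!nrow(x)) stopf("panel is empty")
    map <- panel_cell_map(x, schedule)
    ok <- !is.na(map$column)
    wave_by_age[] <- as.matrix(stats::xtabs(~ factor(wave_year, levels = schedule$wave_years) +
                                              factor(column, levels = seq_len(n_col)),
                                            data = map[ok, ]))
    cohort_by_age[] <- as.matrix(stats::xtabs(~ factor(cohort, levels = cohorts) +
                                                factor(column, levels = seq_len(n_col)),
                                              data = map[ok, ]))
  }
  structure(list(wave_by_age = wave_by_age, cohort_by_age = cohort_by_age),
            class = "ald_count_tables")
}

# per-record (wave, cohort, mapped column) bookkeeping shared by count_tables
# and overlap_statistics
panel_cell_map <- function(panel, schedule) {
  panel <- panel[order(panel$person_id, panel$wave_year), , drop = FALSE]
  first <- !duplicated(panel$person_id)
  persons <- panel$person_id[first]
  entry_wave <- panel$wave_year[first]
  entry_age <- panel$age[first]
  birth <- entry_wave - entry_age
  cohort <- assign_cohort(birth, schedule, strict = FALSE)
  baseline_col <- age_column(entry_age, schedule)
  pidx <- match(panel$person_id, persons)
  col <- rep(NA_integer_, nrow(panel))
  for (ew in unique(entry_wave)) {
    key <- as.character(ew)
    rows <- which(entry_wave[pidx] == ew)
    if (!key %in% names(schedule$wave_offsets)) next
    tab <- schedule$wave_offsets[[key]]
    o <- as.integer(tab[as.character(panel$wave_year[rows])])
    cc <- baseline_col[pidx[rows]] + o
    cc[cc > schedule$n_columns] <- NA_integer_
    col[rows] <- cc
  }
  col[is.na(cohort[pidx])] <- NA_integer_
  data.frame(person_id = panel$person_id, wave_year = panel$wave_year,
             cohort = cohort[pidx], column = col, stringsAsFactors = FALSE)
}

#' @export
print.ald_count_tables <- function(x, ...) {
  cat("Observations by wave and age column:\n")
  print(cbind(x$wave_by_age, n = rowSums(x$wave_by_age)))
  cat("\nObservations by cohort and age column:\n")
  print(cbind(x$cohort_by_age, n = rowSums(x$cohort_by_age)))
  cat("\nGrand total:", sum(x$wave_by_age), "\n")
  invisible(x)
}

#' Attach aggregated group labels to an ALD array
#'
#' @param ald An [ald_matrix()].
#' @param grouping Named character vector mapping cohort id to group label;
#'   defaults to the schedule's decade-of-birth grouping. Use an identity map
#'   (each cohort its own group) to keep cohorts ungrouped.
#' @return The `ald_matrix` with its `group` field replaced.
#' @export
group_cohorts <- function(ald, grouping = NULL) {
  stopifnot(inherits(ald, "ald_matrix"))
  grouping <- grouping %||% (ald$schedule %||% design_schedule())$grouping
  present <- unique(ald$cohort[!is.na(ald$cohort)])
  miss <- setdiff(as.character(present), names(grouping))
  if (length(miss)) stopf("grouping is missing cohort(s): %s", paste(miss, collapse = ", "))
  ald$group <- unname(grouping[as.character(ald$cohort)])
  ald
}

#' Share of persons observed in consecutive wave pairs
#'
#' For each pair of consecutive waves, the number of persons present in both
#' divided by the number present in the earlier wave, plus their mean. Accepts
#' either a long panel or a rearranged [ald_matrix()] (wave participation is
#' reconstructed from entry stream, baseline column, and observed time points).
#'
#' @param x A long panel data frame or an `ald_matrix`.
#' @param schedule A [design_schedule()].
#' @return List with `pairwise` (named shares) and `mean`.
#' @export
overlap_statistics <- function(x, schedule = design_schedule()) {
  wy <- schedule$wave_years
  if (length(wy) < 2L) stopf("need at least two waves")
  if (inherits(x, "ald_matrix")) {
    # a wave counts as participated when its mapped time point has >= 1
    # observed cell; waves whose column lies beyond the design (aged out)
    # cannot be recovered from the array and are not counted
    sch <- x$schedule %||% schedule
    wy <- sch$wave_years
    n <- nrow(x$values)
    pres <- matrix(FALSE, n, length(wy), dimnames = list(NULL, wy))
    t_any <- t(apply(x$observed, 1L, function(r) colSums(matrix(r, nrow = x$n_items)) > 0))
    for (r in seq_len(n)) {
      key <- as.character(x$entry_wave[r])
      if (!key %in% names(sch$wave_offsets)) next
      off <- sch$wave_offsets[[key]]
      cols_at <- x$baseline_column[r] + off
      ok <- cols_at <= sch$n_columns
      pres[r, names(off)[ok]] <- t_any[r, cols_at[ok]]
    }
  } else {
    persons <- unique(x$person_id)
    pres <- matrix(FALSE, length(persons), length(wy), dimnames = list(NULL, wy))
    pres[cbind(match(x$person_id, persons), match(x$wave_year, wy))] <- TRUE
  }
  pair <- numeric(length(wy) - 1L)
  names(pair) <- paste(wy[-length(wy)], wy[-1L], sep = "-")
  for (k in seq_len(length(wy) - 1L)) {
    denom <- sum(pres[, k])
    pair[k] <- if (denom == 0) NA_real_ else sum(pres[, k] & pres[, k + 1L]) / denom
  }
  list(pairwise = pair, mean = mean(pair, na.rm = TRUE))
}

#' Write a rearranged ALD array as a wide CSV
#'
#' One row per person: `person_id, cohort, group, entry_wave`, then one column
#' per (item, time) cell with empty cells where unobserved.
#'
#' @param ald An [ald_matrix()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ald_csv <- function(ald, path) {
  df <- data.frame(person_id = ald$person_id, cohort = ald$cohort,
                   group = ald$group, entry_wave = ald$entry_wave,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ald$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Published wave-by-age observation counts (MHAS 2001--2015)
#'
#' The wave x age-column observation counts of the Mexican Health and Aging
#' Study four-wave panel (2001, 2003, 2012, 2015) across the nine age columns
#' of the accelerated layout, as published. Useful as the cell-mode input of
#' [count_tables()].
#'
#' @return Numeric 4 x 9 matrix, rownames = wave years, colnames = nominal ages.
#' @export
mhas_wave_counts <- function() {
  f <- system.file("extdata", "mhas_wave_age_counts.csv", package = "aldlca", mustWork = TRUE)
  d <- utils::read.csv(f, check.names = FALSE)
  m <- as.matrix(d[, -1]) * 1.0
  dimnames(m) <- list(d$wave, sub("^c", "", colnames(d)[-1]))
  m
}

#' Published cohort-by-age observation counts (MHAS accelerated layout)
#'
#' The cohort x age-column staircase table corresponding to
#' [mhas_wave_counts()], as published (zeros where a cohort is never observed).
#'
#' @return Numeric 12 x 9 matrix, rownames = cohorts (youngest first).
#' @export
mhas_cohort_counts <- function() {
  f <- system.file("extdata", "mhas_cohort_age_counts.csv", package = "aldlca", mustWork = TRUE)
  d <- utils::read.csv(f, check.names = FALSE)
  m <- as.matrix(d[, -1]) * 1.0
  dimnames(m) <- list(d$cohort, sub("^c", "", colnames(d)[-1]))
  m
}
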