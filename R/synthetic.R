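#' Solve a logistic-in-age prevalence curve from two endpoints
#'
#' Given the prevalence of a binary marker at two ages, returns the intercept
#' and slope of the logistic curve `p(age) = plogis(intercept + slope * age)`
#' passing through both points.
#'
#' @param p1,p2 Prevalences in (0,1) at `age1` and `age2`.
#' @param age1,age2 Ages in years, `age1 != age2`.
#' @return Named numeric vector with elements `intercept` and `slope`.
#' @examples
#' # partner-presence marginal falling from 77.8% at age 52 to 35.2% at 86
#' solve_curve_endpoints(0.778, 52, 0.352, 86)
#' @export
solve_curve_endpoints <- function(p1, age1, p2, age2) {
  if (age1 == age2) stopf("age1 and age2 must differ")
  if (any(c(p1, p2) <= 0 | c(p1, p2) >= 1)) stopf("endpoint prevalences must be in (0,1)")
  slope <- (stats::qlogis(p2) - stats::qlogis(p1)) / (age2 - age1)
  c(intercept = stats::qlogis(p1) - slope * age1, slope = slope)
}

curves_from_endpoints <- function(p_young, p_old, age_young = 52, age_old = 86) {
  s <- nrow(p_young); k <- ncol(p_young)
  intercept <- slope <- matrix(0, s, k)
  for (cl in seq_len(s)) for (j in seq_len(k)) {
    ab <- solve_curve_endpoints(p_young[cl, j], age_young, p_old[cl, j], age_old)
    intercept[cl, j] <- ab[["intercept"]]
    slope[cl, j] <- ab[["slope"]]
  }
  list(intercept = intercept, slope = slope)
}

#' Default three-class item curves
#'
#' Logistic-in-age prevalence curves for the nine household markers under three
#' latent trajectory archetypes: a large multigenerational household class, a
#' couple/emptying-nest class, and a small household class without a partner.
#' Endpoint prevalences at ages 52 and 86 are calibrated loosely to published
#' marginal trends for Mexican adults aged 50+ (partner presence falling from
#' roughly 78% to 35%, grandchildren presence rising from roughly 21% to 34%,
#' children presence falling from 82% to 55%), with class contrasts large
#' enough that class membership is well identified from a few observed waves.
#'
#' @param s_true Number of classes; only 3 is provided here.
#' @return List with `intercept` and `slope` matrices (class x 9 items).
#' @export
default_item_curves <- function(s_true = 3) {
  if (s_true != 3) stopf("default_item_curves are defined for 3 classes; use separated_item_curves() or supply your own")
  # items: 1 children in hh, 2 children >=18, 3 studying children, 4 working
  # children, 5 children's partners, 6 own partner/spouse, 7 nonrelatives,
  # 8 other relatives, 9 grandchildren
  p52 <- rbind(
    c(0.95, 0.92, 0.35, 0.85, 0.55, 0.80, 0.05, 0.60, 0.70),
    c(0.85, 0.55, 0.15, 0.55, 0.04, 0.97, 0.02, 0.10, 0.04),
    c(0.35, 0.30, 0.04, 0.25, 0.06, 0.30, 0.03, 0.40, 0.15))
  p86 <- rbind(
    c(0.92, 0.90, 0.05, 0.75, 0.75, 0.35, 0.06, 0.65, 0.85),
    c(0.20, 0.18, 0.02, 0.12, 0.05, 0.70, 0.02, 0.12, 0.12),
    c(0.30, 0.35, 0.02, 0.25, 0.15, 0.03, 0.04, 0.50, 0.45))
  curves_from_endpoints(p52, p86)
}

#' Flat, well-separated item curves for recovery experiments
#'
#' Age-constant curves whose class-conditional prevalences sit at one of two
#' levels (default 0.1 / 0.9), with a distinct high/low pattern per class, so
#' that parameter recovery can be assessed against a sharply separated truth.
#'
#' @param s_true Number of classes (2--6).
#' @param p_lo,p_hi The two prevalence levels.
#' @param n_items Number of markers (default 9).
#' @return List with `intercept` and `slope` (all-zero) matrices.
#' @export
separated_item_curves <- function(s_true = 3, p_lo = 0.1, p_hi = 0.9, n_items = 9) {
  if (s_true < 2 || s_true > 6) stopf("s_true must be in 2..6")
  # deterministic staggered block pattern: class s is 'high' on items
  # shifted by (s-1) * floor(n_items / s_true), guaranteeing distinct profiles
  hi <- matrix(FALSE, s_true, n_items)
  block <- max(1L, floor(n_items / s_true))
  for (s in seq_len(s_true)) {
    idx <- ((seq_len(ceiling(n_items / 2)) - 1L + (s - 1L) * block) %% n_items) + 1L
    hi[s, idx] <- TRUE
  }
  p <- matrix(p_lo, s_true, n_items)
  p[hi] <- p_hi
  list(intercept = stats::qlogis(p), slope = matrix(0, s_true, n_items))
}

#' Configuration of the synthetic aging-panel generator
#'
#' Describes a panel with known latent-class structure compatible with the
#' accelerated longitudinal schedule: `n_baseline` persons enter at the first
#' wave, `n_refresh` at the refreshment wave (third wave), class membership is
#' drawn from `class_proportions`, and each of the nine binary household
#' markers follows a class-specific logistic-in-age prevalence curve.
#' Respondent sex enters as a tenth binary marker with class-specific
#' probability `sex_prob`. By default it is drawn independently at every
#' observed wave given class, so the generated data satisfy the local
#' independence the latent class model assumes at every cell;
#' `sex_time_constant = TRUE` instead draws sex once per person and
#' replicates it (demographically realistic, but the replication is
#' within-person dependence beyond class membership, i.e. a deliberate
#' model violation for robustness experiments).
#' Attrition removes persons permanently before each follow-up wave with
#' probability `attrition_hazard` (per follow-up occasion, optionally
#' age-increasing on the logit scale via `attrition_age_slope`); by default it
#' does not depend on class (missing at random by design), and
#' `attrition_class_shift` can switch on class-dependent attrition for
#' robustness experiments.
#'
#' @param n_baseline Persons entering at wave 1.
#' @param n_refresh Persons entering at wave 3 (the refreshment sample).
#' @param s_true True number of latent classes.
#' @param class_proportions Simplex of length `s_true` (sums to 1 within 1e-12).
#' @param item_curves List with `intercept` and `slope` matrices (class x 9).
#' @param sex_prob Per-class probability that the respondent is female (item 10).
#' @param sex_time_constant Draw sex once per person instead of per wave
#'   (default `FALSE`; see Details).
#' @param birth_year_range Inclusive birth-year range for baseline entrants
#'   (subject to age >= 50 at entry).
#' @param refresh_birth_range Inclusive birth-year range for refreshment
#'   entrants (subject to age >= 50 at the refreshment wave).
#' @param wave_years Calendar interview years, strictly increasing.
#' @param attrition_hazard Dropout probability before each follow-up wave;
#'   scalar or one value per follow-up wave.
#' @param attrition_age_slope Per-year logit increase of the dropout hazard
#'   around age 70.
#' @param attrition_class_shift Per-class logit shift of the hazard (default all 0).
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_baseline = 8000,
                             n_refresh = 2000,
                             s_true = 3,
                             class_proportions = c(0.40, 0.35, 0.25),
                             item_curves = default_item_curves(s_true),
                             sex_prob = c(0.80, 0.15, 0.90),
                             sex_time_constant = FALSE,
                             birth_year_range = c(1909L, 1951L),
                             refresh_birth_range = c(1952L, 1962L),
                             wave_years = c(2001L, 2003L, 2012L, 2015L),
                             attrition_hazard = c(0.06, 0.35, 0.11),
                             attrition_age_slope = 0.03,
                             attrition_class_shift = rep(0, s_true),
                             seed = 1L) {
  if (n_baseline < 1) stopf("n_baseline must be >= 1")
  if (n_refresh < 0) stopf("n_refresh must be >= 0")
  if (length(class_proportions) != s_true || !length(class_proportions))
    stopf("class_proportions must have length s_true")
  if (abs(sum(class_proportions) - 1) > 1e-12)
    stopf("class_proportions must sum to 1 within 1e-12")
  if (any(diff(wave_years) <= 0)) stopf("wave_years must be strictly increasing")
  if (!is.list(item_curves) || is.null(item_curves$intercept) || is.null(item_curves$slope))
    stopf("item_curves must be a list with intercept and slope matrices")
  if (!all(dim(item_curves$intercept) == c(s_true, 9)) ||
      !all(dim(item_curves$slope) == c(s_true, 9)))
    stopf("item_curves matrices must be s_true x 9")
  if (length(sex_prob) != s_true || any(sex_prob <= 0 | sex_prob >= 1))
    stopf("sex_prob must be s_true probabilities in (0,1)")
  n_follow <- length(wave_years) - 1L
  if (!length(attrition_hazard) %in% c(1L, n_follow))
    stopf("attrition_hazard must be scalar or one value per follow-up wave")
  if (any(attrition_hazard < 0 | attrition_hazard > 1)) stopf("attrition_hazard must be in [0,1]")
  if (length(attrition_class_shift) != s_true)
    stopf("attrition_class_shift must have length s_true")
  cfg <- structure(list(
    n_baseline = as.integer(n_baseline), n_refresh = as.integer(n_refresh),
    s_true = as.integer(s_true), class_proportions = class_proportions,
    item_curves = item_curves, sex_prob = sex_prob,
    sex_time_constant = isTRUE(sex_time_constant),
    birth_year_range = as.integer(birth_year_range),
    refresh_birth_range = as.integer(refresh_birth_range),
    wave_years = as.integer(wave_years),
    attrition_hazard = rep_len(attrition_hazard, n_follow),
    attrition_age_slope = attrition_age_slope,
    attrition_class_shift = attrition_class_shift,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  # config invariant: curve-implied probabilities stay inside (0,1) over the
  # design's age span
  pr <- evaluate_item_curves(cfg, c(50, 95))
  if (any(pr <= 1e-9 | pr >= 1 - 1e-9))
    stopf("item_curves imply probabilities outside (0,1) over ages 50-95")
  cfg
}

#' Evaluate class-conditional marker prevalence curves at given ages
#'
#' @param config A [synthetic_config()].
#' @param ages Ages in years, within `[45, 100]`.
#' @return Array `class x item x age` of prevalences in (0,1).
#' @export
evaluate_item_curves <- function(config, ages) {
  if (any(ages < 45 | ages > 100)) stopf("ages must lie within [45, 100]")
  s <- config$s_true
  a <- config$item_curves$intercept
  b <- config$item_curves$slope
  out <- array(NA_real_, dim = c(s, ncol(a), length(ages)),
               dimnames = list(class = paste0("class_", seq_len(s)),
                               item = paste0("marker_", seq_len(ncol(a))),
                               age = ages))
  for (k in seq_along(ages)) out[, , k] <- stats::plogis(a + b * ages[k])
  if (any(out <= 1e-12 | out >= 1 - 1e-12))
    stopf("curve parameters produce probabilities outside (0,1)")
  out
}

#' Generate a synthetic aging panel with known latent structure
#'
#' Draws a long-format panel emulating a four-wave aging survey: baseline
#' entrants with birth year uniform over `birth_year_range` (age >= 50 at
#' entry), a refreshment sample first interviewed at wave 3, permanent
#' age-dependent attrition, and nine binary household markers drawn
#' independently given (class, age) from the configured logistic curves --
#' exactly the conditional-independence structure the latent class model
#' assumes, so parameter recovery is a clean test of the estimator.
#'
#' @param config A [synthetic_config()].
#' @param schedule A [design_schedule()]; supplies the nominal column ages at
#'   which the generating probabilities are tabulated in `true_params`.
#' @return An object of class `true_population`: list with `panel` (data frame
#'   `person_id, wave_year, age, sex, marker_1..marker_9`), `true_class`
#'   (named integer vector), `true_params` (class x 10 items x 9 time points
#'   array of generating probabilities, item 10 = sex), and `config`.
#' @export
generate_population <- function(config, schedule = design_schedule()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    wy <- config$wave_years
    n_w <- length(wy)
    # baseline entrants: uniform birth year, at least 50 at wave 1
    lo_b <- config$birth_year_range[1]
    hi_b <- min(config$birth_year_range[2], wy[1] - 50L)
    if (lo_b > hi_b) stopf("birth_year_range admits no baseline entrant aged >= 50")
    birth <- sample(lo_b:hi_b, config$n_baseline, replace = TRUE)
    entry <- rep(wy[1], config$n_baseline)
    if (config$n_refresh > 0) {
      lo_r <- config$refresh_birth_range[1]
      hi_r <- min(config$refresh_birth_range[2], wy[3] - 50L)
      if (lo_r > hi_r) stopf("refresh_birth_range admits no refreshment entrant aged >= 50")
      birth <- c(birth, sample(lo_r:hi_r, config$n_refresh, replace = TRUE))
      entry <- c(entry, rep(wy[3], config$n_refresh))
    }
    n <- length(birth)
    person_id <- sprintf("P%06d", seq_len(n))
    cls <- sample.int(config$s_true, n, replace = TRUE, prob = config$class_proportions)
    sex_person <- stats::rbinom(n, 1L, config$sex_prob[cls])

    # wave participation with permanent dropout
    present <- matrix(FALSE, n, n_w)
    present[cbind(seq_len(n), match(entry, wy))] <- TRUE
    for (k in 2:n_w) {
      cand <- present[, k - 1L] & entry < wy[k]
      if (!any(cand)) next
      h <- config$attrition_hazard[k - 1L]
      age_k <- wy[k] - birth[cand]
      p_drop <- if (h <= 0) rep(0, sum(cand)) else if (h >= 1) rep(1, sum(cand)) else
        stats::plogis(stats::qlogis(h) + config$attrition_age_slope * (age_k - 70) +
                      config$attrition_class_shift[cls[cand]])
      keep <- stats::rbinom(sum(cand), 1L, 1 - p_drop) == 1L
      present[cand, k] <- keep
    }

    idx <- which(present, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    p_row <- idx[, 1L]
    w_row <- idx[, 2L]
    age <- wy[w_row] - birth[p_row]
    sex_rec <- if (config$sex_time_constant) sex_person[p_row] else
      stats::rbinom(length(p_row), 1L, config$sex_prob[cls[p_row]])
    panel <- data.frame(person_id = person_id[p_row],
                        wave_year = wy[w_row],
                        age = age,
                        sex = sex_rec,
                        stringsAsFactors = FALSE)
    a <- config$item_curves$intercept
    b <- config$item_curves$slope
    for (j in 1:9) {
      pj <- stats::plogis(a[cls[p_row], j] + b[cls[p_row], j] * age)
      panel[[paste0("marker_", j)]] <- stats::rbinom(length(pj), 1L, pj)
    }

    true_params <- array(NA_real_, dim = c(config$s_true, 10L, schedule$n_columns),
                         dimnames = list(class = paste0("class_", seq_len(config$s_true)),
                                         item = c(paste0("marker_", 1:9), "sex"),
                                         time = seq_len(schedule$n_columns)))
    curves <- evaluate_item_curves(config, schedule$nominal_ages)
    true_params[, 1:9, ] <- aperm(curves, c(1, 2, 3))
    true_params[, 10L, ] <- matrix(config$sex_prob, config$s_true, schedule$n_columns)

    structure(list(panel = panel,
                   true_class = stats::setNames(cls, person_id),
                   true_params = true_params,
                   config = config),
              class = "true_population")
  })
}

#' @export
print.true_population <- function(x, ...) {
  cat("Synthetic panel population\n")
  cat("  persons:  ", length(x$true_class), " (", x$config$n_baseline, " baseline + ",
      x$config$n_refresh, " refreshment)\n", sep = "")
  cat("  records:  ", nrow(x$panel), "\n", sep = "")
  cat("  classes:  ", x$config$s_true, " with proportions ",
      paste(format(x$config$class_proportions), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic population to CSV
#'
#' Emits the long panel (`person_id, wave_year, age, sex, marker_1..marker_9`)
#' and a separate ground-truth file (`person_id, true_class`).
#'
#' @param population A [generate_population()] result.
#' @param panel_path,truth_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_population <- function(population, panel_path, truth_path) {
  stopifnot(inherits(population, "true_population"))
  utils::write.csv(population$panel, panel_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(person_id = names(population$true_class),
                              true_class = unname(population$true_class)),
                   truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(panel = panel_path, truth = truth_path))
}
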