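#' Read a long-format panel CSV
#'
#' Expects the documented header `person_id, wave_year, age, sex,
#' marker_1..marker_9`. Rows with malformed ages or non-binary marker/sex
#' values are rejected with line-numbered diagnostics (messages), and the
#' rejected rows are attached as attribute `rejected`.
#'
#' @param path CSV path.
#' @return A validated panel data frame.
#' @export
read_panel <- function(path) {
  req <- c("person_id", "wave_year", "age", "sex", paste0("marker_", 1:9))
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stopf("cannot read panel CSV %s: %s", path, conditionMessage(e)))
  miss <- setdiff(req, names(d))
  if (length(miss)) stopf("panel %s is missing required columns: %s",
                          path, paste(miss, collapse = ", "))
  if (!nrow(d)) stopf("panel %s has a header but no records", path)
  bad_reason <- rep(NA_character_, nrow(d))
  age_ok <- is.finite(suppressWarnings(as.numeric(d$age))) &
    d$age >= 0 & d$age <= 130
  bad_reason[!age_ok] <- "malformed age"
  for (col in c("sex", paste0("marker_", 1:9))) {
    ok <- d[[col]] %in% c(0, 1)
    bad_reason[!ok & is.na(bad_reason)] <- paste0("non-binary ", col)
  }
  wave_ok <- is.finite(suppressWarnings(as.numeric(d$wave_year)))
  bad_reason[!wave_ok & is.na(bad_reason)] <- "malformed wave_year"
  bad <- !is.na(bad_reason)
  if (any(bad)) {
    lines <- which(bad) + 1L  # header offset
    for (k in utils::head(which(bad), 10))
      message(sprintf("rejecting line %d: %s", k + 1L, bad_reason[k]))
    message(sum(bad), " row(s) rejected, ", sum(!bad), " kept")
  }
  out <- d[!bad, , drop = FALSE]
  if (!nrow(out)) stopf("panel %s has no valid records", path)
  attr(out, "rejected") <- data.frame(line = which(bad) + 1L,
                                      reason = bad_reason[bad],
                                      stringsAsFactors = FALSE)
  out
}

#' Serialise a fitted model to JSON
#'
#' Stores the class count, class proportions, item-probability array (as a
#' flat vector with dimensions), log-likelihood, convergence info, and
#' settings. Numbers are written at full precision.
#'
#' @param model A fitted [fit_mglca()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "mglca"))
  obj <- list(
    n_classes = model$params$n_classes,
    class_proportions = model$params$class_proportions,
    item_probs = as.vector(model$params$item_probs),
    item_probs_dim = dim(model$params$item_probs),
    loglik = model$loglik,
    n_obs_used = model$n_obs_used,
    converged = model$converged,
    n_iter = model$n_iter,
    n_starts = model$n_starts,
    best_start = model$best_start,
    settings = model$settings
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `seed` (mandatory), `s_range`, `n_starts`, `tol`,
#' `max_iter`, `panel` (path to a long panel CSV; when absent a synthetic
#' panel is generated), and `synthetic` (a mapping of [synthetic_config()]
#' arguments, e.g. `n_baseline`, `n_refresh`, `s_true`, `class_proportions`,
#' `attrition_hazard`).
#'
#' @param path YAML path.
#' @return A validated configuration list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stopf("run config must set a seed")
  if (!is.null(cfg$panel) && !file.exists(cfg$panel))
    stopf("panel path does not resolve: %s", cfg$panel)
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (unless a panel is supplied) -> rearrange -> count tables
#' -> class enumeration -> profiles for the BIC-optimal class count, writing
#' every artifact plus a manifest with seeds and MD5 hashes; rerunning with
#' the same configuration reproduces identical artifact hashes. Artifacts are
#' written via write-then-rename so a failed stage never leaves a partial
#' file. All randomness derives from the single root `seed`.
#'
#' @param config A list as returned by [read_run_config()], or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @param schedule A [design_schedule()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, schedule = design_schedule()) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stopf("config must set a seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  s_range <- config$s_range %||% 1:4
  n_starts <- config$n_starts %||% 20
  tol <- config$tol %||% 1e-6
  max_iter <- config$max_iter %||% 1000
  artifacts <- character(0)

  emit <- function(writer, file) {
    tmp <- file.path(out_dir, paste0(".tmp_", file))
    writer(tmp)
    file.rename(tmp, file.path(out_dir, file))
    artifacts <<- c(artifacts, file)
  }

  if (is.null(config$panel)) {
    message("[simulate] generating synthetic panel")
    syn_args <- config$synthetic %||% list()
    syn_args$seed <- derive_seed(seed, 1L)
    syn <- do.call(synthetic_config, syn_args)
    pop <- generate_population(syn, schedule)
    panel <- pop$panel
    emit(function(p) utils::write.csv(panel, p, row.names = FALSE, quote = FALSE), "panel.csv")
    emit(function(p) utils::write.csv(
      data.frame(person_id = names(pop$true_class), true_class = unname(pop$true_class)),
      p, row.names = FALSE, quote = FALSE), "truth.csv")
  } else {
    message("[read] loading panel from ", config$panel)
    panel <- read_panel(config$panel)
  }

  message("[rearrange] building the accelerated layout")
  ald <- rearrange(panel, schedule)
  emit(function(p) write_ald_csv(ald, p), "ald.csv")
  ct <- count_tables(panel, schedule)
  emit(function(p) utils::write.csv(ct$wave_by_age, p), "counts_wave_by_age.csv")
  emit(function(p) utils::write.csv(ct$cohort_by_age, p), "counts_cohort_by_age.csv")

  message("[select] enumerating classes S = ", paste(range(s_range), collapse = ".."))
  sel <- enumerate_classes(ald, s_range, n_starts = n_starts, tol = tol,
                           max_iter = max_iter, seed = derive_seed(seed, 2L))
  emit(function(p) utils::write.csv(as.data.frame(sel), p, row.names = FALSE), "selection.csv")
  models <- attr(sel, "models")
  for (nm in names(models)) {
    emit(local({
      m <- models[[nm]]
      function(p) write_model_json(m, p)
    }), paste0("model_", nm, ".json"))
  }

  best_S <- attr(sel, "best_bic_S")
  message("[profile] trajectory profiles for BIC-optimal S = ", best_S)
  best <- models[[paste0("S", best_S)]]
  prof <- class_profiles(best, ald, weighting = "posterior")
  emit(function(p) utils::write.csv(profile_report(prof, schedule), p, row.names = FALSE),
       "profiles.csv")

  manifest <- list(
    package = "aldlca",
    version = as.character(utils::packageVersion("aldlca")),
    seed = seed,
    s_range = as.integer(s_range),
    best_bic_S = as.integer(best_S),
    artifacts = lapply(stats::setNames(artifacts, artifacts), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  emit(function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA),
       "manifest.json")
  invisible(manifest)
}
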