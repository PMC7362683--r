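#' Marker prevalence by time point
#'
#' For each (item, time-point) cell: the share of observed cells with value
#' "present", together with the observed-cell count. Cells observed for no
#' person are `NA` (not 0).
#'
#' @param ald An [ald_matrix()].
#' @return List of class `marker_prevalence` with `prevalence` and `n_obs`
#'   (items x time matrices).
#' @export
marker_prevalence <- function(ald) {
  stopifnot(inherits(ald, "ald_matrix"))
  if (!nrow(ald$values)) stopf("ald is empty")
  dm <- ald_design_matrices(ald)
  n_obs <- colSums(dm$O)
  prev <- ifelse(n_obs > 0, colSums(dm$Y) / pmax(n_obs, 1), NA_real_)
  dn <- list(item = ald$item_names, time = seq_len(ald$n_time))
  structure(list(prevalence = matrix(prev, ald$n_items, ald$n_time, dimnames = dn),
                 n_obs = matrix(n_obs, ald$n_items, ald$n_time, dimnames = dn)),
            class = "marker_prevalence")
}

#' @export
print.marker_prevalence <- function(x, digits = 3, ...) {
  cat("Marker prevalence by time point (share of observed cells)\n")
  print(round(x$prevalence, digits))
  invisible(x)
}

#' Per-class trajectory profiles of the markers
#'
#' Describes each latent class's household-composition trajectory: for every
#' (class, item, time-point) cell, the prevalence of the marker among class
#' members. With `weighting = "posterior"` the mean is weighted by the
#' posterior class-membership probabilities; with `"modal"` it is the plain
#' mean among modally assigned persons. Each cell carries its effective sample
#' size (total weight of contributing persons); cells with no contributing
#' observation are `NA`.
#'
#' @param model A fitted [fit_mglca()] object.
#' @param ald The [ald_matrix()] the model was fitted on.
#' @param weighting `"posterior"` (default) or `"modal"`.
#' @return List of class `class_profiles`: `profile` (class x item x time),
#'   `n_eff` (same shape), `weighting`, `class_proportions`.
#' @export
class_profiles <- function(model, ald, weighting = c("posterior", "modal")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(model, "mglca"), inherits(ald, "ald_matrix"))
  if (nrow(model$posteriors) != nrow(ald$values))
    stopf("model was not fitted on this ald (person counts differ)")
  S <- model$params$n_classes
  W <- if (weighting == "posterior") model$posteriors else {
    cl <- classify(model)$class
    mw <- matrix(0, nrow(ald$values), S)
    mw[cbind(seq_along(cl), cl)] <- 1
    mw
  }
  if (weighting == "modal" && any(colSums(W) == 0))
    warning("class(es) with zero assigned members: ",
            paste(which(colSums(W) == 0), collapse = ", "))
  dm <- ald_design_matrices(ald)
  num <- crossprod(dm$Y, W)   # cells x S
  den <- crossprod(dm$O, W)
  prof <- ifelse(den > 0, num / pmax(den, 1e-300), NA_real_)
  dn <- list(class = paste0("class_", seq_len(S)), item = ald$item_names,
             time = seq_len(ald$n_time))
  arr <- array(NA_real_, dim = c(S, ald$n_items, ald$n_time), dimnames = dn)
  ne <- array(0, dim = c(S, ald$n_items, ald$n_time), dimnames = dn)
  for (s in seq_len(S)) {
    arr[s, , ] <- matrix(prof[, s], ald$n_items, ald$n_time)
    ne[s, , ] <- matrix(den[, s], ald$n_items, ald$n_time)
  }
  structure(list(profile = arr, n_eff = ne, weighting = weighting,
                 class_proportions = model$params$class_proportions),
            class = "class_profiles")
}

#' Long-format export of trajectory profiles
#'
#' One row per (class, item, time-point) cell -- including explicitly
#' not-available rows for unobserved cells, preserving the full grid -- with
#' the nominal mean age of the column for axis labelling.
#'
#' @param profiles A [class_profiles()] result.
#' @param schedule Optional [design_schedule()] supplying nominal column ages;
#'   the time index is used when absent.
#' @return Data frame with columns
#'   `class, item, time, mean_age, prevalence, n_effective`.
#' @export
profile_report <- function(profiles, schedule = NULL) {
  stopifnot(inherits(profiles, "class_profiles"))
  d <- dim(profiles$profile)
  ages <- if (is.null(schedule)) seq_len(d[3]) else schedule$nominal_ages
  grid <- expand.grid(class = seq_len(d[1]), item = seq_len(d[2]), time = seq_len(d[3]))
  items <- dimnames(profiles$profile)$item %||% paste0("item_", seq_len(d[2]))
  data.frame(class = grid$class,
             item = items[grid$item],
             time = grid$time,
             mean_age = ages[grid$time],
             prevalence = profiles$profile[as.matrix(grid)],
             n_effective = profiles$n_eff[as.matrix(grid)],
             stringsAsFactors = FALSE)
}

#' Mixture-consistency check of posterior-weighted profiles
#'
#' At every observed cell, the average of the per-class posterior-weighted
#' profiles, weighted by each class's posterior mass in that cell, equals the
#' overall marker prevalence (an exact identity because posterior rows sum
#' to 1); the function returns the largest absolute deviation, which should be
#' at machine-precision level for posterior weighting.
#'
#' @param profiles A posterior-weighted [class_profiles()] result.
#' @param prevalence The matching [marker_prevalence()] result.
#' @return Maximum absolute deviation over observed cells.
#' @export
mixture_check <- function(profiles, prevalence) {
  stopifnot(inherits(profiles, "class_profiles"), inherits(prevalence, "marker_prevalence"))
  tot_w <- apply(profiles$n_eff, c(2, 3), sum)
  wavg <- apply(profiles$profile * profiles$n_eff, c(2, 3), sum) / pmax(tot_w, 1e-300)
  obs <- prevalence$n_obs > 0
  max(abs(wavg[obs] - prevalence$prevalence[obs]))
}

#' Plot per-class trajectory profiles
#'
#' Base-graphics line panels: one panel per item, age on the x axis, one line
#' per class.
#'
#' @param x A [class_profiles()] result.
#' @param schedule Optional [design_schedule()] for the age axis.
#' @param items Items to plot (indices); defaults to all.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.class_profiles <- function(x, schedule = NULL, items = NULL, ...) {
  d <- dim(x$profile)
  ages <- if (is.null(schedule)) seq_len(d[3]) else schedule$nominal_ages
  items <- items %||% seq_len(d[2])
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(items)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  labs <- dimnames(x$profile)$item
  for (i in items) {
    graphics::matplot(ages, t(x$profile[, i, ]), type = "b", pch = 16, lty = 1,
                      xlab = "age", ylab = "prevalence", ylim = c(0, 1),
                      main = labs[i], ...)
  }
  invisible(x)
}
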