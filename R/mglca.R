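#' Parameters of the invariance-restricted multigroup latent class model
#'
#' The model assumes, given latent class membership, local independence of all
#' binary indicators across items and time points, with class proportions and
#' class-conditional item probabilities restricted equal across cohorts (the
#' fully invariant, "completely equivalent" specification). Under that
#' restriction the parameter set contains no group index at all: a simplex of
#' `S` class proportions and an `S x items x time` array of probabilities that
#' an indicator is "present" given class.
#'
#' @param class_proportions Simplex of length `S` (sums to 1 within 1e-10).
#' @param item_probs Array `S x n_items x n_time` of probabilities, each inside
#'   `[1e-6, 1 - 1e-6]` after clamping.
#' @return An object of class `mglca_params`.
#' @export
mglca_params <- function(class_proportions, item_probs) {
  if (length(dim(item_probs)) == 2L) item_probs <- array(item_probs, dim = c(dim(item_probs), 1L))
  S <- length(class_proportions)
  if (dim(item_probs)[1L] != S) stopf("item_probs must have one slice per class")
  if (abs(sum(class_proportions) - 1) > 1e-10) stopf("class_proportions must sum to 1")
  if (any(class_proportions < 0)) stopf("class_proportions must be non-negative")
  item_probs[] <- clamp_prob(item_probs)
  structure(list(class_proportions = as.numeric(class_proportions),
                 item_probs = item_probs,
                 n_classes = S,
                 n_items = dim(item_probs)[2L],
                 n_time = dim(item_probs)[3L]),
            class = "mglca_params")
}

# flat cells x S matrix of item probabilities (cells ordered item-fastest,
# matching ald_matrix columns)
flat_item_probs <- function(params) {
  S <- params$n_classes
  m <- matrix(NA_real_, params$n_items * params$n_time, S)
  for (s in seq_len(S)) m[, s] <- as.vector(params$item_probs[s, , ])
  m
}

unflatten_item_probs <- function(P, n_items, n_time) {
  S <- ncol(P)
  arr <- array(NA_real_, dim = c(S, n_items, n_time))
  for (s in seq_len(S)) arr[s, , ] <- matrix(P[, s], n_items, n_time)
  arr
}

check_dims <- function(params, ald) {
  if (params$n_items != ald$n_items || params$n_time != ald$n_time)
    stopf("parameter grid (%d x %d) does not match data grid (%d x %d)",
          params$n_items, params$n_time, ald$n_items, ald$n_time)
}

# person x S matrix of per-class log-likelihood contributions over each
# person's observed cells
class_logliks <- function(params, ald) {
  check_dims(params, ald)
  dm <- ald_design_matrices(ald)
  P <- clamp_prob(flat_item_probs(params))
  dm$Y %*% log(P) + (dm$O - dm$Y) %*% log1p(-P)
}

#' Observed-data log-likelihood of the latent class model
#'
#' Sums, over persons, the log of the class-proportion-weighted product of
#' Bernoulli terms restricted to each person's observed cells; the planned
#' missingness of the accelerated design enters only through that restriction
#' (missing at random by design). Persons with no observed cells contribute 0.
#'
#' @param params An [mglca_params()].
#' @param ald An [ald_matrix()].
#' @return Scalar log-likelihood.
#' @export
observed_loglik <- function(params, ald) {
  ll <- class_logliks(params, ald) +
    matrix(log(params$class_proportions), nrow(ald$values), params$n_classes, byrow = TRUE)
  has_obs <- rowSums(ald$observed) > 0
  sum(row_log_sum_exp(ll[has_obs, , drop = FALSE]))
}

#' E step: posterior class-membership probabilities
#'
#' Bayes' rule per person over the observed cells, accumulated in log space so
#' that long response patterns never underflow. A person with no observed
#' cells receives the prior class proportions as posterior.
#'
#' @inheritParams observed_loglik
#' @return Person x class matrix with rows summing to 1; the observed-data
#'   log-likelihood is attached as attribute `loglik`.
#' @export
e_step <- function(params, ald) {
  ll <- class_logliks(params, ald) +
    matrix(log(params$class_proportions), nrow(ald$values), params$n_classes, byrow = TRUE)
  lse <- row_log_sum_exp(ll)
  post <- exp(ll - lse)
  has_obs <- rowSums(ald$observed) > 0
  structure(post, loglik = sum(lse[has_obs]))
}

#' M step: invariance-restricted parameter update
#'
#' Pools all cohorts in a single posterior-weighted update (that pooling *is*
#' the equality restriction): class proportions are the mean posterior over
#' persons with at least one observed cell, and each item probability is the
#' posterior-weighted mean of the observed values in that cell. Cells observed
#' for no person keep their previous value and are flagged.
#'
#' @param posteriors Person x class matrix with rows summing to 1.
#' @param ald An [ald_matrix()].
#' @param previous Optional [mglca_params()] supplying values for cells with no
#'   observations (0.5 is used when absent).
#' @return An [mglca_params()]; unsupported cells are listed in attribute
#'   `empty_cells`.
#' @export
m_step <- function(posteriors, ald, previous = NULL) {
  posteriors <- as.matrix(posteriors)
  if (max(abs(rowSums(posteriors) - 1)) > 1e-8) stopf("posterior rows must sum to 1")
  dm <- ald_design_matrices(ald)
  has_obs <- rowSums(ald$observed) > 0
  mass <- colSums(posteriors[has_obs, , drop = FALSE])
  if (any(mass < 1e-8)) stopf("degenerate class (posterior mass < 1e-8); restart advised")
  pi_new <- mass / sum(has_obs)
  num <- crossprod(dm$Y, posteriors)   # cells x S
  den <- crossprod(dm$O, posteriors)
  P <- num / den
  empty <- colSums(dm$O) == 0
  if (any(empty)) {
    fill <- if (is.null(previous)) 0.5 else flat_item_probs(previous)[empty, , drop = FALSE]
    P[empty, ] <- fill
  }
  P <- clamp_prob(P)
  out <- mglca_params(pi_new, unflatten_item_probs(P, ald$n_items, ald$n_time))
  attr(out, "empty_cells") <- which(empty)
  out
}

init_params <- function(ald, S) {
  dm <- ald_design_matrices(ald)
  marg <- colSums(dm$Y) / pmax(colSums(dm$O), 1)
  marg[colSums(dm$O) == 0] <- 0.5
  P <- matrix(marg, length(marg), S) +
    matrix(stats::runif(length(marg) * S, -0.15, 0.15), length(marg), S)
  P <- pmin(pmax(P, 0.05), 0.95)
  mglca_params(rep(1 / S, S), unflatten_item_probs(P, ald$n_items, ald$n_time))
}

#' Fit the invariance-restricted latent class model by EM
#'
#' Runs `n_starts` EM chains from perturbed-marginal initialisations and keeps
#' the chain with the highest converged log-likelihood. Convergence is declared
#' when the relative log-likelihood change falls below `tol`. Classes are
#' relabelled by descending class proportion after fitting. The fit is a pure
#' function of (`ald`, `n_classes`, settings, `seed`).
#'
#' @param ald An [ald_matrix()].
#' @param n_classes Number of latent classes `S >= 1`.
#' @param n_starts Number of random starts (ignored for `S = 1`, which has a
#'   closed-form solution).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Integer seed for the initialisations.
#' @param verbose Print per-start progress.
#' @return An object of class `mglca`: `params`, `loglik`, `n_obs_used`
#'   (persons contributing at least one observed cell), `posteriors`,
#'   `converged`, `n_iter`, `n_starts`, `best_start`, `loglik_trace` (best
#'   chain), and the settings.
#' @export
fit_mglca <- function(ald, n_classes, n_starts = 20, tol = 1e-6, max_iter = 1000,
                      seed = NULL, verbose = FALSE) {
  stopifnot(inherits(ald, "ald_matrix"), n_classes >= 1)
  n <- nrow(ald$values)
  has_obs <- rowSums(ald$observed) > 0
  n_obs_used <- sum(has_obs)
  if (n_obs_used < 1) stopf("no person has any observed cell")

  if (n_classes == 1L) {
    dm <- ald_design_matrices(ald)
    marg <- colSums(dm$Y) / pmax(colSums(dm$O), 1)
    marg[colSums(dm$O) == 0] <- 0.5
    params <- mglca_params(1, unflatten_item_probs(cbind(clamp_prob(marg)),
                                                   ald$n_items, ald$n_time))
    ll <- observed_loglik(params, ald)
    return(new_mglca(params, ll, n_obs_used, matrix(1, n, 1), TRUE, 1L, 1L, 1L, ll,
                     list(n_starts = 1L, tol = tol, max_iter = max_iter, seed = seed)))
  }

  best <- NULL
  with_seed(seed, {
    for (k in seq_len(n_starts)) {
      chain <- tryCatch(
        run_em_chain(ald, n_classes, tol, max_iter),
        error = function(e) NULL)
      if (verbose && !is.null(chain))
        message(sprintf("start %d: loglik %.4f (%s, %d iterations)", k, chain$loglik,
                        if (chain$converged) "converged" else "not converged", chain$n_iter))
      if (is.null(chain)) next
      better <- is.null(best) ||
        (chain$converged && !best$converged) ||
        (chain$converged == best$converged && chain$loglik > best$loglik)
      if (better) { best <- chain; best$start <- k }
    }
  })
  if (is.null(best)) stopf("every EM start failed (degenerate classes); increase n_starts")

  ord <- order(best$params$class_proportions, decreasing = TRUE)
  params <- mglca_params(best$params$class_proportions[ord],
                         best$params$item_probs[ord, , , drop = FALSE])
  post <- best$posteriors[, ord, drop = FALSE]
  new_mglca(params, best$loglik, n_obs_used, post, best$converged, best$n_iter,
            n_starts, best$start, best$trace,
            list(n_starts = n_starts, tol = tol, max_iter = max_iter, seed = seed))
}

run_em_chain <- function(ald, S, tol, max_iter) {
  params <- init_params(ald, S)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    post <- e_step(params, ald)
    ll <- attr(post, "loglik")
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    params <- m_step(post, ald, previous = params)
    ll_old <- ll
  }
  list(params = params, loglik = ll, posteriors = unclass(post),
       converged = converged, n_iter = iter, trace = trace)
}

new_mglca <- function(params, loglik, n_obs_used, posteriors, converged, n_iter,
                      n_starts, best_start, trace, settings) {
  structure(list(params = params, loglik = loglik, n_obs_used = n_obs_used,
                 posteriors = posteriors, converged = converged, n_iter = n_iter,
                 n_starts = n_starts, best_start = best_start,
                 loglik_trace = trace, settings = settings),
            class = "mglca")
}

#' @export
print.mglca <- function(x, ...) {
  cat("Multigroup latent class model (full invariance across cohorts)\n")
  cat(sprintf("  classes:    %d\n", x$params$n_classes))
  cat(sprintf("  loglik:     %.3f  (-2logL = %.1f)\n", x$loglik, -2 * x$loglik))
  cat(sprintf("  persons:    %d with >= 1 observed cell\n", x$n_obs_used))
  cat(sprintf("  proportions: %s\n", paste(sprintf("%.3f", x$params$class_proportions), collapse = ", ")))
  cat(sprintf("  converged:  %s after %d iterations (best of %d starts: #%d)\n",
              x$converged, x$n_iter, x$n_starts, x$best_start))
  invisible(x)
}

#' Modal classification and per-class posterior quality
#'
#' Assigns each person to the class with the largest posterior probability
#' (ties break to the lower class index and are flagged) and summarises, per
#' class, the minimum, mean, and maximum posterior probability of the assigned
#' class among its members -- the classification-quality range reported
#' alongside enumeration statistics.
#'
#' @param model A fitted [fit_mglca()] object, or a bare posterior matrix.
#' @return List with `class` (modal assignment), `tie` (logical), and
#'   `summary` (data frame: class, n_assigned, post_min, post_mean, post_max).
#' @export
classify <- function(model) {
  post <- if (inherits(model, "mglca")) model$posteriors else as.matrix(model)
  S <- ncol(post)
  assign <- max.col(post, ties.method = "first")
  best_p <- post[cbind(seq_len(nrow(post)), assign)]
  tie <- rowSums(abs(post - best_p) < 1e-12) > 1L
  summ <- data.frame(class = seq_len(S), n_assigned = 0L,
                     post_min = NA_real_, post_mean = NA_real_, post_max = NA_real_)
  for (s in seq_len(S)) {
    members <- assign == s
    summ$n_assigned[s] <- sum(members)
    if (any(members)) {
      p <- best_p[members]
      summ$post_min[s] <- min(p); summ$post_mean[s] <- mean(p); summ$post_max[s] <- max(p)
    }
  }
  list(class = assign, tie = tie, summary = summ)
}

#' Check the cohort-invariance contract of a fitted model
#'
#' Under full invariance the fitted parameters carry no cohort index, so (a)
#' two persons with identical observed response patterns but different cohort
#' labels must receive identical posteriors, and (b) model-implied class
#' proportions are identical across groups by construction. The check
#' duplicates a sample of persons into a different cohort, recomputes their
#' posteriors, and reports the maximum absolute difference, together with the
#' empirical (posterior-weighted) class composition per group for diagnostics.
#'
#' @param model A fitted [fit_mglca()] object.
#' @param ald The [ald_matrix()] the model was fitted on.
#' @param n_probe Number of persons to duplicate (capped at the sample size).
#' @return List with `max_posterior_diff`, `class_by_group` (group x class
#'   shares), and `max_group_share_gap` (largest across-group difference of a
#'   class share).
#' @export
invariance_check <- function(model, ald, n_probe = 100L) {
  stopifnot(inherits(model, "mglca"), inherits(ald, "ald_matrix"))
  n <- nrow(ald$values)
  probe <- seq_len(min(n_probe, n))
  dup <- ald
  dup$values <- ald$values[probe, , drop = FALSE]
  dup$observed <- ald$observed[probe, , drop = FALSE]
  dup$person_id <- paste0(ald$person_id[probe], "_dup")
  coh <- ald$cohort[probe]
  other <- vapply(coh, function(co) {
    pool <- setdiff(unique(ald$cohort[!is.na(ald$cohort)]), co)
    if (length(pool)) pool[1L] else co
  }, integer(1))
  dup$cohort <- other
  dup$group <- rep(NA_character_, length(probe))
  p_orig <- e_step(model$params, ald)[probe, , drop = FALSE]
  p_dup <- e_step(model$params, dup)
  max_diff <- max(abs(unclass(p_orig) - unclass(p_dup)))

  grp <- ald$group
  grp[is.na(grp)] <- "(none)"
  groups <- sort(unique(grp))
  comp <- matrix(NA_real_, length(groups), model$params$n_classes,
                 dimnames = list(groups, paste0("class_", seq_len(model$params$n_classes))))
  for (g in groups) comp[g, ] <- colMeans(model$posteriors[grp == g, , drop = FALSE])
  gap <- if (length(groups) > 1) max(apply(comp, 2, function(x) diff(range(x)))) else 0
  list(max_posterior_diff = max_diff, class_by_group = comp, max_group_share_gap = gap)
}

#' Align estimated class labels with a reference by permutation search
#'
#' Mixture labels are arbitrary; this finds the label permutation minimising
#' the summed squared difference between estimated and reference
#' class-conditional item probabilities (over cells where both are finite),
#' enumerating all `S!` permutations exactly -- optimal, and cheap for the
#' handful of classes used in practice.
#'
#' @param est,ref Arrays `S x items x time` of item probabilities (an
#'   [mglca_params()] is also accepted).
#' @return List with `perm` (index such that `est[perm[s], , ]` matches class
#'   `s` of `ref`) and `cost`.
#' @export
align_classes <- function(est, ref) {
  if (inherits(est, "mglca_params")) est <- est$item_probs
  if (inherits(ref, "mglca_params")) ref <- ref$item_probs
  S <- dim(est)[1L]
  if (dim(ref)[1L] != S) stopf("est and ref must have the same number of classes")
  cost <- matrix(0, S, S)
  for (a in seq_len(S)) for (b in seq_len(S)) {
    d <- (est[a, , ] - ref[b, , ])^2
    cost[a, b] <- sum(d[is.finite(d)])
  }
  best <- NULL; best_cost <- Inf
  for (p in all_permutations(S)) {
    cc <- sum(cost[cbind(p, seq_len(S))])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  list(perm = unlist(best), cost = best_cost)
}
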