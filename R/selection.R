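#' Number of free parameters of the latent class model
#'
#' In `"all"` mode every cell of the measurement grid carries one threshold per
#' class, giving `(S - 1) + S * n_items * n_time` free parameters (under the
#' default 10 x 9 grid, 90 thresholds per class). In `"observed"` mode only
#' cells observed for at least one person are counted, since thresholds of
#' never-observed cells are not identified by the data. Both counts are
#' reported by [enumerate_classes()] so the ambiguity is transparent.
#'
#' @param S Number of classes.
#' @param ald An [ald_matrix()].
#' @param mode `"all"` (default) or `"observed"`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(S, ald, mode = c("all", "observed")) {
  mode <- match.arg(mode)
  stopifnot(S >= 1)
  n_cells <- if (mode == "all") ald$n_items * ald$n_time else sum(colSums(ald$observed) > 0)
  as.integer((S - 1) + S * n_cells)
}

#' Bayesian information criterion
#'
#' `BIC = -2 logL + n_params * ln(n)`; lower is better. The sample size `n` is
#' the number of persons contributing at least one observed cell (the unit of
#' analysis is the individual, not the person-wave record).
#'
#' @param minus2_loglik Minus twice the maximised log-likelihood.
#' @param n_params Number of free parameters.
#' @param n Sample size, `n >= 1`.
#' @return Scalar BIC.
#' @export
lca_bic <- function(minus2_loglik, n_params, n) {
  if (n < 1) stopf("n must be >= 1")
  minus2_loglik + n_params * log(n)
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum(-p * ln p) / (N * ln S)`, with `0 * ln 0 := 0`: a rescaled measure
#' of classification certainty equal to 1 when every posterior row is a unit
#' vector (perfect separation) and 0 when every row is uniform. Undefined for
#' a single class (`NA` is returned, printed as "-" in selection tables).
#'
#' @param posteriors Person x class matrix with rows summing to 1.
#' @return Scalar in `[0, 1]`, or `NA_real_` when `S = 1`.
#' @export
relative_entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  S <- ncol(posteriors)
  if (S < 2L) return(NA_real_)
  if (max(abs(rowSums(posteriors) - 1)) > 1e-8) stopf("posterior rows must sum to 1")
  p <- posteriors
  h <- -p * log(p)
  h[p == 0] <- 0
  1 - sum(h) / (nrow(p) * log(S))
}

#' Fit a sequence of class counts and tabulate enumeration statistics
#'
#' Fits the invariance-restricted model for each `S` in `S_range` with shared
#' EM settings and reports, per row: -2logL, parameter counts and BIC under
#' both counting modes, relative entropy, the minimum and maximum relative
#' class size (percent), and the range across classes of the average posterior
#' probability among assigned members. A fit that fails to converge is
#' reported with `converged = FALSE` rather than aborting the table.
#'
#' @param ald An [ald_matrix()].
#' @param S_range Ascending class counts to fit.
#' @param n_starts,tol,max_iter EM settings passed to [fit_mglca()].
#' @param seed Root seed; each `S` receives a deterministic child seed.
#' @param keep_models Keep the fitted models as attribute `models`.
#' @return A data frame of class `lca_selection`, with attributes
#'   `best_bic_S` (BIC-minimising `S`, all-cells mode) and `best_entropy_S`.
#' @export
enumerate_classes <- function(ald, S_range = 1:5, n_starts = 20, tol = 1e-6,
                              max_iter = 1000, seed = NULL, keep_models = TRUE) {
  if (!length(S_range) || is.unsorted(S_range, strictly = TRUE))
    stopf("S_range must be non-empty and strictly ascending")
  rows <- vector("list", length(S_range))
  models <- vector("list", length(S_range))
  for (k in seq_along(S_range)) {
    S <- S_range[k]
    m <- fit_mglca(ald, S, n_starts = n_starts, tol = tol, max_iter = max_iter,
                   seed = derive_seed(seed, S))
    cl <- classify(m)
    sizes <- 100 * m$params$class_proportions
    pr <- cl$summary$post_mean
    rows[[k]] <- data.frame(
      S = S,
      minus2_loglik = -2 * m$loglik,
      n_params_all = count_parameters(S, ald, "all"),
      bic_all = lca_bic(-2 * m$loglik, count_parameters(S, ald, "all"), m$n_obs_used),
      n_params_observed = count_parameters(S, ald, "observed"),
      bic_observed = lca_bic(-2 * m$loglik, count_parameters(S, ald, "observed"), m$n_obs_used),
      entropy = relative_entropy(m$posteriors),
      class_size_min_pct = min(sizes),
      class_size_max_pct = max(sizes),
      post_range_min = suppressWarnings(min(pr, na.rm = TRUE)),
      post_range_max = suppressWarnings(max(pr, na.rm = TRUE)),
      converged = m$converged
    )
    models[[k]] <- m
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lca_selection", "data.frame")
  attr(out, "best_bic_S") <- out$S[which.min(out$bic_all)]
  ent <- out$entropy
  attr(out, "best_entropy_S") <- if (all(is.na(ent))) NA_integer_ else out$S[which.max(ent)]
  if (keep_models) attr(out, "models") <- stats::setNames(models, paste0("S", S_range))
  out
}

#' @export
print.lca_selection <- function(x, digits = 3, ...) {
  d <- data.frame(
    Class = x$S,
    `-2logL` = formatC(x$minus2_loglik, format = "f", digits = 1),
    BIC = formatC(x$bic_all, format = "f", digits = 1),
    Entropy = ifelse(is.na(x$entropy), "-", formatC(x$entropy, format = "f", digits = 3)),
    `Class size (%)` = ifelse(x$S == 1, "-",
      paste0(formatC(x$class_size_min_pct, format = "f", digits = 0), " - ",
             formatC(x$class_size_max_pct, format = "f", digits = 0))),
    `Posterior range` = ifelse(x$S == 1, "-",
      paste0(formatC(x$post_range_min, format = "f", digits = 3), " - ",
             formatC(x$post_range_max, format = "f", digits = 3))),
    check.names = FALSE
  )
  print(d, row.names = FALSE)
  cat(sprintf("\nBIC-minimising S = %d; entropy-maximising S = %s\n",
              attr(x, "best_bic_S"),
              ifelse(is.na(attr(x, "best_entropy_S")), "-", attr(x, "best_entropy_S"))))
  if (any(!x$converged))
    cat("warning: S =", paste(x$S[!x$converged], collapse = ", "), "did not converge\n")
  invisible(x)
}
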