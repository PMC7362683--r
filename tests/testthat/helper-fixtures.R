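# shared fixtures: tiny hand-made ALD arrays and pattern-count builders

patterns2 <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))

# complete-data ald (one time point) from response-pattern counts
ald_from_counts <- function(counts, patterns) {
  rows <- patterns[rep(seq_len(nrow(patterns)), counts), , drop = FALSE]
  ald_matrix(rows, n_items = ncol(patterns), n_time = 1L)
}

# ald straight from a values matrix (NA = unobserved), 1 time point
ald_from_matrix <- function(values, n_time = 1L) {
  ald_matrix(as.matrix(values), n_items = ncol(as.matrix(values)) / n_time, n_time = n_time)
}

# small synthetic population + rearranged array, memoised per (n, seed, curves)
small_ald <- local({
  cache <- new.env()
  function(n_baseline = 1200, n_refresh = 300, seed = 7, curves = NULL) {
    key <- paste(n_baseline, n_refresh, seed, is.null(curves))
    if (is.null(cache[[key]])) {
      cfg <- if (is.null(curves)) {
        synthetic_config(n_baseline = n_baseline, n_refresh = n_refresh, seed = seed)
      } else {
        synthetic_config(n_baseline = n_baseline, n_refresh = n_refresh, seed = seed,
                         item_curves = curves)
      }
      pop <- generate_population(cfg)
      cache[[key]] <- list(pop = pop, ald = rearrange(pop$panel, design_schedule()))
    }
    cache[[key]]
  }
})

# RMSE between aligned estimated and generating item probabilities over cells
# observed for at least one person
recovery_errors <- function(model, pop, ald) {
  al <- align_classes(model$params$item_probs, pop$true_params)
  est <- model$params$item_probs[al$perm, , , drop = FALSE]
  obs <- apply(ald$observed, 2, any)
  d2 <- (est - pop$true_params)^2
  S <- dim(est)[1]
  msk <- aperm(array(rep(matrix(obs, ald$n_items, ald$n_time), S),
                     dim = c(ald$n_items, ald$n_time, S)), c(3, 1, 2))
  list(rmse = sqrt(mean(d2[msk])),
       prop_err = max(abs(model$params$class_proportions[al$perm] -
                            pop$config$class_proportions)))
}
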