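test_that("observed likelihood matches direct pattern enumeration", {
  # single class, one person, one observed "present" item at p = 0.5
  ald1 <- ald_from_matrix(matrix(1, 1, 1))
  p1 <- mglca_params(1, array(0.5, c(1, 1, 1)))
  expect_equal(observed_loglik(p1, ald1), log(0.5), tolerance = 1e-12)

  # mixture of identical components: likelihood free of the proportions
  ald2 <- ald_from_counts(c(2, 1, 1, 2), patterns2)
  same <- array(rep(c(0.3, 0.7), each = 1), c(2, 2, 1))
  same[1, , 1] <- c(0.3, 0.7); same[2, , 1] <- c(0.3, 0.7)
  llA <- observed_loglik(mglca_params(c(0.5, 0.5), same), ald2)
  llB <- observed_loglik(mglca_params(c(0.9, 0.1), same), ald2)
  expect_equal(llA, llB, tolerance = 1e-12)

  # 6-person, 2-item complete-data toy vs a hand-expanded sum over the four
  # response patterns (independent arithmetic path)
  counts <- c(2, 1, 0, 3)
  ald6 <- ald_from_counts(counts, patterns2)
  pars <- mglca_params(c(0.6, 0.4), array(c(0.8, 0.2, 0.3, 0.9), c(2, 2, 1)))
  pat_prob <- function(y) {
    0.6 * (0.8^y[1] * 0.2^(1 - y[1])) * (0.3^y[2] * 0.7^(1 - y[2])) +
    0.4 * (0.2^y[1] * 0.8^(1 - y[1])) * (0.9^y[2] * 0.1^(1 - y[2]))
  }
  expected <- sum(counts * apply(patterns2, 1, function(y) log(pat_prob(y))))
  expect_equal(observed_loglik(pars, ald6), expected, tolerance = 1e-10)
})

test_that("the E step is Bayes' rule over observed cells", {
  # one observed "present" item; class 1 nearly always present, class 2 nearly never
  ald <- ald_from_matrix(matrix(1, 1, 1))
  pars <- mglca_params(c(0.5, 0.5), array(c(0.999, 0.001), c(2, 1, 1)))
  post <- e_step(pars, ald)
  expect_equal(unclass(post)[1, ], c(0.999, 0.001), tolerance = 1e-6)

  # a person with every cell missing receives the prior as posterior
  vals <- rbind(c(1, 0), c(NA, NA))
  ald2 <- ald_from_matrix(vals)
  pars2 <- mglca_params(c(0.7, 0.3), array(runif(4, 0.2, 0.8), c(2, 2, 1)))
  post2 <- unclass(e_step(pars2, ald2))
  expect_equal(post2[2, ], c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(rowSums(post2), c(1, 1), tolerance = 1e-10)

  # single class: a column of ones
  pars3 <- mglca_params(1, array(0.4, c(1, 2, 1)))
  expect_equal(unname(unclass(e_step(pars3, ald2))[, 1]), c(1, 1))
})

test_that("the M step pools cohorts into posterior-weighted means", {
  # hard 0/1 posteriors on complete data give within-class sample means
  vals <- rbind(c(1, 1), c(1, 0), c(0, 0), c(0, 1))
  ald <- ald_from_matrix(vals)
  hard <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  pars <- m_step(hard, ald)
  expect_equal(pars$item_probs[1, , 1], c(1 - 1e-6, 0.5), tolerance = 1e-9)
  expect_equal(pars$item_probs[2, , 1], c(1e-6, 0.5), tolerance = 1e-9)

  # uniform posteriors: both classes collapse to the overall mean
  unif <- matrix(0.5, 4, 2)
  pu <- m_step(unif, ald)
  expect_equal(pu$item_probs[1, , 1], pu$item_probs[2, , 1], tolerance = 1e-12)
  expect_equal(pu$item_probs[1, , 1], c(0.5, 0.5), tolerance = 1e-12)

  # fractional posteriors vs hand-computed weighted means
  w <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8), c(0.1, 0.9))
  pw <- m_step(w, ald)
  expect_equal(pw$class_proportions, colMeans(w), tolerance = 1e-12)
  expect_equal(pw$item_probs[1, 1, 1], sum(w[, 1] * vals[, 1]) / sum(w[, 1]), tolerance = 1e-12)
  expect_equal(pw$item_probs[2, 2, 1], sum(w[, 2] * vals[, 2]) / sum(w[, 2]), tolerance = 1e-12)

  # a never-observed cell keeps its previous value and is flagged
  vals3 <- rbind(c(1, NA), c(0, NA))
  ald3 <- ald_from_matrix(vals3)
  prev <- mglca_params(c(0.5, 0.5), array(0.42, c(2, 2, 1)))
  p3 <- m_step(matrix(0.5, 2, 2), ald3, previous = prev)
  expect_identical(unname(attr(p3, "empty_cells")), 2L)
  expect_equal(p3$item_probs[1, 2, 1], 0.42, tolerance = 1e-12)

  expect_error(m_step(rbind(c(1, 0), c(1, 0)), ald3), "degenerate class")
})

test_that("a one-class fit is the closed-form solution", {
  x <- small_ald(n_baseline = 400, n_refresh = 100)
  m1 <- fit_mglca(x$ald, 1)
  dmY <- x$ald$values; dmY[is.na(dmY)] <- 0
  means <- colSums(dmY) / pmax(colSums(x$ald$observed), 1)
  obs <- colSums(x$ald$observed) > 0
  est <- as.vector(sapply(1:9, function(t) m1$params$item_probs[1, , t]))
  expect_equal(est[obs], unname(means[obs]), tolerance = 1e-9)
  expect_equal(m1$loglik, observed_loglik(m1$params, x$ald), tolerance = 1e-9)
  expect_true(all(m1$posteriors == 1))
})

test_that("EM log-likelihood is monotone and the fit deterministic given a seed", {
  x <- small_ald(n_baseline = 400, n_refresh = 100)
  m <- fit_mglca(x$ald, 2, n_starts = 3, seed = 31)
  expect_true(all(diff(m$loglik_trace) >= -1e-10))
  m2 <- fit_mglca(x$ald, 2, n_starts = 3, seed = 31)
  expect_identical(m$loglik, m2$loglik)
  expect_identical(m$params$item_probs, m2$params$item_probs)
  # classes come out ordered by descending proportion
  expect_true(all(diff(m$params$class_proportions) <= 0))
  # posterior rows sum to one
  expect_equal(rowSums(m$posteriors), rep(1, nrow(m$posteriors)), tolerance = 1e-10)
})

test_that("persons with no observed cells change no estimate", {
  x <- small_ald(n_baseline = 400, n_refresh = 100)
  m <- fit_mglca(x$ald, 2, n_starts = 2, seed = 41)
  padded <- x$ald
  extra <- 5L
  padded$values <- rbind(padded$values, matrix(NA_real_, extra, ncol(padded$values)))
  padded$observed <- rbind(padded$observed, matrix(FALSE, extra, ncol(padded$values)))
  padded$person_id <- c(padded$person_id, sprintf("EMPTY%02d", 1:extra))
  padded$cohort <- c(padded$cohort, rep(9L, extra))
  padded$group <- c(padded$group, rep("G2", extra))
  padded$entry_wave <- c(padded$entry_wave, rep(2001L, extra))
  padded$baseline_column <- c(padded$baseline_column, rep(1L, extra))
  mp <- fit_mglca(padded, 2, n_starts = 2, seed = 41)
  expect_equal(mp$loglik, m$loglik, tolerance = 1e-9)
  expect_equal(mp$params$item_probs, m$params$item_probs, tolerance = 1e-9)
  expect_identical(mp$n_obs_used, m$n_obs_used + 0L)
})

test_that("permuting person order leaves the likelihood unchanged", {
  x <- small_ald(n_baseline = 400, n_refresh = 100)
  m <- fit_mglca(x$ald, 2, n_starts = 2, seed = 51)
  set.seed(1)
  perm <- sample(nrow(x$ald$values))
  shuf <- x$ald
  shuf$values <- shuf$values[perm, ]
  shuf$observed <- shuf$observed[perm, ]
  shuf$person_id <- shuf$person_id[perm]
  shuf$cohort <- shuf$cohort[perm]
  expect_lt(abs(observed_loglik(m$params, shuf) - m$loglik), 1e-9)
})

test_that("modal classification reports tie flags and per-class posterior ranges", {
  post <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4))
  cl <- classify(post)
  expect_identical(cl$class, c(1L, 2L, 1L))
  expect_equal(cl$summary$post_min, c(0.6, 0.8))
  expect_equal(cl$summary$post_max, c(0.9, 0.8))
  expect_equal(cl$summary$post_mean, c(0.75, 0.8))
  tied <- classify(rbind(c(0.5, 0.5)))
  expect_identical(tied$class, 1L)
  expect_true(tied$tie[1])
  sharp <- classify(diag(3))
  expect_equal(sharp$summary$post_mean, rep(1, 3))
})

test_that("posteriors carry no cohort information and grouping cannot move the likelihood", {
  x <- small_ald(n_baseline = 400, n_refresh = 100)
  m <- fit_mglca(x$ald, 3, n_starts = 2, seed = 61)
  chk <- invariance_check(m, x$ald)
  expect_lt(chk$max_posterior_diff, 1e-15)
  # identity grouping vs the decade grouping: identical fitted likelihood
  ident <- setNames(as.character(1:12), as.character(1:12))
  ald_id <- group_cohorts(x$ald, ident)
  m_id <- fit_mglca(ald_id, 3, n_starts = 2, seed = 61)
  expect_identical(m_id$loglik, m$loglik)
})

test_that("label alignment finds the generating permutation", {
  set.seed(8)
  truth <- array(runif(3 * 4 * 2, 0.1, 0.9), c(3, 4, 2))
  est <- truth[c(3, 1, 2), , ] + array(rnorm(24, 0, 0.01), c(3, 4, 2))
  # est[s] was built from truth class (3,1,2)[s]; inverting, truth class s is
  # matched by est class perm[s]
  al <- align_classes(est, truth)
  expect_identical(al$perm, c(2L, 3L, 1L))
  expect_lt(max(abs(est[al$perm, , ] - truth)), 0.05)
})
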