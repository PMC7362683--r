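test_that("logistic item curves evaluate and respect monotonicity", {
  cfg <- synthetic_config(n_baseline = 10, n_refresh = 0, s_true = 3, seed = 1)
  flat <- cfg
  flat$item_curves$intercept[] <- 0
  flat$item_curves$slope[] <- 0
  p <- evaluate_item_curves(flat, c(52, 70, 86))
  expect_true(all(abs(p - 0.5) < 1e-12))

  dec <- cfg
  dec$item_curves$slope[] <- -0.1
  dec$item_curves$intercept[] <- 0.1 * 70  # centred so probs stay interior
  pd <- evaluate_item_curves(dec, c(52, 86))
  expect_true(all(pd[, , 2] < pd[, , 1]))
  expect_true(all(pd > 0 & pd < 1))
  expect_error(evaluate_item_curves(cfg, c(30, 52)), "\\[45, 100\\]")
})

test_that("curve endpoints solve the published partner-presence decline", {
  # marginal partner presence: 77.8% at mean age 52, 35.2% at mean age 86;
  # oracle: direct algebraic solution of the 2x2 logit system
  ab <- solve_curve_endpoints(0.778, 52, 0.352, 86)
  slope_expected <- (qlogis(0.352) - qlogis(0.778)) / (86 - 52)
  expect_equal(unname(ab["slope"]), slope_expected, tolerance = 1e-12)
  expect_equal(plogis(ab["intercept"] + ab["slope"] * 52), c(intercept = 0.778), tolerance = 1e-12)
  expect_equal(plogis(ab["intercept"] + ab["slope"] * 86), c(intercept = 0.352), tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(class_proportions = c(0.6, 0.5, 0.1)), "sum to 1")
  expect_error(synthetic_config(n_baseline = 0), "n_baseline")
  expect_error(synthetic_config(wave_years = c(2001, 2003, 2003, 2015)), "increasing")
  bad <- default_item_curves()
  bad$intercept[1, 1] <- 80  # probability 1 to machine precision at all ages
  expect_error(synthetic_config(item_curves = bad), "outside")
})

test_that("a single-class population carries one label and no-attrition panels are complete", {
  cfg1 <- synthetic_config(n_baseline = 60, n_refresh = 0, s_true = 1,
                           class_proportions = 1,
                           item_curves = list(intercept = matrix(0, 1, 9),
                                              slope = matrix(0, 1, 9)),
                           sex_prob = 0.5, attrition_hazard = 0, seed = 3)
  pop1 <- generate_population(cfg1)
  expect_true(all(pop1$true_class == 1L))
  expect_true(all(table(pop1$panel$person_id) == 4L))
  # ages advance by exactly the wave-year gaps
  byp <- split(pop1$panel, pop1$panel$person_id)
  expect_true(all(vapply(byp, function(d) all(diff(d$age) == diff(d$wave_year)), TRUE)))
})

test_that("class shares match the generating proportions within binomial bounds", {
  cfg <- synthetic_config(n_baseline = 10000, n_refresh = 0, s_true = 2,
                          class_proportions = c(0.6, 0.4),
                          item_curves = separated_item_curves(2),
                          sex_prob = c(0.5, 0.5), seed = 11)
  pop <- generate_population(cfg)
  share1 <- mean(pop$true_class == 1L)
  half_width <- qnorm(0.995) * sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(share1 - 0.6), half_width)
})

test_that("the generator is a pure function of its configuration", {
  cfg <- synthetic_config(n_baseline = 300, n_refresh = 80, seed = 21)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$true_class, b$true_class)
  # and leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_population(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("refreshment persons first appear at wave 3 and dropout is permanent", {
  cfg <- synthetic_config(n_baseline = 400, n_refresh = 150, seed = 5)
  pop <- generate_population(cfg)
  byp <- split(pop$panel$wave_year, pop$panel$person_id)
  entries <- vapply(byp, min, 0)
  expect_setequal(unique(entries), c(2001, 2012))
  expect_equal(sum(entries == 2012), 150)
  # monotone participation: observed waves are a prefix of the schedule
  wy <- cfg$wave_years
  ok <- vapply(byp, function(w) {
    sched <- wy[wy >= min(w)]
    identical(sort(w), sched[seq_along(w)])
  }, TRUE)
  expect_true(all(ok))
})

test_that("marginal marker prevalence matches the class mixture of the curves", {
  cfg <- synthetic_config(n_baseline = 50000, n_refresh = 0, seed = 13,
                          attrition_hazard = 0)
  pop <- generate_population(cfg)
  w1 <- pop$panel[pop$panel$wave_year == 2001 & pop$panel$age >= 58 & pop$panel$age <= 61, ]
  cls_w1 <- pop$true_class[w1$person_id]
  for (j in c(1, 6, 9)) {
    # expected mixture at each person's actual age, averaged
    a <- cfg$item_curves$intercept; b <- cfg$item_curves$slope
    pmix <- mean(plogis(a[cls_w1, j] + b[cls_w1, j] * w1$age))
    expect_equal(mean(w1[[paste0("marker_", j)]]), pmix, tolerance = 0.02)
  }
})

test_that("markers are conditionally independent within class and age", {
  cfg <- synthetic_config(n_baseline = 50000, n_refresh = 0, seed = 17,
                          attrition_hazard = 0)
  pop <- generate_population(cfg)
  w1 <- pop$panel[pop$panel$wave_year == 2001, ]
  cls_w1 <- pop$true_class[w1$person_id]
  sub <- w1[cls_w1 == 1 & w1$age == 60, ]
  cors <- cor(as.matrix(sub[, paste0("marker_", c(1, 4, 6, 9))]))
  off <- cors[upper.tri(cors)]
  expect_true(all(abs(off) < 3 / sqrt(nrow(sub))))
})
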