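test_that("the micro-population fractions match hand evaluation", {
  lpA <- micro_lp(correlated = FALSE)
  lpB <- micro_lp(correlated = TRUE)
  # uncorrelated: 1 - 8/12; correlated: 1 - 8/14
  expect_equal(af_backdoor(lpA)$estimate, 1 / 3, tolerance = 1e-12)
  expect_equal(af_backdoor(lpB)$estimate, 3 / 7, tolerance = 1e-12)
  expect_equal(af_weights(lpA), c(1, 1, 3, 3) / 8, tolerance = 1e-12)
  expect_equal(af_who(lpA)$estimate, 1 / 3, tolerance = 1e-12)
  # WHO fraction ignores confounding, bounding the correlated case from below
  expect_equal(af_who(lpB)$estimate, 1 / 3, tolerance = 1e-12)
  expect_lt(af_who(lpB)$estimate, af_backdoor(lpB)$estimate)
  # null exposure
  lp0 <- tibble::tibble(eta_x = 0, eta_w = c(0, 1), eta_z = 0.5)
  expect_equal(af_backdoor(lp0)$estimate, 0)
  expect_equal(af_who(lp0)$estimate, 0)
  expect_error(af_backdoor(lpA[0, ]), "empty")
})

test_that("the weight identity reproduces the direct form to machine precision", {
  set.seed(7)
  for (rep in 1:25) {
    lp <- tibble::tibble(eta_x = stats::rnorm(40, sd = 0.8),
                         eta_w = stats::rnorm(40, sd = 0.4),
                         eta_z = stats::rnorm(40, sd = 0.6))
    w <- af_weights(lp)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(1 - 1 / sum(w * exp(lp$eta_x)), af_backdoor(lp)$estimate,
                 tolerance = 1e-12)
    expect_lte(af_backdoor(lp)$estimate, 1)
  }
  # with no confounders or other risks the weights are uniform
  lp <- tibble::tibble(eta_x = stats::rnorm(10), eta_w = 0, eta_z = 0)
  expect_equal(af_weights(lp), rep(0.1, 10))
})

test_that("the WHO fraction bounds the backdoor fraction by covariance sign", {
  set.seed(11)
  for (rep in 1:50) {
    lp <- tibble::tibble(eta_x = stats::rnorm(30, sd = 0.7),
                         eta_w = stats::rnorm(30, sd = 0.3),
                         eta_z = stats::rnorm(30, sd = 0.5))
    cv <- stats::cov(exp(lp$eta_x), exp(lp$eta_w + lp$eta_z))
    d <- af_backdoor(lp)$estimate - af_who(lp)$estimate
    expect_equal(sign(d), sign(cv))
  }
  # exact equality at zero sample covariance
  expect_equal(af_who(micro_lp())$estimate, af_backdoor(micro_lp())$estimate,
               tolerance = 1e-12)
})

test_that("the age-dependent fraction matches hand sums and limits", {
  bh <- weibull_hazard(2, 50)
  lpA <- micro_lp()
  # frozen by direct evaluation of the two incidence sums at H0(10) = 0.04
  expect_equal(af_age(lpA, bh, 10)$estimate, 0.311754471608615,
               tolerance = 1e-10)
  expect_lt(af_age(lpA, bh, 10)$estimate, 1 / 3)
  # t -> 0 limit recovers the age-independent fraction
  t0 <- 50 * sqrt(1e-6)
  expect_lt(abs(af_age(lpA, bh, t0)$estimate - 1 / 3), 1e-4)
  # zero exposure effect: zero at every horizon
  lp0 <- tibble::tibble(eta_x = 0, eta_w = 0, eta_z = c(0, 1))
  for (t in c(1, 10, 40)) expect_equal(af_age(lp0, bh, t)$estimate, 0)
  # nonincreasing in t for nonnegative exposure effects
  afs <- vapply(seq(1, 60, by = 1),
                function(t) af_age(lpA, bh, t)$estimate, numeric(1))
  expect_true(all(diff(afs) <= 1e-12))
  expect_error(af_age(lpA, bh, 0), "positive")
})

test_that("pairwise and treated-on-treated fractions follow their closed forms", {
  expect_equal(af_pairwise(0.3, 0.3), 0)
  expect_equal(af_pairwise(log(2), log(4)), 0.5)
  expect_equal(af_pairwise(log(4), log(2)), -1)
  expect_equal(af_ett(1), 0)
  expect_equal(af_ett(2), 0.5)
  expect_equal(af_ett(0.5), -1)
  expect_error(af_ett(0), "positive")
})

test_that("attributed cases round as printed in ranked attribution tables", {
  expect_equal(attributed_cases(0.9836, 3113), 3062L)
  expect_equal(attributed_cases(0, 500), 0L)
  expect_equal(attributed_cases(0.5, 200), 100L)
  expect_equal(attributed_cases(-0.29, 272), -79L)
  expect_error(attributed_cases(0.5, -1), "nonnegative")
})

test_that("the protective-scale transform matches its algebra and series", {
  expect_equal(af_flip(0)$exact, 0)
  f <- af_flip(-0.24)
  expect_equal(f$exact, 0.24 / 1.24, tolerance = 1e-12)
  expect_equal(f$first_order, 0.24 * 0.76, tolerance = 1e-12)
  f2 <- af_flip(-0.01)
  expect_equal(f2$exact, 0.01 / 1.01, tolerance = 1e-12)
  expect_lt(abs(f2$exact - f2$first_order), 2 * 0.01^3)
  expect_error(af_flip(1), "< 1")
})

test_that("the rare binary-exposure approximation is linear in prevalence", {
  b0 <- af_binary_approx(0, 2)
  expect_equal(unlist(b0), c(approx = 0, exact = 0))
  b <- af_binary_approx(0.5, 1.1)
  expect_equal(b$approx, 0.05)
  expect_equal(b$exact, 1 - 1 / 1.05, tolerance = 1e-12)
  expect_equal(af_binary_approx(0.25, 1.1)$approx, b$approx / 2)
  # exact form agrees with the backdoor estimator on an uncorrelated
  # binary-exposure population
  p <- 0.3; R <- 1.4
  lp <- tibble::tibble(eta_x = log(R) * c(rep(1, 30), rep(0, 70)),
                       eta_w = 0, eta_z = 0)
  expect_equal(af_backdoor(lp)$estimate, af_binary_approx(p, R)$exact,
               tolerance = 1e-12)
})

test_that("estimates above one and large protective values are policed", {
  expect_error(af_pairwise_result <- causalaf:::new_attribution_result(1.2, "backdoor"),
               "at most 1")
  expect_warning(causalaf:::new_attribution_result(-0.7, "backdoor"),
                 "protective")
})

test_that("the bootstrap interval is seeded, consistent and shrinks with n", {
  gm <- smoking_model()
  co <- simulate_cohort(gm, 2500, seed = 31)
  roles <- roles_of(gm)
  expect_error(bootstrap_af(co, roles, B = 50), "at least 100")
  b1 <- bootstrap_af(co, roles, B = 100, seed = 4)
  b2 <- bootstrap_af(co, roles, B = 100, seed = 4)
  expect_identical(b1, b2)
  expect_lt(b1$conf_low, b1$estimate)
  expect_gt(b1$conf_high, b1$estimate)
  co_big <- simulate_cohort(gm, 10000, seed = 31)
  b3 <- bootstrap_af(co_big, roles, B = 100, seed = 4)
  expect_lt(b3$conf_high - b3$conf_low, b1$conf_high - b1$conf_low)
})

test_that("bootstrap intervals cover a null effect at about their level", {
  gm <- smoking_model()
  gm$log_hr$smoking[] <- 0
  gm$log_hr$alcohol[] <- 0
  gm$log_hr$ses[] <- 0
  roles <- roles_of(gm)
  covered <- vapply(1:12, function(s) {
    co <- simulate_cohort(gm, 1500, seed = 300 + s)
    ci <- suppressWarnings(bootstrap_af(co, roles, B = 100, seed = s,
                                        level = 0.9))
    ci$conf_low <= 0 && 0 <= ci$conf_high
  }, logical(1))
  expect_gte(sum(covered), 9)
})
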