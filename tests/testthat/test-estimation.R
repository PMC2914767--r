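test_that("single-ratio MLE agrees with an exhaustive grid-search oracle", {
  set.seed(42)
  for (i in 1:6) {
    mode <- if (i %% 2 == 0) "truncate" else "complete"
    set <- random_seg_set(n_fam = sample(2:6, 1L), max_s = 8,
                          ascertainment = mode)
    fit <- fit_single_R(set)
    expect_equal(fit$estimate, grid_mle(set), tolerance = 1e-4)
  }
})

test_that("profile CI endpoints sit at the 5.0238/2 log-likelihood drop", {
  set <- ascertain(filter_families(load_fixture("table1A"),
                                   segregating_only = TRUE))
  fit <- fit_single_R(set)
  thr <- fit$loglik - 5.0238 / 2
  for (bound in c(fit$ci_low, fit$ci_high)) {
    expect_equal(set_loglik(set, seg_params(bound)), thr, tolerance = 1e-6)
  }
  expect_true(fit$ci_low < fit$estimate && fit$estimate < fit$ci_high)
})

test_that("degenerate single-ratio inputs are handled as specified", {
  # no recessive offspring under complete selection: boundary MLE at 0
  allzero <- make_set(c(0, 0), c(5, 8))
  fit <- fit_single_R(allzero)
  expect_equal(fit$estimate, 0)
  expect_true(fit$boundary[1L])
  expect_gt(fit$ci_high, 0)

  expect_error(fit_single_R(make_set(integer(), integer())), "empty")
  expect_error(fit_single_R(make_set(1, 4), composition = "HR"), "H_fixed")
})

test_that("conditional single-offspring fit matches its closed form", {
  so <- single_offspring_set(16, 55)
  expect_equal(fit_single_offspring(so, "R", 0.5)$estimate, (16 / 55) / 0.5,
               tolerance = 1e-12)
  expect_equal(fit_single_offspring(so, "H", 0.88)$estimate,
               (16 / 55) / 0.88, tolerance = 1e-12)
  # closed form equals a numeric maximization of the binomial likelihood
  num <- optimize(function(x) dbinom(16, 55, x * 0.5, log = TRUE),
                  c(1e-6, 1), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(fit_single_offspring(so, "R", 0.5)$estimate, num,
               tolerance = 1e-5)
  # clamping and edge cases
  expect_equal(fit_single_offspring(single_offspring_set(0, 20),
                                    "R", 0.5)$estimate, 0)
  expect_equal(fit_single_offspring(single_offspring_set(20, 20),
                                    "H", 0.5)$estimate, 1)
  expect_error(fit_single_offspring(single_offspring_set(0, 0), "R", 0.5))
})

test_that("two-ratio fit collapses to the single ratio when data are homogeneous", {
  set <- make_set(rep(2L, 5), rep(9L, 5), "truncate")
  single <- fit_single_R(set)
  two <- fit_two_ratio(set)
  expect_equal(two$R1, single$estimate, tolerance = 1e-6)
  expect_equal(two$R2, single$estimate, tolerance = 1e-6)
  expect_equal(two$loglik, single$loglik, tolerance = 1e-8)
})

test_that("two-ratio fit nests the single fit and its assignment is self-consistent", {
  set.seed(7)
  for (i in 1:5) {
    mode <- if (i %% 2 == 0) "truncate" else "complete"
    set <- random_seg_set(n_fam = sample(3:8, 1L), max_s = 8,
                          ascertainment = mode)
    single <- fit_single_R(set)
    two <- fit_two_ratio(set)
    expect_lte(two$R1, two$R2)
    expect_gte(two$loglik + 1e-8, single$loglik)
    # re-evaluating per-family likelihoods at (R1, R2) reproduces the
    # assignment (ties to component 1)
    l1 <- family_prob(set$n_huacaya, set$n_total, two$R1, mode, log = TRUE)
    l2 <- family_prob(set$n_huacaya, set$n_total, two$R2, mode, log = TRUE)
    expect_identical(unname(two$assignment), ifelse(l1 >= l2, 1L, 2L))
    expect_equal(two$loglik, sum(pmax(l1, l2)), tolerance = 1e-10)
  }
})

test_that("two-ratio fit flags single-family sets as degenerate", {
  two <- fit_two_ratio(make_set(3, 10, "truncate"))
  expect_true(two$degenerate)
  expect_equal(two$R1, two$R2)
})

test_that("likelihood-ratio test compares the nested models", {
  set <- ascertain(filter_families(load_fixture("table1A"),
                                   segregating_only = TRUE))
  single <- fit_single_R(set)
  two <- fit_two_ratio(set)
  lrt <- lrt_two_vs_one(single, two)
  expect_equal(lrt$statistic, 2 * (two$loglik - single$loglik))
  expect_equal(lrt$df, 1L)
  expect_lt(lrt$p_value, 0.001)

  same <- fit_two_ratio(make_set(rep(2L, 4), rep(9L, 4), "truncate"))
  lrt0 <- lrt_two_vs_one(fit_single_R(make_set(rep(2L, 4), rep(9L, 4),
                                               "truncate")), same)
  expect_equal(lrt0$statistic, 0, tolerance = 1e-6)
  expect_equal(lrt0$p_value, 1, tolerance = 1e-4)
})

test_that("profile CIs are calibrated on truncate-ascertained simulations", {
  covered <- 0L
  n_rep <- 500L
  for (b in seq_len(n_rep)) {
    sim <- simulate_crosses(sim_config("one_locus", n_sires = 20, R = 0.3,
                                       sizes = 10, seed = 20000 + b))
    asc <- tryCatch(ascertain(sim), error = function(e) NULL)
    if (is.null(asc)) next  # no segregating family drawn; cannot fit
    fit <- fit_single_R(asc)
    if (fit$ci_low <= 0.3 && 0.3 <= fit$ci_high) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.90)
})
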