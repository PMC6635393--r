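test_that("parameter transforms are exact inverses", {
  set.seed(51)
  for (i in 1:20) {
    pp <- random_init()
    for (v in list(model_variant(), model_variant("lapse"),
                   model_variant("bias"), model_variant(c("lapse", "bias")))) {
      u <- puffddm:::params_to_unconstrained(pp, v)
      back <- puffddm:::unconstrained_to_params(u, v)
      nm <- puffddm:::free_names(v)
      expect_equal(unlist(back[nm]), unlist(pp[nm]), tolerance = 1e-12)
      for (om in v$omit) expect_equal(back[[om]], 0)
    }
  }
})

test_that("model variants count their parameters", {
  expect_equal(model_variant()$k, 5L)
  expect_equal(model_variant("lapse")$k, 4L)
  expect_equal(model_variant(c("lapse", "bias"))$k, 3L)
  expect_error(model_variant("sigma_a2"))
})

test_that("BIC follows the larger-is-better convention", {
  expect_equal(bic(-100, 5, 1000), -100 - 5 * log(1000) / 2)
  expect_equal(bic(-100, 5, 1000), -117.2693, tolerance = 1e-4)
  # equal likelihood with one fewer parameter is favored by ln(n)/2
  d <- relative_bic(list(loglik = -100, k = 4, n = 1000),
                    list(loglik = -100, k = 5, n = 1000))
  expect_equal(d, log(1000) / 2)
  expect_gt(d, 0)
})

test_that("the numerical Hessian matches a central-difference oracle", {
  set.seed(52)
  ts <- ddm_agent_choices(generate_session(quiet_config(), 150),
                          baseline_ddm_params())
  stim <- puffddm:::prepare_stim(ts)
  nm <- c("lambda", "sigma_a2", "sigma_s2", "bias", "lapse")
  f <- function(th) {
    p <- ddm_params(th[1], th[2], th[3], th[4], th[5])
    -puffddm:::loglik_stim(stim, p)
  }
  th0 <- c(-0.2, 0.6, 0.9, 0.1, 0.1)
  H_pkg <- pracma::hessian(f, th0)
  # independent brute-force central-difference Hessian
  h <- 1e-4 * pmax(1, abs(th0))
  H_fd <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    e_i <- e_j <- numeric(5)
    e_i[i] <- h[i]; e_j[j] <- h[j]
    H_fd[i, j] <- (f(th0 + e_i + e_j) - f(th0 + e_i - e_j) -
                     f(th0 - e_i + e_j) + f(th0 - e_i - e_j)) /
      (4 * h[i] * h[j])
  }
  expect_equal(H_pkg, H_fd, tolerance = 1e-3)
})

test_that("the PSD filter accepts a well-conditioned optimum", {
  set.seed(53)
  ts <- ddm_agent_choices(generate_session(quiet_config(), 800),
                          ddm_params(lambda = -0.3, sigma_a2 = 0.5,
                                     sigma_s2 = 1, bias = 0.2, lapse = 0.1))
  f <- fit_once(ts, init = ddm_params(lambda = -0.3, sigma_a2 = 0.5,
                                      sigma_s2 = 1, bias = 0.2, lapse = 0.1))
  expect_true(f$converged)
  expect_true(hessian_psd_check(f$params, ts))
})

test_that("fitting is deterministic given seed and initialization", {
  set.seed(54)
  ts <- ddm_agent_choices(generate_session(quiet_config(), 500),
                          baseline_ddm_params())
  init <- baseline_ddm_params()
  f1 <- fit_once(ts, init = init)
  f2 <- fit_once(ts, init = init)
  expect_identical(f1, f2)
  set.seed(77)
  r1 <- fit_ddm(ts, n_reps = 2, hessian_filter = FALSE)
  set.seed(77)
  r2 <- fit_ddm(ts, n_reps = 2, hessian_filter = FALSE)
  expect_identical(r1$reps, r2$reps)
})

test_that("ideal-agent data drives noise parameters to the floor with perfect prediction", {
  set.seed(55)
  ts <- ddm_agent_choices(generate_session(quiet_config(), 400), ddm_params())
  f <- fit_once(ts, init = ddm_params(lambda = 0.01, sigma_a2 = 0.05,
                                      sigma_s2 = 0.05, bias = 0, lapse = 0.01))
  expect_lt(f$params$sigma_a2, 0.05)
  expect_lt(f$params$lapse, 0.05)
  # held-out prediction of a separate ideal-agent set is perfect
  test <- ddm_agent_choices(generate_session(quiet_config(), 200),
                            ddm_params())
  stim <- puffddm:::prepare_stim(test)
  pr <- puffddm:::stim_choice_prob(stim, f$params)
  expect_equal(mean((pr >= 0.5) == stim$right), 1)
})

test_that("cross-validated accuracy degrades from near-perfect to chance with lapse", {
  set.seed(56)
  accs <- vapply(c(0, 1), function(lp) {
    gen <- ddm_params(lapse = lp)
    train <- ddm_agent_choices(generate_session(quiet_config(), 1500), gen)
    test <- ddm_agent_choices(generate_session(quiet_config(), 1500), gen)
    cv_choice_accuracy(train, test, n_starts = 2)
  }, numeric(1))
  expect_gt(accs[1], 0.95)
  expect_lt(abs(accs[2] - 0.5), 3 * sqrt(0.25 / 1500))
  expect_error(cv_choice_accuracy(
    ddm_agent_choices(generate_session(quiet_config(), 150), ddm_params()),
    trial_set(list())), "empty test")
})

test_that("repetition spread tightens with more trials", {
  set.seed(57)
  gen <- baseline_ddm_params()
  small <- ddm_agent_choices(generate_session(quiet_config(), 400), gen)
  large <- ddm_agent_choices(generate_session(quiet_config(), 4000), gen)
  f_small <- fit_ddm(small, n_reps = 6, hessian_filter = FALSE)
  f_large <- fit_ddm(large, n_reps = 6, hessian_filter = FALSE)
  sd_small <- stats::sd(f_small$reps$lambda)
  sd_large <- stats::sd(f_large$reps$lambda)
  expect_lt(sd_large, sd_small)
  # medians are invariant to repetition order by construction
  expect_equal(f_large$median_params$lambda,
               stats::median(f_large$reps$lambda[f_large$reps$accepted]))
})

test_that("fit_ddm enforces its floors and reports acceptance diagnostics", {
  set.seed(58)
  tiny <- ddm_agent_choices(generate_session(quiet_config(), 50),
                            baseline_ddm_params())
  expect_error(fit_ddm(tiny, n_reps = 2), "floor")
  ts <- ddm_agent_choices(generate_session(quiet_config(), 150),
                          baseline_ddm_params())
  f <- fit_ddm(ts, n_reps = 3, min_trials = 100, hessian_filter = FALSE)
  expect_s3_class(f, "ddm_fit")
  expect_true(all(c("q2.5", "median", "q97.5") %in% colnames(f$quantiles)))
  expect_lte(f$n_accepted, 3)
})

test_that("a moderate lapse is recovered from flipped-choice data", {
  set.seed(59)
  ts <- generate_session(quiet_config(), 3000)
  ts <- apply_impairment(ts, impairment_scenario("lapse_flip",
                                                 flip_fraction = 0.25),
                         ideal_curve)
  f <- fit_ddm(ts, n_reps = 3, hessian_filter = FALSE)
  # flip fraction f corresponds to lapse = 2f
  expect_equal(f$median_params$lapse, 0.5, tolerance = 0.1)
})
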