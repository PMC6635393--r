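test_that("the noise-free accumulator sums signed puffs exactly", {
  s <- simulate_accumulator(worked_trial(), ddm_params(), dt = 0.015)
  expect_equal(s$a[length(s$a)], -2, tolerance = 1e-12)
  expect_equal(s$a[1], 0)
  expect_equal(s$time[1], 0)
  expect_equal(s$time[length(s$time)], 4.6)
})

test_that("a single noise-free pulse decays along the exponential closed form", {
  tr <- trial(puffs_right = 1.0, choice = "none", correct_side = "right")
  for (lam in c(-2, -0.5, 0, 0.5)) {
    s <- simulate_accumulator(tr, ddm_params(lambda = lam), dt = 0.001)
    expect_equal(s$a[length(s$a)], exp(lam * (4.6 - 1.0)), tolerance = 1e-6)
  }
  # the pulse is at e^-1 of its initial value one time constant after onset
  lam <- -0.5
  s <- simulate_accumulator(tr, ddm_params(lambda = lam), dt = 0.001)
  tau <- tau_from_lambda(lam)$tau
  at <- s$a[which.min(abs(s$time - (1.0 + tau)))]
  expect_equal(at, exp(-1), tolerance = 1e-3)
})

test_that("pure diffusion accumulates variance at sigma_a2 per second", {
  set.seed(41)
  tr <- trial(guided = TRUE, correct_side = "left", choice = "none",
              condition_label = "guided") # no puffs
  pp <- ddm_params(sigma_a2 = 0.8)
  n <- 10000
  a <- simulate_endpoints(tr, pp, n = n)
  v_true <- 0.8 * 4.6
  expect_lt(abs(mean(a)), 3 * sqrt(v_true / n))
  # chi-square sampling error of the sample variance
  se_var <- v_true * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(a) - v_true), 3 * se_var)
})

test_that("grid propagation is mass-conserving and matches degenerate limits", {
  tr <- worked_trial()
  d0 <- propagate_distribution(tr, ddm_params())
  expect_equal(sum(d0$mass), 1, tolerance = 1e-9)
  # noise-free: all mass within one cell of #R - #L
  expect_equal(sum(d0$mass * d0$x), -2, tolerance = d0$dx)
  expect_equal(d0$x[which.max(d0$mass)], -2, tolerance = d0$dx + 1e-9)
  set.seed(42)
  for (i in 1:5) {
    inst <- random_instance()
    d <- propagate_distribution(inst$trial, inst$params)
    expect_equal(sum(d$mass), 1, tolerance = 1e-9)
    expect_true(all(d$mass >= 0))
  }
})

test_that("a too-narrow grid raises an explicit error instead of truncating", {
  tr <- worked_trial()
  expect_error(
    propagate_distribution(tr, ddm_params(sigma_s2 = 1), halfwidth = 3),
    "grid too narrow")
})

test_that("grid and closed-form choice probabilities agree", {
  set.seed(43)
  for (i in 1:8) {
    inst <- random_instance()
    pg <- ddm_choice_prob(inst$trial, inst$params, method = "grid")
    pc <- ddm_choice_prob(inst$trial, inst$params, method = "closed")
    expect_lt(abs(pg - pc), 5e-3)
  }
})

test_that("halving dt and dx barely changes the grid choice probability", {
  set.seed(44)
  for (i in 1:3) {
    inst <- random_instance(lambda_range = c(-1.5, 0.3))
    p1 <- ddm_choice_prob(inst$trial, inst$params, method = "grid",
                          dt = 0.015, dx = 0.02)
    p2 <- ddm_choice_prob(inst$trial, inst$params, method = "grid",
                          dt = 0.0075, dx = 0.01)
    expect_lt(abs(p1 - p2), 1e-3)
  }
})

test_that("swapping puff sides and negating bias mirrors P(right) exactly", {
  set.seed(45)
  for (i in 1:5) {
    inst <- random_instance()
    tr2 <- inst$trial
    tmp <- tr2$puffs_left
    tr2$puffs_left <- tr2$puffs_right
    tr2$puffs_right <- tmp
    pp2 <- inst$params
    pp2$bias <- -inst$params$bias
    for (m in c("grid", "closed")) {
      p1 <- ddm_choice_prob(inst$trial, inst$params, method = m)
      p2 <- ddm_choice_prob(tr2, pp2, method = m)
      expect_equal(p1, 1 - p2, tolerance = 1e-12)
    }
  }
})

test_that("lapse bounds and monotonicity hold for the choice rule", {
  set.seed(46)
  for (i in 1:10) {
    inst <- random_instance()
    p <- ddm_choice_prob(inst$trial, inst$params)
    expect_gte(p, inst$params$lapse / 2 - 1e-12)
    expect_lte(p, 1 - inst$params$lapse / 2 + 1e-12)
  }
  # noise-free limit: P(right) non-decreasing in #R - #L
  deltas <- -3:3
  ps <- vapply(deltas, function(d) {
    nr <- 5 + max(d, 0)
    nl <- 5 - min(d, 0)
    tr <- trial(puffs_right = seq_len(nr) * 0.2 - 0.1,
                puffs_left = seq_len(nl) * 0.2 - 0.1 + 0.02,
                choice = "none", correct_side = if (d >= 0) "right" else "left")
    ddm_choice_prob(tr, ddm_params(lapse = 0.1))
  }, numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("choice_probability implements the lapse and threshold-splitting rules", {
  tr <- trial(puffs_right = c(0.5, 1.0, 1.5), choice = "none",
              correct_side = "right")
  # all mass above the threshold, lapse 0.2: P(right) = 1 - 0.5 * 0.2 = 0.9
  d <- propagate_distribution(tr, ddm_params(lapse = 0.2))
  expect_equal(choice_probability(d, ddm_params(lapse = 0.2)), 0.9,
               tolerance = 1e-9)
  # lapse 1 gives 0.5 for any distribution
  expect_equal(choice_probability(d, ddm_params(lapse = 1)), 0.5)
  # a symmetric distribution about the threshold gives exactly 0.5
  tr0 <- trial(guided = TRUE, correct_side = "left", choice = "none",
               condition_label = "guided")
  d0 <- propagate_distribution(tr0, ddm_params(sigma_a2 = 0.5))
  expect_equal(choice_probability(d0, ddm_params(sigma_a2 = 0.5)), 0.5,
               tolerance = 1e-9)
  # a point mass exactly at the threshold splits 50/50
  dd <- propagate_distribution(tr0, ddm_params())
  expect_equal(choice_probability(dd, ddm_params()), 0.5)
})

test_that("trial and dataset log-likelihoods obey their identities", {
  tr <- worked_trial()
  tr$choice <- "left"
  # lapse 1: every choice has probability 0.5
  expect_equal(trial_loglik(tr, "left", ddm_params(lapse = 1)), log(0.5))
  expect_equal(trial_loglik(tr, "right", ddm_params(lapse = 1)), log(0.5))
  # ideal parameters, correct-sign choice: log 1 = 0
  expect_equal(trial_loglik(tr, "left", ddm_params()), 0)
  expect_error(trial_loglik(tr, "none", ddm_params()), "choice")

  set.seed(47)
  ts <- ddm_agent_choices(generate_session(quiet_config(), 40),
                          baseline_ddm_params())
  pp <- baseline_ddm_params()
  ll <- dataset_loglik(ts, pp)
  expect_equal(ll$n_included, 40)
  # additivity: duplicating the set doubles the log-likelihood
  ts2 <- trial_set(c(ts$trials, ts$trials), validate = FALSE)
  expect_equal(dataset_loglik(ts2, pp)$loglik, 2 * ll$loglik,
               tolerance = 1e-9)
  # invariance under trial reordering
  set.seed(1)
  ts3 <- trial_set(ts$trials[sample(40)], validate = FALSE)
  expect_equal(dataset_loglik(ts3, pp)$loglik, ll$loglik, tolerance = 1e-9)
  # lapse 1: n * log(0.5)
  expect_equal(dataset_loglik(ts, ddm_params(lapse = 1))$loglik,
               40 * log(0.5))
  # grid and closed methods agree on the dataset likelihood
  sub <- trial_set(ts$trials[1:8], validate = FALSE)
  expect_equal(dataset_loglik(sub, pp, method = "grid")$loglik,
               dataset_loglik(sub, pp, method = "closed")$loglik,
               tolerance = 0.05)
  # excluded trials are counted, and an empty inclusion set errors
  ts$trials[[1]]$choice <- "none"
  expect_equal(dataset_loglik(ts, pp)$n_excluded, 1)
  none <- trial_set(ts$trials[1], validate = FALSE)
  expect_error(dataset_loglik(none, pp), "inclusion")
})

test_that("tau_from_lambda reports the time constant and regime", {
  expect_equal(tau_from_lambda(-0.5), list(tau = 2, regime = "leaky"))
  expect_equal(tau_from_lambda(0.25), list(tau = 4, regime = "unstable"))
  expect_equal(tau_from_lambda(0), list(tau = Inf, regime = "perfect"))
})
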