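test_that("puff trains respect the refractory period and the cue window", {
  set.seed(1)
  for (i in 1:50) {
    p <- generate_puff_train(2.5, 0.2, 3.8)
    expect_true(all(p >= 0 & p < 3.8))
    if (length(p) > 1) expect_true(all(diff(p) >= 0.2 - 1e-12))
  }
  expect_identical(generate_puff_train(2.5, 0.2, 0), numeric())
  expect_error(generate_puff_train(10, 0.2, 3.8), "min_gap")
})

test_that("puff train mean count matches a brute-force renewal oracle", {
  set.seed(2)
  n <- 4000
  counts <- replicate(n, length(generate_puff_train(2.5, 0.2, 3.8)))
  # independent oracle: direct renewal simulation, one interval at a time
  oracle_count <- function() {
    t <- 0.2 + stats::rexp(1, 1 / 0.2)
    k <- 0
    while (t < 3.8) {
      k <- k + 1
      t <- t + 0.2 + stats::rexp(1, 1 / 0.2)
    }
    k
  }
  oracle <- replicate(n, oracle_count())
  se <- sqrt(stats::var(counts) / n + stats::var(oracle) / n)
  expect_lt(abs(mean(counts) - mean(oracle)), 3 * se)
  # and the mean interval is 1/rate, so counts sit below rate*duration
  expect_lt(mean(counts), 2.5 * 3.8)
})

test_that("cue durations and light fractions follow the task mix", {
  set.seed(3)
  cfg <- task_config(light_fraction = 0.2)
  ts <- generate_session(cfg, 4000)
  cues <- vapply(ts$trials, `[[`, numeric(1), "cue_duration")
  p_long <- mean(cues == 3.8)
  expect_lt(abs(p_long - 0.85), 3 * sqrt(0.85 * 0.15 / 4000))
  light_on <- mean(vapply(ts$trials, function(tr) !is.null(tr$light_window),
                          logical(1)))
  expect_lt(abs(light_on - 0.2), 3 * sqrt(0.2 * 0.8 / 4000))
  # every generated trial validates
  expect_true(all(vapply(ts$trials, function(tr)
    length(validate_trial(tr)) == 0, logical(1))))
})

test_that("session size defaults to the 200-300 trial range", {
  set.seed(4)
  ts <- generate_session(task_config())
  expect_gte(length(ts), 200)
  expect_lte(length(ts), 300)
})

test_that("light windows match their condition definitions", {
  set.seed(5)
  cfg <- quiet_config()
  expects <- list("full-cue" = c(0, 3.8), "first-third" = c(0, 3.8 / 3),
                  "middle-third" = c(3.8 / 3, 2 * 3.8 / 3),
                  "last-third" = c(2 * 3.8 / 3, 3.8),
                  "delay" = c(3.8, 4.6), "delay-200ms" = c(3.8, 4.0),
                  "delay-500ms" = c(3.8, 4.3))
  for (cond in names(expects)) {
    tr <- generate_trial(cfg, cond)
    expect_equal(c(tr$light_window$start, tr$light_window$end),
                 expects[[cond]], info = cond)
  }
  expect_null(generate_trial(cfg, "light-off")$light_window)
})

test_that("guided trials have single-sided cues and regular delay guide puffs", {
  set.seed(6)
  for (i in 1:10) {
    tr <- generate_trial(quiet_config(), "guided")
    expect_true(tr$guided)
    cue_l <- sum(tr$puffs_left < tr$cue_duration)
    cue_r <- sum(tr$puffs_right < tr$cue_duration)
    expect_true(xor(cue_l > 0, cue_r > 0))
    p <- c(tr$puffs_left, tr$puffs_right)
    guide <- sort(p[p >= tr$cue_duration])
    expect_equal(guide, tr$cue_duration + c(0, 0.4))
  }
})

test_that("sessions are bit-identical under a fixed seed", {
  cfg <- task_config(light_fraction = 0.25)
  set.seed(99)
  a <- generate_session(cfg, 50)
  set.seed(99)
  b <- generate_session(cfg, 50)
  expect_identical(a, b)
})

test_that("the psychometric agent reproduces its curve", {
  set.seed(7)
  curve <- psychometric_curve(y0 = 0.05, A = 0.9, x0 = 0, b = 2)
  # balanced trial: P(right) must be 0.5 by symmetry
  tr0 <- trial(puffs_left = c(0.3, 1.2), puffs_right = c(2.1, 3.0),
               guided = TRUE, correct_side = "left", choice = "none",
               condition_label = "guided")
  draws <- replicate(2000, psychometric_agent(tr0, curve) == "right")
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 2000))
  # choice fractions track the curve across evidence strengths
  ts <- generate_session(quiet_config(), 4000)
  ts <- apply_impairment(ts, impairment_scenario("none"), curve)
  pc <- puff_counts(ts)
  for (d in c(-4, -2, 2, 4)) {
    sel <- pc$delta == d
    if (sum(sel) < 50) next
    p_hat <- mean(pc$choice[sel] == "right")
    p_true <- predict(curve, d)
    expect_lt(abs(p_hat - p_true),
              3 * sqrt(p_true * (1 - p_true) / sum(sel)) + 1e-6)
  }
  # a saturated curve makes strong-evidence choices near-deterministic
  sat <- psychometric_curve(y0 = 0, A = 1, x0 = 0, b = 0.1)
  tr_strong <- trial(puffs_right = c(0.5, 1.0, 1.5, 2.0, 2.5),
                     puffs_left = 0.1, choice = "none")
  expect_true(all(replicate(20, psychometric_agent(tr_strong, sat)) == "right"))
})

test_that("the noise-free accumulator agent is the sign rule", {
  set.seed(8)
  ts <- generate_session(quiet_config(), 300)
  ts <- ddm_agent_choices(ts, ddm_params())
  pc <- puff_counts(ts)
  expect_identical(pc$choice, ifelse(pc$delta > 0, "right", "left"))
  # single-trial interface agrees
  tr <- ts$trials[[1]]
  expect_identical(ddm_agent(tr, ddm_params()),
                   if (puff_counts(tr)[["delta"]] > 0) "right" else "left")
})

test_that("accumulator agent choice fractions match the grid propagation", {
  set.seed(9)
  for (i in 1:5) {
    inst <- random_instance()
    p_grid <- ddm_choice_prob(inst$trial, inst$params, method = "grid")
    n_sim <- 4000
    one <- trial_set(rep(list(inst$trial), n_sim), validate = FALSE)
    one <- ddm_agent_choices(one, inst$params)
    p_sim <- mean(choices_of(one) == "right")
    se <- sqrt(max(p_grid * (1 - p_grid), 1e-4) / n_sim)
    expect_lt(abs(p_sim - p_grid), 3.5 * se)
  }
})

test_that("attenuation 1.0 makes sensation and retention equal to no impairment", {
  cfg <- task_config(p_long = 1, light_fraction = 1,
                     light_schedule = c("last-third" = 1))
  set.seed(10)
  ts <- generate_session(cfg, 400)
  curve <- psychometric_curve()
  for (kind in c("sensation", "retention")) {
    set.seed(11)
    plain <- apply_impairment(ts, impairment_scenario("none"), curve)
    set.seed(11)
    same <- apply_impairment(ts, impairment_scenario(kind, attenuation = 1),
                             curve)
    expect_identical(choices_of(plain), choices_of(same))
  }
})

test_that("lapse_flip flips exactly the requested fraction of an ideal agent", {
  set.seed(12)
  ts <- generate_session(quiet_config(), 2000)
  ts <- apply_impairment(ts, impairment_scenario("lapse_flip",
                                                 flip_fraction = 0.25),
                         ideal_curve)
  pc <- puff_counts(ts)
  err <- mean(pc$choice != pc$correct_side)
  expect_equal(err, 0.25, tolerance = 0.001)
})

test_that("scenarios requiring a light window refuse light-off-only data", {
  set.seed(13)
  ts <- generate_session(quiet_config(), 20)
  for (kind in c("sensation", "retention", "action"))
    expect_error(apply_impairment(ts, impairment_scenario(kind),
                                  ideal_curve),
                 "light window")
})

test_that("the action scenario flips more choices when light ends near the lick", {
  set.seed(14)
  curve <- ideal_curve
  mk <- function(cond) {
    cfg <- task_config(p_long = 1, light_fraction = 1,
                       light_schedule = stats::setNames(1, cond))
    apply_impairment(generate_session(cfg, 1500),
                     impairment_scenario("action", action_scale = 0.4), curve)
  }
  err_rate <- function(ts) {
    pc <- puff_counts(ts)
    mean(pc$choice != pc$correct_side)
  }
  e_first <- err_rate(mk("first-third"))  # light ends long before the lick
  e_delay <- err_rate(mk("delay"))        # light ends at the lick
  expect_gt(e_delay, e_first + 0.1)
})
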