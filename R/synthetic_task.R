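#' Task configuration for the synthetic trial generator
#'
#' Defaults emulate the published task statistics: independent per-side
#' puff trains at a mean 2.5 events/s with a 200-ms minimum inter-puff
#' interval, a 3.8-s cue period with probability 0.85 (else 1.5 s), an
#' 800-ms delay, light delivered on a random 15-30% of trials, and
#' sessions of 200-300 trials.
#'
#' @param puff_rate Mean puff rate per side (events/s).
#' @param min_gap Minimum inter-puff interval (s).
#' @param long_cue,short_cue Cue durations (s).
#' @param p_long Probability of the long cue.
#' @param delay Delay duration (s).
#' @param light_fraction Fraction of light-on trials.
#' @param light_schedule Named probability vector over light-on condition
#'   labels (see [condition_labels()]); default all full-cue.
#' @param light_side Laterality of light delivery: `"bilateral"`, `"left"`
#'   or `"right"`.
#' @param session_size Length-2 range of trials per session.
#' @param lick_latency Latency (s) from end of delay to the decision lick
#'   synthesized onto generated trials (mean light-off value from the
#'   task).
#' @return An object of class `task_config`.
#' @export
task_config <- function(puff_rate = 2.5, min_gap = 0.2,
                        long_cue = 3.8, short_cue = 1.5, p_long = 0.85,
                        delay = 0.8, light_fraction = 0.2,
                        light_schedule = c("full-cue" = 1),
                        light_side = "bilateral",
                        session_size = c(200, 300),
                        lick_latency = 0.578) {
  stopifnot(puff_rate > 0, min_gap >= 0, 1 / puff_rate >= min_gap,
            p_long >= 0, p_long <= 1,
            light_fraction >= 0, light_fraction <= 1,
            abs(sum(light_schedule) - 1) < 1e-9,
            all(names(light_schedule) %in% setdiff(condition_labels(),
                                                   "light-off")),
            light_side %in% c("bilateral", "left", "right"),
            length(session_size) == 2, session_size[1] <= session_size[2])
  structure(list(puff_rate = puff_rate, min_gap = min_gap,
                 long_cue = long_cue, short_cue = short_cue, p_long = p_long,
                 delay = delay, light_fraction = light_fraction,
                 light_schedule = light_schedule, light_side = light_side,
                 session_size = session_size, lick_latency = lick_latency),
            class = "task_config")
}

#' Generate one randomly timed puff train
#'
#' The train is a renewal process whose inter-event intervals are
#' `min_gap + Exponential(mean = 1/rate - min_gap)`, so the mean interval
#' is exactly `1/rate` and the refractory period is exactly respected; the
#' first event's time is drawn the same way from time 0. When
#' `1/rate == min_gap` the train is perfectly regular.
#'
#' @param rate Mean event rate (events/s).
#' @param min_gap Minimum inter-event interval (s).
#' @param duration Train duration (s); events at `>= duration` are dropped.
#' @return Sorted numeric vector of event times in `[0, duration)`.
#' @export
generate_puff_train <- function(rate, min_gap, duration) {
  if (1 / rate < min_gap)
    stop("mean interval 1/rate must be at least min_gap", call. = FALSE)
  if (duration <= 0) return(numeric())
  mean_ex <- 1 / rate - min_gap
  times <- numeric()
  last <- 0
  repeat {
    k <- max(8, ceiling((duration - last) * rate * 1.5))
    gaps <- min_gap + if (mean_ex > 0) stats::rexp(k, 1 / mean_ex) else 0
    new <- last + cumsum(gaps)
    times <- c(times, new)
    last <- new[k]
    if (last >= duration) break
  }
  times[times < duration]
}

#' Generate a single trial (choice unset)
#'
#' Draws the cue duration (long with probability `p_long`), independent
#' left and right puff trains (tie trials are regenerated, since the
#' correct side is undefined for ties), and sets the light window implied
#' by the condition label: full cue `[0, cue]`; first/middle/last third
#' the corresponding third of the cue; `delay` the full delay
#' `[cue, cue + delay]` (`delay-200ms`/`delay-500ms` its first 0.2/0.5 s).
#' Guided trials carry a single-sided cue train plus regular guide puffs
#' during the delay and are marked `guided`.
#'
#' @param config A [task_config()].
#' @param condition Condition label from [condition_labels()].
#' @return A [trial()] with `choice = "none"`.
#' @export
generate_trial <- function(config, condition = "light-off") {
  stopifnot(inherits(config, "task_config"),
            condition %in% condition_labels())
  cue <- if (stats::runif(1) < config$p_long) config$long_cue else
    config$short_cue
  delay <- config$delay
  if (condition == "guided") {
    side <- if (stats::runif(1) < 0.5) "left" else "right"
    cue_train <- generate_puff_train(config$puff_rate, config$min_gap, cue)
    # regular guide puffs through the delay at the nominal rate
    guide <- cue + seq(0, delay - 1e-9, by = 1 / config$puff_rate)
    train <- sort(c(cue_train, guide))
    lw <- list(start = 0, end = cue, side = config$light_side)
    return(trial(
      puffs_left = if (side == "left") train else numeric(),
      puffs_right = if (side == "right") train else numeric(),
      cue_duration = cue, delay_duration = delay,
      light_window = lw, guided = TRUE, choice = "none",
      correct_side = side, decision_latency = config$lick_latency,
      condition_label = "guided"))
  }
  for (attempt in 1:1000) {
    pl <- generate_puff_train(config$puff_rate, config$min_gap, cue)
    pr <- generate_puff_train(config$puff_rate, config$min_gap, cue)
    if (length(pl) != length(pr)) break
  }
  lw <- switch(condition,
    "light-off" = NULL,
    "full-cue" = list(start = 0, end = cue),
    "first-third" = list(start = 0, end = cue / 3),
    "middle-third" = list(start = cue / 3, end = 2 * cue / 3),
    "last-third" = list(start = 2 * cue / 3, end = cue),
    "delay" = list(start = cue, end = cue + delay),
    "delay-200ms" = list(start = cue, end = cue + 0.2),
    "delay-500ms" = list(start = cue, end = cue + 0.5))
  if (!is.null(lw)) lw$side <- config$light_side
  trial(puffs_left = pl, puffs_right = pr, cue_duration = cue,
        delay_duration = delay, light_window = lw, guided = FALSE,
        choice = "none", decision_latency = config$lick_latency,
        condition_label = condition)
}

#' Generate a session of interleaved trials
#'
#' Light-on trials are interleaved uniformly at random at the configured
#' `light_fraction`, with the light-on condition drawn from
#' `light_schedule`.
#'
#' @param config A [task_config()].
#' @param n_trials Number of trials; default drawn uniformly from
#'   `config$session_size`.
#' @param subject_id,session_id Labels stored on the trials.
#' @return A validated [trial_set()] with `choice = "none"` on every trial.
#' @export
generate_session <- function(config, n_trials = NULL,
                             subject_id = "sim", session_id = "s1") {
  stopifnot(inherits(config, "task_config"))
  if (is.null(n_trials))
    n_trials <- sample(config$session_size[1]:config$session_size[2], 1)
  stopifnot(n_trials >= 1)
  conds <- names(config$light_schedule)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    light_on <- stats::runif(1) < config$light_fraction
    cond <- if (!light_on) "light-off" else if (length(conds) == 1) conds else
      sample(conds, 1, prob = config$light_schedule)
    tr <- generate_trial(config, cond)
    tr$subject_id <- subject_id
    tr$session_id <- session_id
    tr$trial_index <- i
    trials[[i]] <- tr
  }
  trial_set(trials, subject_id = subject_id, session_id = session_id)
}

# evaluate a psychometric curve object/function at evidence values
eval_curve <- function(curve, x) {
  p <- if (is.function(curve)) curve(x) else
    if (inherits(curve, "psychometric_fit")) predict(curve, x) else
      stop("curve must be a function or psychometric_fit", call. = FALSE)
  pmin(1, pmax(0, p))
}

#' Simulate a choice from the empirical psychometric curve
#'
#' Bernoulli draw of a rightward choice at the curve's value for the
#' trial's total #R - #L.
#'
#' @param tr A [trial()].
#' @param curve A [psychometric_fit()] object (see [fit_psychometric()]) or
#'   a function mapping #R - #L to P(right).
#' @return `"left"` or `"right"`.
#' @export
psychometric_agent <- function(tr, curve) {
  delta <- puff_counts(tr)[["delta"]]
  p <- eval_curve(curve, delta)
  if (stats::runif(1) < p) "right" else "left"
}

#' Simulate a choice from the accumulator model
#'
#' Forward-simulates the accumulator ([simulate_endpoints()]) and applies
#' the bias/lapse decision rule: with probability `lapse` the choice is
#' random; otherwise right when the endpoint exceeds `bias` (a coin flip
#' on an exact tie).
#'
#' @param tr A [trial()].
#' @param params A [ddm_params()].
#' @param dt Simulation time step (s); default 0.015.
#' @return `"left"` or `"right"`.
#' @export
ddm_agent <- function(tr, params, dt = 0.015) {
  a <- simulate_endpoints(tr, params, dt = dt, n = 1)
  lapse_draw <- stats::runif(1)
  if (lapse_draw < params$lapse)
    return(if (stats::runif(1) < 0.5) "right" else "left")
  if (a == params$bias) return(if (stats::runif(1) < 0.5) "right" else "left")
  if (a > params$bias) "right" else "left"
}

#' Simulate choices for a whole trial set with the accumulator model
#'
#' Batch equivalent of applying [ddm_agent()] to every trial: one forward
#' simulation per trial, vectorized across trials sharing a trial length
#' (the draws differ from trial-by-trial calls only in RNG consumption
#' order).
#'
#' @param ts A [trial_set()].
#' @inheritParams ddm_agent
#' @return The trial set with simulated choices filled in.
#' @export
ddm_agent_choices <- function(ts, params, dt = 0.015) {
  stopifnot(inherits(ts, "trial_set"))
  n <- length(ts$trials)
  if (n == 0) return(ts)
  Tend <- vapply(ts$trials, function(tr) tr$cue_duration + tr$delay_duration,
                 numeric(1))
  a_end <- numeric(n)
  sig_s <- sqrt(params$sigma_s2)
  for (Tg in unique(Tend)) {
    grp <- which(abs(Tend - Tg) < 1e-9)
    m <- length(grp)
    n_steps <- max(1L, ceiling(Tg / dt - 1e-9))
    # flat puff arrays: owning trial (within group) and step of each puff
    pt <- lapply(ts$trials[grp], function(tr)
      c(tr$puffs_right, tr$puffs_left))
    ps <- lapply(ts$trials[grp], function(tr)
      c(rep(1, length(tr$puffs_right)), rep(-1, length(tr$puffs_left))))
    owner <- rep.int(seq_len(m), lengths(pt))
    pt <- unlist(pt)
    ps <- unlist(ps)
    step_of <- pmin(n_steps, floor(pt / dt) + 1L)
    by_step <- split(seq_along(pt), step_of)
    a <- numeric(m)
    for (k in seq_len(n_steps)) {
      rows <- by_step[[as.character(k)]]
      if (!is.null(rows)) {
        eta <- ps[rows] * (1 + if (sig_s > 0) sig_s * stats::rnorm(length(rows)) else 0)
        hit <- owner[rows]
        if (anyDuplicated(hit)) {
          agg <- rowsum(eta, hit)
          a[as.integer(rownames(agg))] <- a[as.integer(rownames(agg))] + agg[, 1]
        } else {
          a[hit] <- a[hit] + eta
        }
      }
      dur <- min(dt, Tg - (k - 1) * dt)
      g <- exp(params$lambda * dur)
      sd_k <- sqrt(params$sigma_a2 * dur)
      a <- a * g + if (sd_k > 0) sd_k * stats::rnorm(m) else 0
    }
    a_end[grp] <- a
  }
  lapse_draw <- stats::runif(n) < params$lapse
  tie <- a_end == params$bias
  coin <- stats::runif(n) < 0.5
  right <- ifelse(lapse_draw | tie, coin, a_end > params$bias)
  for (i in seq_len(n))
    ts$trials[[i]]$choice <- if (right[i]) "right" else "left"
  ts
}

#' Impairment scenario for behavioral simulations
#'
#' The interventions used to dissociate mechanisms of impairment:
#' `sensation` halves (by `attenuation`) the magnitude of puffs coinciding
#' with light delivery before evidence is summed; `retention` attenuates
#' puffs preceding light onset; `action` draws the choice normally and
#' then flips it with probability inversely proportional to the time
#' remaining until the decision lick (`min(1, action_scale / time)`);
#' `lapse_flip` flips a uniformly random `flip_fraction` of choices;
#' `none` is the plain psychometric agent.
#'
#' @param kind One of `"none"`, `"sensation"`, `"retention"`, `"action"`,
#'   `"lapse_flip"`.
#' @param attenuation Magnitude factor for affected puffs (default 0.5).
#' @param flip_fraction Fraction of trials flipped under `lapse_flip`
#'   (default 0.25).
#' @param action_scale Proportionality constant kappa (s) of the action
#'   flip rule (default 0.4).
#' @param lick_latency Fallback decision latency (s) when a trial has none.
#' @return An object of class `impairment_scenario`.
#' @export
impairment_scenario <- function(kind = c("none", "sensation", "retention",
                                         "action", "lapse_flip"),
                                attenuation = 0.5, flip_fraction = 0.25,
                                action_scale = 0.4, lick_latency = 0.578) {
  kind <- match.arg(kind)
  stopifnot(attenuation >= 0, attenuation <= 1,
            flip_fraction >= 0, flip_fraction <= 1, action_scale > 0)
  structure(list(kind = kind, attenuation = attenuation,
                 flip_fraction = flip_fraction, action_scale = action_scale,
                 lick_latency = lick_latency),
            class = "impairment_scenario")
}

# weighted cue-period evidence of one trial: puffs matching `affected`
# (a predicate on onset times given the light window) count with weight w
effective_evidence <- function(tr, affected, w) {
  weight_side <- function(p) {
    p <- p[p < tr$cue_duration]
    if (!length(p)) return(0)
    wts <- ifelse(affected(p, tr$light_window), w, 1)
    sum(wts)
  }
  weight_side(tr$puffs_right) - weight_side(tr$puffs_left)
}

#' Simulate choices under an impairment scenario
#'
#' Applies the scenario's intervention to each trial and draws choices
#' from the psychometric curve at the (possibly attenuated) effective
#' evidence. Trials without a light window (e.g. interleaved light-off
#' trials) are drawn without intervention; if the scenario requires a
#' light window and no trial has one, an error is raised.
#'
#' @param ts A [trial_set()].
#' @param scenario An [impairment_scenario()].
#' @param curve Psychometric curve (see [psychometric_agent()]).
#' @return The trial set with simulated choices.
#' @export
apply_impairment <- function(ts, scenario, curve) {
  stopifnot(inherits(ts, "trial_set"), inherits(scenario, "impairment_scenario"))
  n <- length(ts$trials)
  if (n == 0) return(ts)
  has_light <- vapply(ts$trials, function(tr) !is.null(tr$light_window),
                      logical(1))
  if (scenario$kind %in% c("sensation", "retention", "action") &&
      !any(has_light))
    stop(sprintf("scenario '%s' requires trials with a light window",
                 scenario$kind), call. = FALSE)
  affected <- switch(scenario$kind,
    sensation = function(p, lw) p >= lw$start & p < lw$end,
    retention = function(p, lw) p < lw$start,
    function(p, lw) rep(FALSE, length(p)))
  e <- vapply(seq_len(n), function(i) {
    tr <- ts$trials[[i]]
    if (!has_light[i] || scenario$kind %in% c("none", "action", "lapse_flip"))
      return(puff_counts(tr)[["delta"]])
    effective_evidence(tr, affected, scenario$attenuation)
  }, numeric(1))
  p <- eval_curve(curve, e)
  right <- stats::runif(n) < p
  if (scenario$kind == "action") {
    flip_p <- vapply(seq_len(n), function(i) {
      tr <- ts$trials[[i]]
      if (!has_light[i]) return(0)
      lat <- tr$decision_latency
      if (is.na(lat)) lat <- scenario$lick_latency
      t_lick <- tr$cue_duration + tr$delay_duration + lat
      min(1, scenario$action_scale / max(t_lick - tr$light_window$end, 1e-6))
    }, numeric(1))
    flip <- stats::runif(n) < flip_p
    right <- xor(right, flip)
  }
  if (scenario$kind == "lapse_flip") {
    k <- round(scenario$flip_fraction * n)
    flip_idx <- sample.int(n, k)
    right[flip_idx] <- !right[flip_idx]
  }
  for (i in seq_len(n))
    ts$trials[[i]]$choice <- if (right[i]) "right" else "left"
  ts
}

#' Four-parameter logistic psychometric curve object
#'
#' Constructs a psychometric curve `y(x) = y0 + A / (1 + exp(-(x - x0)/b))`
#' without fitting, e.g. for use as a behavioral agent. The defaults mimic
#' a well-trained mouse: small symmetric lapse floor/ceiling and a slope
#' yielding roughly 75% overall accuracy on the task's stimulus
#' distribution.
#'
#' @param y0 Lower asymptote.
#' @param A Range (upper asymptote is `y0 + A`).
#' @param x0 Midpoint (puffs).
#' @param b Slope scale (puffs).
#' @return An object of class `psychometric_fit` (without uncertainty
#'   information).
#' @export
psychometric_curve <- function(y0 = 0.05, A = 0.9, x0 = 0, b = 2) {
  structure(list(coefficients = c(y0 = y0, A = A, x0 = x0, b = b),
                 vcov = NULL, data = NULL, fitted = FALSE),
            class = "psychometric_fit")
}
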