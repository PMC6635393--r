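# shared fixtures for the test suite (all built in code)

# task configuration restricted to the primary 3.8-s cue, no light
quiet_config <- function(...) task_config(p_long = 1, light_fraction = 0, ...)

# the worked example trial: 5 left puffs, 3 right puffs, well spaced
worked_trial <- function() {
  trial(puffs_left = c(0.2, 0.9, 1.6, 2.3, 3.0),
        puffs_right = c(0.5, 1.5, 2.5),
        choice = "none")
}

# deterministic ideal observer: P(right) = 1 for #R > #L, 0.5 on ties
ideal_curve <- function(x) as.numeric(x > 0) + 0.5 * (x == 0)

# pure logistic choice curve on total evidence
logistic_curve <- function(slope = 0.5) function(x) stats::plogis(slope * x)

# random (trial, parameter) instance in the leaky-to-mildly-unstable regime
random_instance <- function(lambda_range = c(-2, 0.5)) {
  tr <- generate_trial(quiet_config(), "light-off")
  pp <- ddm_params(lambda = stats::runif(1, lambda_range[1], lambda_range[2]),
                   sigma_a2 = stats::runif(1, 0, 2),
                   sigma_s2 = stats::runif(1, 0, 2),
                   bias = stats::runif(1, -1, 1),
                   lapse = stats::runif(1, 0, 0.5))
  list(trial = tr, params = pp)
}

# Monte-Carlo P(right) from forward simulation with the full decision rule
simulated_p_right <- function(tr, pp, n_sim) {
  a <- simulate_endpoints(tr, pp, n = n_sim)
  lap <- stats::runif(n_sim) < pp$lapse
  coin <- stats::runif(n_sim) < 0.5
  mean(ifelse(lap | a == pp$bias, coin, a > pp$bias))
}

# choices of a trial set as a character vector
choices_of <- function(ts) vapply(ts$trials, `[[`, character(1), "choice")

# independent Beta-quantile oracle: invert the incomplete beta integral by
# direct quadrature of the density kernel and root finding
oracle_beta_quantile <- function(p, a, b) {
  # substitute x = sin^2(theta): the transformed integrand
  # 2 sin^(2a-1) cos^(2b-1) is smooth for a, b >= 1/2, so plain quadrature
  # converges to full precision without endpoint singularities
  Z <- beta(a, b)
  kernel <- function(th) 2 * sin(th)^(2 * a - 1) * cos(th)^(2 * b - 1)
  cdf <- function(q)
    stats::integrate(kernel, 0, asin(sqrt(q)), rel.tol = 1e-12,
                     abs.tol = 0)$value / Z
  stats::uniroot(function(q) cdf(q) - p, c(1e-12, 1 - 1e-12),
                 tol = 1e-13)$root
}
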