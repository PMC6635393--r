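#' Parameters of the five-parameter pulse accumulator
#'
#' The model tracks a scalar accumulator `a(t)` that starts at 0, drifts
#' exponentially at rate `lambda` (negative = leaky decay towards 0,
#' positive = unstable growth away from 0), diffuses with variance
#' `sigma_a2` per second, and jumps by `+eta` (`-eta`) at each right (left)
#' puff with `eta ~ N(1, sigma_s2)` i.i.d. per puff. At the end of the
#' trial the choice is right when `a` exceeds the `bias` threshold, except
#' on a `lapse` fraction of trials where the choice is random (so the
#' probability of a rightward choice when `a > bias` is `1 - 0.5 * lapse`).
#'
#' @param lambda Drift coefficient (1/s).
#' @param sigma_a2 Accumulator diffusion variance (units^2/s); must be >= 0.
#' @param sigma_s2 Per-pulse variance (units^2); must be >= 0.
#' @param bias Decision-threshold offset (accumulator units).
#' @param lapse Lapse probability in [0, 1].
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(lambda = 0, sigma_a2 = 0, sigma_s2 = 0,
                       bias = 0, lapse = 0) {
  stopifnot(is.finite(lambda), sigma_a2 >= 0, sigma_s2 >= 0,
            lapse >= 0, lapse <= 1, is.finite(bias))
  structure(list(lambda = lambda, sigma_a2 = sigma_a2, sigma_s2 = sigma_s2,
                 bias = bias, lapse = lapse),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  tau <- tau_from_lambda(x$lambda)
  cat(sprintf(
    "<ddm_params> lambda=%.4g /s (%s, tau=%.3g s) sigma_a2=%.4g sigma_s2=%.4g bias=%.4g lapse=%.4g\n",
    x$lambda, tau$regime, tau$tau, x$sigma_a2, x$sigma_s2, x$bias, x$lapse))
  invisible(x)
}

#' Memory time constant implied by the drift coefficient
#'
#' `tau = 1 / |lambda|`; the sign of `lambda` determines whether the
#' accumulator is leaky (decay towards 0) or unstable (growth away from 0).
#' `lambda = 0` gives an unbounded (perfect-integrator) time constant.
#'
#' @param lambda Drift coefficient (1/s).
#' @return List with `tau` (s, `Inf` when `lambda = 0`) and `regime`
#'   (`"leaky"`, `"unstable"`, or `"perfect"`).
#' @export
tau_from_lambda <- function(lambda) {
  regime <- if (lambda < 0) "leaky" else if (lambda > 0) "unstable" else "perfect"
  list(tau = if (lambda == 0) Inf else 1 / abs(lambda), regime = regime)
}

# Accumulation horizon: the model integrates from cue onset to the decision
# point at the end of the delay.
trial_end_time <- function(tr) tr$cue_duration + tr$delay_duration

# All puff events of a trial as (time, sign): right = +1, left = -1.
puff_events <- function(tr) {
  t <- c(tr$puffs_right, tr$puffs_left)
  s <- c(rep(1, length(tr$puffs_right)), rep(-1, length(tr$puffs_left)))
  o <- order(t)
  list(time = t[o], sign = s[o])
}

# Step layout shared by the simulator and the grid propagator: steps
# k = 1..n cover [(k-1)*dt, k*dt) with a possibly shorter final step; a puff
# is applied at the start of the step containing its onset, then drift and
# diffusion act over the step (drift uses the exact one-step multiplier
# exp(lambda * dt_k), the first-order expansion of which is the Euler rule).
step_layout <- function(Tend, dt) {
  n <- max(1L, ceiling(Tend / dt - 1e-9))
  starts <- (seq_len(n) - 1) * dt
  durs <- pmin(dt, Tend - starts)
  list(n = n, starts = starts, durs = durs)
}

#' Forward-simulate the accumulator on one trial
#'
#' Discrete-time simulation of the accumulator SDE: at each step the puffs
#' whose onsets fall in the step are applied (each contributing an
#' independent `N(+/-1, sigma_s2)` increment), then the accumulator decays
#' or grows by the exact drift factor `exp(lambda * dt)` and receives
#' diffusion noise `N(0, sigma_a2 * dt)`. The accumulator starts at 0 at
#' cue onset and runs to the end of the delay.
#'
#' @param tr A [trial()].
#' @param params A [ddm_params()].
#' @param dt Time step (s); default 0.015.
#' @return A data.frame with columns `time` and `a` (value at each step
#'   boundary, beginning at `time = 0`).
#' @export
simulate_accumulator <- function(tr, params, dt = 0.015) {
  stopifnot(dt > 0)
  a <- simulate_endpoints(tr, params, dt = dt, n = 1, full = TRUE)
  a
}

#' Forward-simulate many accumulator endpoint values
#'
#' Vectorized version of [simulate_accumulator()] returning only the value
#' of the accumulator at the end of the trial, for `n` independent runs.
#'
#' @inheritParams simulate_accumulator
#' @param n Number of independent runs.
#' @param full If `TRUE` (requires `n = 1`) return the full time series as
#'   in [simulate_accumulator()].
#' @return Numeric vector of `n` endpoint values (or a data.frame when
#'   `full = TRUE`).
#' @export
simulate_endpoints <- function(tr, params, dt = 0.015, n = 1, full = FALSE) {
  stopifnot(inherits(tr, "puff_trial"), inherits(params, "ddm_params"),
            dt > 0, n >= 1)
  if (full && n != 1) stop("full time series only available for n = 1")
  Tend <- trial_end_time(tr)
  ev <- puff_events(tr)
  lay <- step_layout(Tend, dt)
  step_of <- pmin(lay$n, floor(ev$time / dt) + 1L)
  sig_s <- sqrt(params$sigma_s2)
  a <- numeric(n)
  series <- if (full) numeric(lay$n + 1) else NULL
  for (k in seq_len(lay$n)) {
    here <- which(step_of == k)
    for (j in here) {
      a <- a + ev$sign[j] * (1 + if (sig_s > 0) sig_s * stats::rnorm(n) else 0)
    }
    g <- exp(params$lambda * lay$durs[k])
    sd_k <- sqrt(params$sigma_a2 * lay$durs[k])
    a <- a * g + if (sd_k > 0) sd_k * stats::rnorm(n) else 0
    if (full) series[k + 1] <- a
  }
  if (full)
    return(data.frame(time = c(0, lay$starts + lay$durs), a = series))
  a
}

# Integrated-Gaussian convolution kernel on the grid: weight of offset o
# cells is the N(mean, sd^2) mass falling in [o*dx - dx/2, o*dx + dx/2).
# For sd = 0 the kernel is a (possibly fractional) pure shift. Kernels are
# renormalized to sum exactly to 1 so convolution conserves mass.
gauss_kernel <- function(mean, sd, dx) {
  if (sd <= 0) {
    r <- mean / dx
    lo <- floor(r)
    frac <- r - lo
    if (frac < 1e-12) return(list(offsets = lo, w = 1))
    return(list(offsets = c(lo, lo + 1), w = c(1 - frac, frac)))
  }
  K <- ceiling((6 * sd + abs(mean)) / dx) + 1
  offsets <- seq.int(-K, K)
  edges <- (offsets * dx - dx / 2 - mean) / sd
  w <- stats::pnorm(c(edges, (K * dx + dx / 2 - mean) / sd))
  w <- diff(w)
  list(offsets = offsets, w = w / sum(w))
}

# Convolve a mass vector with a kernel given as (offsets, w); returns the
# new mass on the same grid plus the mass lost off both ends. Small kernels
# use direct shift-adds; large ones zero-padded FFT convolution.
convolve_mass <- function(mass, kern) {
  n <- length(mass)
  offs <- kern$offsets
  m <- length(offs)
  if (m <= 80) {
    out <- numeric(n)
    lost <- 0
    for (i in seq_len(m)) {
      o <- offs[i]
      wi <- kern$w[i]
      if (o == 0) {
        out <- out + mass * wi
      } else if (o > 0) {
        if (o < n) out[(o + 1):n] <- out[(o + 1):n] + mass[1:(n - o)] * wi
        lost <- lost + wi * sum(mass[max(1, n - o + 1):n])
      } else {
        if (-o < n) out[1:(n + o)] <- out[1:(n + o)] + mass[(1 - o):n] * wi
        lost <- lost + wi * sum(mass[1:min(n, -o)])
      }
    }
    return(list(mass = out, lost = lost))
  }
  K <- -offs[1]
  L <- stats::nextn(n + m - 1, 2)
  fa <- stats::fft(c(mass, numeric(L - n)))
  fb <- stats::fft(c(kern$w, numeric(L - m)))
  full <- Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n + m - 1)] / L
  full[full < 0] <- 0
  out <- full[(K + 1):(K + n)]
  lost <- sum(full) - sum(out)
  list(mass = out, lost = max(0, lost))
}

# scatter-add weights w at sorted nondecreasing target indices j into an
# n-vector; returns the accumulated vector and off-grid mass
scatter_sorted <- function(j, w, n) {
  ke <- c(which(diff(j) != 0L), length(j))
  sums <- diff(c(0, cumsum(w)[ke]))
  targets <- j[ke]
  ok <- targets >= 1L & targets <= n
  out <- numeric(n)
  out[targets[ok]] <- sums[ok]
  list(mass = out, lost = sum(sums[!ok]))
}

# Default grid half-width for a trial/parameter pair: generous enough that
# boundary mass stays below the propagation guard.
auto_halfwidth <- function(tr, params) {
  P <- length(tr$puffs_left) + length(tr$puffs_right)
  Tend <- trial_end_time(tr)
  spread <- 6 * sqrt(params$sigma_s2 * max(1, P) + params$sigma_a2 * Tend)
  base <- P + spread + abs(params$bias) + 1
  expand <- exp(max(0, params$lambda) * Tend)
  if (expand > 100)
    stop("unstable drift too strong for grid propagation (lambda * T = ",
         format(params$lambda * Tend), ")", call. = FALSE)
  base * expand
}

#' Propagate the accumulator probability distribution on a grid
#'
#' Computes the probability distribution of the accumulator at the end of
#' a trial by step-wise propagation of a discretized density: the initial
#' mass is a delta at 0; in each time step, puffs whose onsets fall in the
#' step are convolved in (kernel `N(+/-1, sigma_s2)`; a zero-variance puff
#' is a pure shift), the deterministic drift maps each grid point `x` to
#' `exp(lambda * dt) * x` with mass-conserving two-point linear
#' redistribution, and diffusion convolves with `N(0, sigma_a2 * dt)`.
#' Mass is conserved at every step; mass leaking past the grid edges is
#' tracked and an error is raised if it exceeds `loss_tol` (never silently
#' truncated).
#'
#' @inheritParams simulate_accumulator
#' @param dx Grid spacing (accumulator units); default 0.02.
#' @param halfwidth Grid half-width; default auto-sized from the puff count,
#'   the noise parameters and the drift.
#' @param loss_tol Maximum tolerated off-grid mass (default 1e-8).
#' @return An object of class `accumulator_dist`: list with `x` (grid
#'   values), `mass` (probabilities), `time`, `dx`, `boundary_loss`.
#' @export
propagate_distribution <- function(tr, params, dt = 0.015, dx = 0.02,
                                   halfwidth = NULL, loss_tol = 1e-8) {
  stopifnot(inherits(tr, "puff_trial"), inherits(params, "ddm_params"),
            dt > 0, dx > 0)
  if (is.null(halfwidth)) halfwidth <- auto_halfwidth(tr, params)
  m <- ceiling(halfwidth / dx)
  x <- seq.int(-m, m) * dx
  n <- length(x)
  mass <- numeric(n)
  mass[m + 1] <- 1
  Tend <- trial_end_time(tr)
  ev <- puff_events(tr)
  lay <- step_layout(Tend, dt)
  step_of <- pmin(lay$n, floor(ev$time / dt) + 1L)
  lost <- 0
  sig_s <- sqrt(params$sigma_s2)
  for (k in seq_len(lay$n)) {
    for (j in which(step_of == k)) {
      kern <- gauss_kernel(ev$sign[j], sig_s, dx)
      cm <- convolve_mass(mass, kern)
      mass <- cm$mass
      lost <- lost + cm$lost
    }
    g <- exp(params$lambda * lay$durs[k])
    if (g != 1) {
      # mass-conserving two-point redistribution along the monotone map
      # x -> g*x (targets are sorted, enabling a cumsum-based scatter)
      y <- g * x
      pos <- (y - x[1]) / dx
      jdx <- as.integer(floor(pos)) + 1L # 1-based lower neighbor
      frac <- pos - (jdx - 1L)
      lo <- scatter_sorted(jdx, mass * (1 - frac), n)
      hi <- scatter_sorted(jdx + 1L, mass * frac, n)
      mass <- lo$mass + hi$mass
      lost <- lost + lo$lost + hi$lost
    }
    if (params$sigma_a2 > 0) {
      kern <- gauss_kernel(0, sqrt(params$sigma_a2 * lay$durs[k]), dx)
      cm <- convolve_mass(mass, kern)
      mass <- cm$mass
      lost <- lost + cm$lost
    }
  }
  if (lost > loss_tol)
    stop(sprintf(
      "grid too narrow: boundary mass %.3g exceeds %.1g (halfwidth %.3g); widen the grid",
      lost, loss_tol, halfwidth), call. = FALSE)
  structure(list(x = x, mass = mass, time = Tend, dx = dx,
                 boundary_loss = lost),
            class = "accumulator_dist")
}

#' @export
print.accumulator_dist <- function(x, ...) {
  cat(sprintf(
    "<accumulator_dist> t=%.3f s, %d grid points in [%.2f, %.2f], mass=%.9f, boundary loss=%.2g\n",
    x$time, length(x$x), min(x$x), max(x$x), sum(x$mass), x$boundary_loss))
  invisible(x)
}

#' Rightward-choice probability from an accumulator distribution
#'
#' `P(right) = 0.5 * lapse + (1 - lapse) * [P(a > bias) + 0.5 * P(a = bias)]`.
#' Each grid cell is treated as uniform mass over `[x - dx/2, x + dx/2)`;
#' the cell containing the threshold contributes the linearly interpolated
#' fraction above it, so a point mass exactly at the threshold splits 50/50.
#'
#' @param dist An `accumulator_dist` from [propagate_distribution()].
#' @param params A [ddm_params()] (supplies `bias` and `lapse`).
#' @return Probability of a rightward choice, in
#'   `[lapse/2, 1 - lapse/2]`.
#' @export
choice_probability <- function(dist, params) {
  stopifnot(inherits(dist, "accumulator_dist"), inherits(params, "ddm_params"))
  x <- dist$x
  dx <- dist$dx
  b <- params$bias
  lower_edge <- x - dx / 2
  upper_edge <- x + dx / 2
  above <- sum(dist$mass[lower_edge > b])
  strad <- which(lower_edge <= b & upper_edge > b)
  if (length(strad) == 1)
    above <- above + dist$mass[strad] * (upper_edge[strad] - b) / dx
  above <- min(1, max(0, above))
  0.5 * params$lapse + (1 - params$lapse) * above
}

#' Choice probability of a trial under the model
#'
#' Convenience front end computing `P(right)` for one trial, by grid
#' propagation (`method = "grid"`, the step-wise discretization above) or
#' by the exact Gaussian solution of the accumulator SDE
#' (`method = "closed"`): with no accumulation bound the accumulator at
#' trial end is exactly Gaussian with mean
#' `sum_j s_j exp(lambda (T - t_j))` and variance
#' `sigma_s2 * sum_j exp(2 lambda (T - t_j)) + sigma_a2 * (exp(2 lambda T) - 1) / (2 lambda)`.
#' The two agree as `dt, dx -> 0`.
#'
#' @inheritParams propagate_distribution
#' @param method `"closed"` (default) or `"grid"`.
#' @return `P(right)` in `[lapse/2, 1 - lapse/2]`.
#' @export
ddm_choice_prob <- function(tr, params, method = c("closed", "grid"),
                            dt = 0.015, dx = 0.02, halfwidth = NULL) {
  method <- match.arg(method)
  if (method == "grid") {
    dist <- propagate_distribution(tr, params, dt = dt, dx = dx,
                                   halfwidth = halfwidth)
    return(choice_probability(dist, params))
  }
  mo <- ddm_moments(tr, params)
  p_above <- if (mo$var > 0) {
    stats::pnorm((mo$mean - params$bias) / sqrt(mo$var))
  } else {
    (mo$mean > params$bias) + 0.5 * (mo$mean == params$bias)
  }
  0.5 * params$lapse + (1 - params$lapse) * p_above
}

#' Exact mean and variance of the accumulator at trial end
#'
#' @inheritParams simulate_accumulator
#' @return List with `mean` and `var` of `a(T)`, `T = cue + delay`.
#' @export
ddm_moments <- function(tr, params) {
  ev <- puff_events(tr)
  Tend <- trial_end_time(tr)
  lam <- params$lambda
  age <- Tend - ev$time
  e1 <- exp(lam * age)
  dvar <- if (abs(lam) < 1e-12) params$sigma_a2 * Tend else
    params$sigma_a2 * expm1(2 * lam * Tend) / (2 * lam)
  list(mean = sum(ev$sign * e1),
       var = params$sigma_s2 * sum(e1^2) + dvar)
}

#' Log-likelihood of one choice
#'
#' Log of the model probability of the observed choice, floored at
#' `log(.Machine$double.xmin)` to keep optimization finite.
#'
#' @inheritParams ddm_choice_prob
#' @param choice `"left"` or `"right"`.
#' @return Log probability (scalar).
#' @export
trial_loglik <- function(tr, choice, params, method = c("closed", "grid"),
                         dt = 0.015, dx = 0.02) {
  if (!choice %in% c("left", "right"))
    stop("choice must be left or right", call. = FALSE)
  p <- ddm_choice_prob(tr, params, method = method, dt = dt, dx = dx)
  p <- if (choice == "right") p else 1 - p
  max(log(p), log(.Machine$double.xmin))
}

#' Total log-likelihood of a trial set
#'
#' Sums [trial_loglik()] over included trials. By default only decision-made
#' trials with the primary 3.8-s cue period enter (the analysis filter used
#' throughout); trials excluded by the filter are counted in the result.
#'
#' @param ts A [trial_set()].
#' @param params A [ddm_params()].
#' @param choices Optional character vector overriding the stored choices.
#' @param method,dt,dx Passed to the per-trial likelihood.
#' @param cue_duration Cue-duration filter (default 3.8; `NULL` = no filter).
#' @return List with `loglik`, `n_included`, `n_excluded`.
#' @export
dataset_loglik <- function(ts, params, choices = NULL,
                           method = c("closed", "grid"),
                           dt = 0.015, dx = 0.02, cue_duration = 3.8) {
  method <- match.arg(method)
  stopifnot(inherits(ts, "trial_set"))
  if (!is.null(choices)) {
    stopifnot(length(choices) == length(ts$trials))
  } else {
    choices <- vapply(ts$trials, `[[`, character(1), "choice")
  }
  cue <- vapply(ts$trials, `[[`, numeric(1), "cue_duration")
  include <- choices %in% c("left", "right")
  if (!is.null(cue_duration)) include <- include & abs(cue - cue_duration) < 1e-6
  if (!any(include)) stop("no trials pass the inclusion filter", call. = FALSE)
  if (method == "closed") {
    stim <- stim_from_trials(ts$trials[include])
    stim$right <- choices[include] == "right"
    ll <- loglik_stim(stim, params)
  } else {
    ll <- 0
    for (i in which(include))
      ll <- ll + trial_loglik(ts$trials[[i]], choices[i], params,
                              method = "grid", dt = dt, dx = dx)
  }
  list(loglik = ll, n_included = sum(include), n_excluded = sum(!include))
}
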