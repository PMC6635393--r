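#' Four-parameter logistic function
#'
#' `y(x) = y0 + A / (1 + exp(-(x - x0)/b))`.
#'
#' @param x Evidence values (#R - #L).
#' @param y0 Lower asymptote.
#' @param A Range.
#' @param x0 Midpoint.
#' @param b Slope scale.
#' @return Numeric vector of curve values.
#' @export
logistic4 <- function(x, y0, A, x0, b) y0 + A / (1 + exp(-(x - x0) / b))

#' Performance summary with Jeffreys binomial confidence interval
#'
#' Fraction of correct choices among decision-made trials, with the
#' Jeffreys interval: central quantiles of a `Beta(k + 1/2, n - k + 1/2)`
#' reference (lower bound forced to 0 when `k = 0`, upper to 1 when
#' `k = n`). Also reports the response fraction (decision made / total).
#'
#' @param ts A [trial_set()].
#' @param ci_level Confidence level (default 0.95; use 0.99 to match the
#'   figure convention).
#' @return An object of class `performance_summary`: list with `n`,
#'   `n_correct`, `fraction_correct`, `ci_level`, `ci_low`, `ci_high`,
#'   `response_fraction`.
#' @export
performance_summary <- function(ts, ci_level = 0.95) {
  stopifnot(inherits(ts, "trial_set"), ci_level > 0, ci_level < 1)
  total <- length(ts$trials)
  dec <- filter_trials(ts, decided = TRUE)
  n <- length(dec$trials)
  if (n == 0) stop("no decision-made trials", call. = FALSE)
  k <- sum(vapply(dec$trials, function(tr)
    identical(tr$choice, tr$correct_side), logical(1)))
  ci <- jeffreys_interval(k, n, ci_level)
  structure(list(n = n, n_correct = k, fraction_correct = k / n,
                 ci_level = ci_level, ci_low = ci[1], ci_high = ci[2],
                 response_fraction = n / total),
            class = "performance_summary")
}

#' Jeffreys interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level.
#' @return Length-2 vector `c(low, high)`.
#' @export
jeffreys_interval <- function(k, n, level = 0.95) {
  stopifnot(k >= 0, n >= 1, k <= n)
  alpha <- 1 - level
  low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k + 0.5, n - k + 0.5)
  high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 0.5, n - k + 0.5)
  c(low, high)
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf(
    "<performance_summary> %d/%d correct = %.3f (%d%% CI %.3f-%.3f), response fraction %.3f\n",
    x$n_correct, x$n, x$fraction_correct, round(100 * x$ci_level),
    x$ci_low, x$ci_high, x$response_fraction))
  invisible(x)
}

#' Choice-probability matrix over puff counts
#'
#' Right-choice fraction per (#L, #R) cell among decision-made trials.
#'
#' @param ts A [trial_set()].
#' @return Data frame in long format with columns `n_left`, `n_right`, `n`
#'   (trials in the cell), `n_right_choice`, `p_right`; only observed
#'   cells are listed (unobserved cells have `n = 0` and are omitted).
#' @export
choice_matrix <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  dec <- filter_trials(ts, decided = TRUE)
  if (length(dec$trials) == 0)
    return(data.frame(n_left = integer(), n_right = integer(), n = integer(),
                      n_right_choice = integer(), p_right = numeric()))
  pc <- puff_counts(dec)
  agg <- stats::aggregate(cbind(n = rep(1, nrow(pc)),
                                n_right_choice = pc$choice == "right"),
                          by = list(n_left = pc$n_left, n_right = pc$n_right),
                          FUN = sum)
  agg$p_right <- agg$n_right_choice / agg$n
  agg[order(agg$n_left, agg$n_right), ]
}

#' Fit the four-parameter logistic psychometric curve
#'
#' Least-squares fit of the right-choice fraction against total evidence
#' `x = #R - #L`, weighted by the per-x trial count (trials are pooled, as
#' in a meta-mouse analysis). Guided trials are excluded (they are
#' rewarded independent of choice).
#'
#' @param ts A [trial_set()].
#' @param start Optional named start values for `y0, A, x0, b`.
#' @return An object of class `psychometric_fit` with `coefficients`,
#'   `vcov`, and the aggregated `data` (x, fraction, n).
#' @export
fit_psychometric <- function(ts, start = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  dec <- filter_trials(ts, decided = TRUE, guided = FALSE)
  pc <- puff_counts(dec)
  if (nrow(pc) == 0) stop("no decision-made trials", call. = FALSE)
  agg <- stats::aggregate(cbind(n = rep(1, nrow(pc)),
                                n_right = pc$choice == "right"),
                          by = list(x = pc$delta), FUN = sum)
  agg$frac <- agg$n_right / agg$n
  if (nrow(agg) < 4)
    stop("need at least 4 distinct #R - #L values to fit the 4PL curve",
         call. = FALSE)
  if (is.null(start)) {
    lo <- stats::weighted.mean(agg$frac[agg$x < 0], agg$n[agg$x < 0])
    hi <- stats::weighted.mean(agg$frac[agg$x > 0], agg$n[agg$x > 0])
    if (!is.finite(lo)) lo <- min(agg$frac)
    if (!is.finite(hi)) hi <- max(agg$frac)
    start <- c(y0 = max(min(lo, 0.4), 0), A = min(max(hi - lo, 0.2), 1),
               x0 = 0, b = 1.5)
  }
  start <- unlist(start)[c("y0", "A", "x0", "b")]
  sw <- sqrt(agg$n)
  resid_fn <- function(p)
    sw * (agg$frac - logistic4(agg$x, p[1], p[2], p[3], p[4]))
  # bounded Levenberg-Marquardt: keeps the curve inside [0, 1] over the
  # data and keeps b strictly positive even for step-like choice data
  out <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(y0 = 0, A = 0, x0 = -20, b = 1e-3),
    upper = c(y0 = 0.5, A = 1, x0 = 20, b = 50),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (out$info %in% c(0, 9))
    stop("psychometric fit failed to converge: ", out$message, call. = FALSE)
  co <- out$par
  vc <- tryCatch({
    dof <- nrow(agg) - length(co)
    sigma2 <- out$deviance / max(dof, 1)
    sigma2 * solve(out$hessian)
  }, error = function(e) NULL)
  structure(list(coefficients = co, vcov = vc,
                 data = agg[, c("x", "frac", "n")], fitted = TRUE),
            class = "psychometric_fit")
}

#' @export
predict.psychometric_fit <- function(object, newdata, ...) {
  co <- object$coefficients
  x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
  pmin(1, pmax(0, logistic4(x, co["y0"], co["A"], co["x0"], co["b"])))
}

#' @export
print.psychometric_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<psychometric_fit%s> y0=%.3f A=%.3f x0=%.3f b=%.3f\n",
              if (x$fitted) "" else " (constructed)",
              co["y0"], co["A"], co["x0"], co["b"]))
  invisible(x)
}

#' Paired comparison of performance between conditions
#'
#' Per-subject change in fraction correct (`on - off`) with a two-tailed
#' paired t-test.
#'
#' @param off,on Data frames with columns `subject_id` and
#'   `fraction_correct` (one row per subject), e.g. built from
#'   [performance_summary()] per subject.
#' @return List with `delta` (per-subject data frame), `mean_delta`,
#'   `t_statistic`, `df`, `p_value`.
#' @export
compare_conditions <- function(off, on) {
  need <- c("subject_id", "fraction_correct")
  stopifnot(all(need %in% names(off)), all(need %in% names(on)))
  if (!setequal(off$subject_id, on$subject_id) ||
      anyDuplicated(off$subject_id) || anyDuplicated(on$subject_id))
    stop("off/on subject lists must match one-to-one", call. = FALSE)
  if (nrow(off) < 2) stop("need at least 2 subjects", call. = FALSE)
  on <- on[match(off$subject_id, on$subject_id), ]
  d <- on$fraction_correct - off$fraction_correct
  tt <- stats::t.test(on$fraction_correct, off$fraction_correct,
                      paired = TRUE, alternative = "two.sided")
  list(delta = data.frame(subject_id = off$subject_id, delta = d),
       mean_delta = mean(d),
       t_statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value)
}
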