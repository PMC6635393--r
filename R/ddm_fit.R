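#' Model variant with lapse and/or bias omitted
#'
#' Reduced accumulator models fix the lapse and/or bias parameter at 0;
#' the parameter count `k` (used by [bic()]) is 5 minus the number omitted.
#'
#' @param omit Character vector, subset of `c("lapse", "bias")`.
#' @return An object of class `ddm_variant` with fields `omit` and `k`.
#' @export
model_variant <- function(omit = character()) {
  stopifnot(all(omit %in% c("lapse", "bias")))
  omit <- unique(omit)
  structure(list(omit = omit, k = 5L - length(omit)),
            class = "ddm_variant")
}

# --- parameter transforms ---------------------------------------------------
# Internal unconstrained coordinates: lambda and bias free, variances via
# log (with a positivity floor), lapse via the logit map. Free coordinates
# depend on the variant; omitted parameters are pinned at 0.

.par_floor <- 1e-8

free_names <- function(variant) {
  nm <- c("lambda", "sigma_a2", "sigma_s2", "bias", "lapse")
  setdiff(nm, variant$omit)
}

params_to_unconstrained <- function(params, variant = model_variant()) {
  th <- unlist(params[c("lambda", "sigma_a2", "sigma_s2", "bias", "lapse")])
  u <- c(lambda = unname(th["lambda"]),
         sigma_a2 = log(max(th["sigma_a2"], .par_floor)),
         sigma_s2 = log(max(th["sigma_s2"], .par_floor)),
         bias = unname(th["bias"]),
         lapse = stats::qlogis(min(max(th["lapse"], .par_floor),
                                   1 - .par_floor)))
  u[free_names(variant)]
}

unconstrained_to_params <- function(u, variant = model_variant()) {
  full <- c(lambda = 0, sigma_a2 = log(.par_floor), sigma_s2 = log(.par_floor),
            bias = 0, lapse = -Inf)
  full[free_names(variant)] <- u
  ddm_params(
    lambda = unname(full["lambda"]),
    sigma_a2 = exp(unname(full["sigma_a2"])),
    sigma_s2 = exp(unname(full["sigma_s2"])),
    bias = if ("bias" %in% variant$omit) 0 else unname(full["bias"]),
    lapse = if ("lapse" %in% variant$omit) 0 else
      stats::plogis(unname(full["lapse"]))
  )
}

#' Draw a random parameter initialization
#'
#' Initial values for maximum-likelihood repetitions are drawn uniformly
#' from configurable ranges (defaults: `lambda` in \[-5, 5\] /s, variances
#' in \[0, 20\], `bias` in \[-3, 3\], `lapse` in \[0, 1\]).
#'
#' @param init_ranges Named list of length-2 ranges.
#' @return A [ddm_params()].
#' @export
random_init <- function(init_ranges = default_init_ranges()) {
  r <- function(nm) stats::runif(1, init_ranges[[nm]][1], init_ranges[[nm]][2])
  ddm_params(lambda = r("lambda"),
             sigma_a2 = max(r("sigma_a2"), .par_floor),
             sigma_s2 = max(r("sigma_s2"), .par_floor),
             bias = r("bias"),
             lapse = min(max(r("lapse"), .par_floor), 1 - .par_floor))
}

#' @rdname random_init
#' @export
default_init_ranges <- function() {
  list(lambda = c(-5, 5), sigma_a2 = c(0, 20), sigma_s2 = c(0, 20),
       bias = c(-3, 3), lapse = c(0, 1))
}

# central-difference gradient (the numerical-gradient contract of the fit)
central_grad <- function(fn, u, h_rel = 1e-5) {
  g <- numeric(length(u))
  for (i in seq_along(u)) {
    h <- h_rel * max(1, abs(u[i]))
    up <- u; up[i] <- u[i] + h
    dn <- u; dn[i] <- u[i] - h
    g[i] <- (fn(up) - fn(dn)) / (2 * h)
  }
  g
}

# subset a ddm_stim to a set of trial indices
stim_subset <- function(stim, keep) {
  counts <- stim$ends - stim$starts
  sel <- stim$puff_row[keep]
  rows <- unlist(sel, use.names = FALSE)
  counts_k <- counts[keep]
  ends <- cumsum(counts_k)
  structure(list(
    age = stim$age[rows], sign = stim$sign[rows],
    n = length(keep), Tend = stim$Tend[keep],
    right = stim$right[keep],
    starts = ends - counts_k, ends = ends,
    puff_row = NULL
  ), class = "ddm_stim")
}

#' Fit the accumulator model once from a given initialization
#'
#' Gradient-based maximization (BFGS with central-difference gradients in
#' unconstrained coordinates) of the closed-form dataset log-likelihood.
#' If the likelihood at the initialization is non-finite, a fresh random
#' initialization is drawn (bounded retries).
#'
#' @param ts A [trial_set()] or a prepared internal stimulus object.
#' @param variant A [model_variant()].
#' @param init A [ddm_params()] initialization; default: `n_candidates`
#'   random draws are screened and the one with the best likelihood is
#'   used (the likelihood surface has a flat chance-performance plateau at
#'   `lapse -> 1` that can trap ascent from very poor starting points).
#' @param init_ranges Ranges for redrawn initializations.
#' @param n_candidates Random initializations screened when `init` is not
#'   given.
#' @param maxit,reltol Optimizer control.
#' @param cue_duration Cue filter applied when `ts` is a trial set.
#' @return List with `params` (natural scale), `loglik`, `converged`,
#'   `n_trials`.
#' @export
fit_once <- function(ts, variant = model_variant(), init = NULL,
                     init_ranges = default_init_ranges(), n_candidates = 10,
                     maxit = 500, reltol = 1e-9, cue_duration = 3.8) {
  stim <- if (inherits(ts, "ddm_stim")) ts else
    prepare_stim(ts, cue_duration = cue_duration)
  if (stim$n < 1) stop("no trials to fit", call. = FALSE)
  negll <- function(u) {
    p <- unconstrained_to_params(u, variant)
    ll <- loglik_stim(stim, p)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  if (is.null(init)) {
    cand <- replicate(max(1, n_candidates),
                      params_to_unconstrained(random_init(init_ranges),
                                              variant),
                      simplify = FALSE)
    vals <- vapply(cand, negll, numeric(1))
    u0 <- cand[[which.min(vals)]]
  } else {
    u0 <- params_to_unconstrained(init, variant)
  }
  for (retry in 1:20) {
    if (is.finite(negll(u0)) && negll(u0) < 1e12) break
    u0 <- params_to_unconstrained(random_init(init_ranges), variant)
  }
  opt <- stats::optim(u0, fn = negll, gr = function(u) central_grad(negll, u),
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  list(params = unconstrained_to_params(opt$par, variant),
       loglik = -opt$value,
       converged = opt$convergence == 0,
       n_trials = stim$n)
}

# standard DDM-analysis inclusion: decision-made, non-guided, primary cue
prepare_stim <- function(ts, cue_duration = 3.8) {
  stopifnot(inherits(ts, "trial_set"))
  kept <- filter_trials(ts, cue_duration = cue_duration, decided = TRUE,
                        guided = FALSE)
  stim_from_trials(kept$trials)
}

stim_from_trials <- function(trials) {
  n <- length(trials)
  Tend <- vapply(trials, trial_end_time, numeric(1))
  ages <- vector("list", n)
  signs <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- puff_events(trials[[i]])
    ages[[i]] <- Tend[i] - ev$time
    signs[[i]] <- ev$sign
  }
  counts <- lengths(ages)
  ends <- cumsum(counts)
  starts <- ends - counts
  puff_row <- mapply(function(s, c) if (c) (s + 1):(s + c) else integer(),
                     starts, counts, SIMPLIFY = FALSE)
  structure(list(
    age = unlist(ages), sign = unlist(signs),
    n = n, Tend = Tend,
    right = vapply(trials, `[[`, character(1), "choice") == "right",
    starts = starts, ends = ends, puff_row = puff_row
  ), class = "ddm_stim")
}

# fast grouped closed-form log-likelihood (cumulative-sum aggregation)
loglik_stim <- function(stim, params) {
  pr <- stim_choice_prob(stim, params)
  p_obs <- ifelse(stim$right, pr, 1 - pr)
  sum(pmax(log(p_obs), log(.Machine$double.xmin)))
}

stim_choice_prob <- function(stim, params) {
  lam <- min(50, max(-50, params$lambda))
  e1 <- exp(lam * stim$age)
  cs1 <- c(0, cumsum(stim$sign * e1))
  cs2 <- c(0, cumsum(e1 * e1))
  mu <- cs1[stim$ends + 1] - cs1[stim$starts + 1]
  s2 <- cs2[stim$ends + 1] - cs2[stim$starts + 1]
  dvar <- if (abs(lam) < 1e-12) params$sigma_a2 * stim$Tend else
    params$sigma_a2 * expm1(2 * lam * stim$Tend) / (2 * lam)
  v <- params$sigma_s2 * s2 + dvar
  z <- ifelse(v > 0, (mu - params$bias) / sqrt(pmax(v, 0)),
              sign(mu - params$bias) * Inf)
  p_above <- ifelse(is.nan(z), 0.5, stats::pnorm(z))
  0.5 * params$lapse + (1 - params$lapse) * p_above
}

#' Positive-semidefiniteness check of the likelihood Hessian
#'
#' Fit repetitions are accepted only when the numerical Hessian of the
#' negative log-likelihood with respect to the natural-scale free
#' parameters, evaluated at the optimum, is positive semidefinite: the
#' smallest eigenvalue must be at least `-tol` times the largest.
#'
#' @param params Fitted [ddm_params()].
#' @param ts A [trial_set()] or prepared stimulus object.
#' @param variant A [model_variant()].
#' @param tol Relative eigenvalue tolerance (default 1e-6).
#' @param cue_duration Cue filter applied when `ts` is a trial set.
#' @return Logical flag (`FALSE` for non-finite Hessian entries).
#' @export
hessian_psd_check <- function(params, ts, variant = model_variant(),
                              tol = 1e-6, cue_duration = 3.8) {
  stim <- if (inherits(ts, "ddm_stim")) ts else
    prepare_stim(ts, cue_duration = cue_duration)
  nm <- free_names(variant)
  th0 <- unlist(params[nm])
  f <- function(th) {
    full <- list(lambda = 0, sigma_a2 = 0, sigma_s2 = 0, bias = 0, lapse = 0)
    full[nm] <- as.list(th)
    p <- list(lambda = full$lambda,
              sigma_a2 = max(full$sigma_a2, 0),
              sigma_s2 = max(full$sigma_s2, 0),
              bias = full$bias,
              lapse = min(max(full$lapse, 0), 1))
    class(p) <- "ddm_params"
    -loglik_stim(stim, p)
  }
  H <- tryCatch(pracma::hessian(f, th0), error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H))) return(FALSE)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}

#' Maximum-likelihood fit with random restarts and trial subsampling
#'
#' The fitting protocol: the model is fit `n_reps` times; each repetition
#' draws a random initialization and omits a random `holdout` fraction of
#' trials; a repetition is kept only if the optimizer converged and the
#' Hessian of the likelihood at its optimum is positive semidefinite.
#' Median parameters and repetition quantiles are reported across kept
#' repetitions, together with the cross-validated choice-prediction
#' accuracy on each repetition's held-out trials (predicting right when
#' `p(R|theta) > 0.5`, right on exact ties).
#'
#' @param ts A [trial_set()].
#' @param variant A [model_variant()].
#' @param n_reps Number of fit repetitions (the full protocol uses 1000; a
#'   reduced count gives a faster profile with wider repetition spread).
#' @param holdout Fraction of trials omitted per repetition (default 0.2).
#' @param init_ranges Initialization ranges, see [random_init()].
#' @param min_trials Minimum included-trial floor (default 100).
#' @param cue_duration Cue-duration filter (default 3.8 s; `NULL` keeps
#'   short-cue trials too).
#' @param hessian_filter Apply the PSD acceptance filter (default `TRUE`).
#' @param progress Print per-repetition progress (default `FALSE`).
#' @return An object of class `ddm_fit`: list with `reps` (one row per
#'   repetition: parameters, log-likelihood, convergence/PSD/acceptance
#'   flags, held-out accuracy), `median_params`, `quantiles` (2.5/50/97.5%
#'   per parameter over accepted repetitions), `cv_accuracy` (mean, sd),
#'   `loglik_full` (full-data log-likelihood at the median parameters),
#'   `n_trials`, `n_accepted`, `variant`.
#' @export
fit_ddm <- function(ts, variant = model_variant(), n_reps = 50,
                    holdout = 0.2, init_ranges = default_init_ranges(),
                    min_trials = 100, cue_duration = 3.8,
                    hessian_filter = TRUE, progress = FALSE) {
  stopifnot(n_reps >= 1, holdout >= 0, holdout < 1)
  stim <- prepare_stim(ts, cue_duration = cue_duration)
  if (stim$n < min_trials)
    stop(sprintf("only %d included trials (< floor of %d)", stim$n, min_trials),
         call. = FALSE)
  nm <- c("lambda", "sigma_a2", "sigma_s2", "bias", "lapse")
  reps <- data.frame(matrix(NA_real_, n_reps, length(nm),
                            dimnames = list(NULL, nm)))
  reps$loglik <- NA_real_
  reps$converged <- FALSE
  reps$hessian_psd <- NA
  reps$accepted <- FALSE
  reps$cv_accuracy <- NA_real_
  n_hold <- round(holdout * stim$n)
  for (r in seq_len(n_reps)) {
    hold <- if (n_hold > 0) sample.int(stim$n, n_hold) else integer()
    train_idx <- setdiff(seq_len(stim$n), hold)
    train <- stim_subset(stim, train_idx)
    fit <- fit_once(train, variant = variant, init_ranges = init_ranges)
    reps[r, nm] <- unlist(fit$params[nm])
    reps$loglik[r] <- fit$loglik
    reps$converged[r] <- fit$converged
    if (fit$converged) {
      psd <- if (hessian_filter)
        hessian_psd_check(fit$params, train, variant = variant) else TRUE
      reps$hessian_psd[r] <- psd
      reps$accepted[r] <- psd
      if (length(hold) > 0) {
        test <- stim_subset(stim, hold)
        pr <- stim_choice_prob(test, fit$params)
        pred_right <- pr >= 0.5
        reps$cv_accuracy[r] <- mean(pred_right == test$right)
      }
    }
    if (progress)
      message(sprintf("rep %d/%d: lnL=%.1f conv=%s psd=%s", r, n_reps,
                      fit$loglik, fit$converged, reps$hessian_psd[r]))
  }
  acc <- reps[reps$accepted, , drop = FALSE]
  if (nrow(acc) == 0)
    stop(sprintf(
      "no accepted fit repetitions (%d/%d converged, %d passed the Hessian filter)",
      sum(reps$converged), n_reps, sum(reps$hessian_psd %in% TRUE)),
      call. = FALSE)
  med <- vapply(nm, function(p) stats::median(acc[[p]]), numeric(1))
  qs <- t(vapply(nm, function(p)
    stats::quantile(acc[[p]], c(0.025, 0.5, 0.975), names = FALSE),
    numeric(3)))
  colnames(qs) <- c("q2.5", "median", "q97.5")
  med_params <- ddm_params(unname(med["lambda"]),
                           max(unname(med["sigma_a2"]), 0),
                           max(unname(med["sigma_s2"]), 0),
                           unname(med["bias"]),
                           min(max(unname(med["lapse"]), 0), 1))
  structure(list(
    reps = reps,
    median_params = med_params,
    quantiles = qs,
    cv_accuracy = c(mean = mean(acc$cv_accuracy, na.rm = TRUE),
                    sd = stats::sd(acc$cv_accuracy)),
    loglik_full = loglik_stim(stim, med_params),
    n_trials = stim$n,
    n_accepted = nrow(acc),
    variant = variant
  ), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  tau <- tau_from_lambda(x$median_params$lambda)
  cat(sprintf("<ddm_fit> %d/%d repetitions accepted, %d trials\n",
              x$n_accepted, nrow(x$reps), x$n_trials))
  print(round(x$quantiles, 4))
  cat(sprintf("memory time constant: %.3g s (%s)\n", tau$tau, tau$regime))
  cat(sprintf("held-out choice-prediction accuracy: %.3f +/- %.3f\n",
              x$cv_accuracy["mean"], x$cv_accuracy["sd"]))
  cat(sprintf("full-data lnL at median parameters: %.2f\n", x$loglik_full))
  invisible(x)
}

#' Cross-validated choice-prediction accuracy on held-out trials
#'
#' Fits the model on training trials (best of `n_starts` random
#' initializations) and predicts each held-out trial's choice by
#' thresholding `p(R|theta)` at 0.5 (an exact 0.5 predicts right).
#'
#' @param train,test Disjoint [trial_set()]s.
#' @param variant A [model_variant()].
#' @param n_starts Random restarts for the training fit.
#' @param cue_duration Cue filter.
#' @return Fraction of held-out choices predicted correctly.
#' @export
cv_choice_accuracy <- function(train, test, variant = model_variant(),
                               n_starts = 3, cue_duration = 3.8) {
  test_stim <- if (inherits(test, "ddm_stim")) test else
    prepare_stim(test, cue_duration = cue_duration)
  if (test_stim$n == 0) stop("empty test set", call. = FALSE)
  train_stim <- if (inherits(train, "ddm_stim")) train else
    prepare_stim(train, cue_duration = cue_duration)
  best <- NULL
  for (s in seq_len(n_starts)) {
    f <- fit_once(train_stim, variant = variant)
    if (is.null(best) || (f$converged && f$loglik > best$loglik)) best <- f
  }
  pr <- stim_choice_prob(test_stim, best$params)
  mean((pr >= 0.5) == test_stim$right)
}

#' Bayesian information criterion, larger-is-better convention
#'
#' `BIC = lnL - k * ln(n) / 2`. Note the sign convention: this is the
#' negative of the textbook `k ln n - 2 lnL` (up to the factor 2), so
#' larger values indicate a favored model. [relative_bic()] reports
#' `BIC(variant) - BIC(full)`, positive when the reduced variant is
#' favored.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of fitted parameters.
#' @param n Number of trials used in the fit.
#' @return BIC value (larger is better under this convention).
#' @export
bic <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  loglik - k * log(n) / 2
}

#' @rdname bic
#' @param variant,full Lists (or `ddm_fit` objects) with elements
#'   `loglik`/`loglik_full`, a `variant` or `k`, and matching `n_trials`/`n`.
#' @export
relative_bic <- function(variant, full) {
  part <- function(x) {
    if (inherits(x, "ddm_fit"))
      list(loglik = x$loglik_full, k = x$variant$k, n = x$n_trials)
    else list(loglik = x$loglik, k = x$k, n = x$n)
  }
  v <- part(variant); f <- part(full)
  if (v$n != f$n)
    warning("variant and full model fit on different trial counts")
  bic(v$loglik, v$k, v$n) - bic(f$loglik, f$k, f$n)
}
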