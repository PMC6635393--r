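#' Logistic regression of choice on binned evidence
#'
#' Fits the no-intercept logistic model
#' `ln(p/(1-p)) = beta_1 E_1 + ... + beta_n E_n`, where `E_i` is the
#' #R - #L puff count in the i-th temporally uniform bin of the cue period
#' (see [bin_evidence()]), to decision-made, non-guided trials with the
#' primary 3.8-s cue period. Reports asymptotic standard errors and 99%
#' confidence intervals; optionally bootstrap SDs.
#'
#' Near-deterministic choice data can be completely separable, in which
#' case the unpenalized fit diverges; this raises an error unless
#' `ridge = TRUE`, which applies a documented tiny ridge penalty.
#'
#' @param ts A [trial_set()].
#' @param n_bins Number of evidence bins (default 3).
#' @param intercept Include an intercept (default `FALSE`, matching the
#'   model; bias is instead captured by the accumulator-model branch).
#' @param ridge Enable the tiny-ridge fallback for separable data.
#' @param ridge_lambda Ridge penalty (default 1e-4).
#' @param n_boot Bootstrap resamples for weight SDs (0 = none; the
#'   standard protocol uses 100).
#' @param ci_level Confidence level (default 0.99).
#' @param cue_duration Cue filter (default 3.8 s).
#' @param condition Optional condition-label filter.
#' @return An object of class `choice_regression`: list with `weights`,
#'   `se`, `ci` (matrix low/high), `boot_sd` and `boot` (when
#'   `n_boot > 0`), `n`, `n_bins`, `cv_accuracy` slot (filled by
#'   [cv_regression_accuracy()] callers), `condition`.
#' @export
fit_choice_regression <- function(ts, n_bins = 3, intercept = FALSE,
                                  ridge = FALSE, ridge_lambda = 1e-4,
                                  n_boot = 0, ci_level = 0.99,
                                  cue_duration = 3.8, condition = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  dec <- filter_trials(ts, condition = condition, cue_duration = cue_duration,
                       decided = TRUE, guided = FALSE)
  n <- length(dec$trials)
  y <- vapply(dec$trials, `[[`, character(1), "choice") == "right"
  if (sum(y) < 2 || sum(!y) < 2)
    stop("need at least 2 trials of each choice", call. = FALSE)
  E <- evidence_matrix(dec, n_bins)
  core <- regression_core(E, y, intercept, ridge, ridge_lambda)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci <- cbind(low = core$weights - z * core$se,
              high = core$weights + z * core$se)
  out <- structure(list(weights = core$weights, se = core$se, ci = ci,
                        ci_level = ci_level, n = n, n_bins = n_bins,
                        intercept = intercept, ridge = ridge,
                        boot = NULL, boot_sd = NULL,
                        condition = condition %||% "all"),
                   class = "choice_regression")
  if (n_boot > 0) {
    bw <- bootstrap_weights(dec, n_boot = n_boot, n_bins = n_bins,
                            intercept = intercept, ridge = ridge,
                            ridge_lambda = ridge_lambda,
                            cue_duration = cue_duration)
    out$boot <- bw$boot
    out$boot_sd <- bw$sd
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared GLM/ridge core; returns weights and asymptotic SEs for the bin
# coefficients (intercept, if any, is dropped from the report)
regression_core <- function(E, y, intercept, ridge, ridge_lambda) {
  n_bins <- ncol(E)
  if (!ridge) {
    df <- as.data.frame(E)
    df$y <- y
    form <- stats::as.formula(paste("y ~", if (intercept) "" else "0 +",
                                    paste(colnames(E), collapse = " + ")))
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(form, family = stats::binomial(), data = df),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    if (separated || !fit$converged || any(!is.finite(se)) ||
        max(abs(co)) > 25)
      stop(paste("complete (or quasi-) separation detected: the",
                 "unpenalized logistic fit diverges; refit with",
                 "ridge = TRUE (tiny ridge penalty) or use bootstrap",
                 "uncertainty"), call. = FALSE)
    keep <- colnames(E)
    return(list(weights = co[keep], se = se[keep]))
  }
  gfit <- glmnet::glmnet(E, factor(y, levels = c(FALSE, TRUE)),
                         family = "binomial", alpha = 0,
                         lambda = ridge_lambda, intercept = intercept,
                         standardize = FALSE)
  co <- as.numeric(gfit$beta[, 1])
  names(co) <- colnames(E)
  # asymptotic SEs from the unpenalized information at the ridge solution
  eta <- as.numeric(E %*% co) +
    (if (intercept) gfit$a0[1] else 0)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-10)
  XtWX <- crossprod(E * sqrt(w))
  se <- sqrt(diag(solve(XtWX + diag(ridge_lambda, ncol(E)))))
  names(se) <- colnames(E)
  list(weights = co, se = se)
}

#' @export
print.choice_regression <- function(x, ...) {
  cat(sprintf("<choice_regression> %d trials, %d bins (%s)%s\n",
              x$n, x$n_bins, x$condition,
              if (x$ridge) ", ridge" else ""))
  tab <- data.frame(weight = x$weights, se = x$se,
                    ci_low = x$ci[, "low"], ci_high = x$ci[, "high"])
  if (!is.null(x$boot_sd)) tab$boot_sd <- x$boot_sd
  print(round(tab, 4))
  invisible(x)
}

#' Bootstrap standard deviations of regression weights
#'
#' Resamples trials with replacement, refits the regression, and returns
#' the SD of each weight across resamples (the standard protocol uses 100
#' resamples). Resamples containing only one choice class are skipped and
#' counted; more than 20% skipped is an error.
#'
#' @param ts A [trial_set()] (already filtered or not; the standard filter
#'   is applied).
#' @param n_boot Number of resamples (>= 2).
#' @inheritParams fit_choice_regression
#' @return List with `sd` (per-bin SD), `boot` (resample x bin matrix),
#'   `n_skipped`.
#' @export
bootstrap_weights <- function(ts, n_boot = 100, n_bins = 3,
                              intercept = FALSE, ridge = FALSE,
                              ridge_lambda = 1e-4, cue_duration = 3.8) {
  stopifnot(n_boot >= 2)
  dec <- filter_trials(ts, cue_duration = cue_duration, decided = TRUE,
                       guided = FALSE)
  n <- length(dec$trials)
  E <- evidence_matrix(dec, n_bins)
  y <- vapply(dec$trials, `[[`, character(1), "choice") == "right"
  boot <- matrix(NA_real_, n_boot, n_bins,
                 dimnames = list(NULL, colnames(E)))
  skipped <- 0
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    yy <- y[idx]
    if (sum(yy) < 2 || sum(!yy) < 2) {
      skipped <- skipped + 1
      next
    }
    w <- tryCatch(
      regression_core(E[idx, , drop = FALSE], yy, intercept, ridge,
                      ridge_lambda)$weights,
      error = function(e) NULL)
    if (is.null(w)) skipped <- skipped + 1 else boot[r, ] <- w
  }
  if (skipped > 0.2 * n_boot)
    stop(sprintf("%d of %d bootstrap resamples unusable", skipped, n_boot),
         call. = FALSE)
  list(sd = apply(boot, 2, stats::sd, na.rm = TRUE), boot = boot,
       n_skipped = skipped)
}

#' Stratified k-fold choice-prediction accuracy of the regression
#'
#' Folds are stratified by choice; the model is fit on k-1 folds and each
#' held-out trial's choice is predicted by thresholding the fitted
#' P(right) at 0.5 (an exact 0.5 predicts right). The standard protocol
#' uses k = 3.
#'
#' @param ts A [trial_set()].
#' @param k Number of folds (>= 2).
#' @inheritParams fit_choice_regression
#' @return Overall fraction of held-out choices predicted correctly.
#' @export
cv_regression_accuracy <- function(ts, k = 3, n_bins = 3, intercept = FALSE,
                                   ridge = FALSE, ridge_lambda = 1e-4,
                                   cue_duration = 3.8) {
  stopifnot(k >= 2)
  dec <- filter_trials(ts, cue_duration = cue_duration, decided = TRUE,
                       guided = FALSE)
  n <- length(dec$trials)
  E <- evidence_matrix(dec, n_bins)
  y <- vapply(dec$trials, `[[`, character(1), "choice") == "right"
  if (sum(y) < k || sum(!y) < k)
    stop("cannot stratify: a class has fewer trials than folds",
         call. = FALSE)
  fold <- integer(n)
  fold[y] <- sample(rep_len(seq_len(k), sum(y)))
  fold[!y] <- sample(rep_len(seq_len(k), sum(!y)))
  correct <- 0
  for (f in seq_len(k)) {
    test <- fold == f
    w <- regression_core(E[!test, , drop = FALSE], y[!test], intercept,
                         ridge, ridge_lambda)$weights
    eta <- as.numeric(E[test, , drop = FALSE] %*% w)
    pred_right <- stats::plogis(eta) >= 0.5
    correct <- correct + sum(pred_right == y[test])
  }
  correct / n
}

#' Average regression weights across conditions, aligned to light onset
#'
#' For sub-cue-period light conditions (first/middle/last third), each
#' condition's three bin weights are re-indexed by lag relative to the
#' light-carrying bin (lag 0 = the bin in which light was delivered), and
#' weights at each lag are averaged across the conditions in which that
#' lag exists. For example, the lag +1 mean combines the second bin of the
#' first-third condition with the third bin of the middle-third condition.
#' Bootstrap SDs per lag are computed by averaging each condition's r-th
#' bootstrap replicate at that lag and taking the SD across replicates
#' (requires the per-condition fits to carry bootstrap draws).
#'
#' @param results Named list of [fit_choice_regression()] results, one per
#'   condition.
#' @param light_bins Named integer vector giving the 1-based light bin of
#'   each condition; defaults map `first-third`, `middle-third`,
#'   `last-third` to bins 1, 2, 3.
#' @return An object of class `aligned_weights`: data frame with columns
#'   `lag`, `mean`, `boot_sd`, `n_conditions`.
#' @export
align_weights_to_light <- function(results,
                                   light_bins = c("first-third" = 1,
                                                  "middle-third" = 2,
                                                  "last-third" = 3)) {
  stopifnot(is.list(results), length(results) >= 1,
            !is.null(names(results)),
            all(names(results) %in% names(light_bins)))
  n_bins <- unique(vapply(results, `[[`, numeric(1), "n_bins"))
  stopifnot(length(n_bins) == 1)
  lags <- seq.int(-(n_bins - 1), n_bins - 1)
  have_boot <- all(vapply(results, function(r) !is.null(r$boot), logical(1)))
  n_rep <- if (have_boot)
    min(vapply(results, function(r) nrow(r$boot), integer(1))) else 0
  rows <- lapply(lags, function(l) {
    contrib <- Filter(function(nm) {
      b <- light_bins[[nm]] + l
      b >= 1 && b <= n_bins
    }, names(results))
    if (!length(contrib)) return(NULL)
    w <- vapply(contrib, function(nm)
      unname(results[[nm]]$weights[light_bins[[nm]] + l]), numeric(1))
    bsd <- NA_real_
    if (have_boot && n_rep >= 2) {
      reps <- vapply(seq_len(n_rep), function(r) {
        mean(vapply(contrib, function(nm)
          results[[nm]]$boot[r, light_bins[[nm]] + l], numeric(1)),
          na.rm = TRUE)
      }, numeric(1))
      bsd <- stats::sd(reps, na.rm = TRUE)
    }
    data.frame(lag = l, mean = mean(w), boot_sd = bsd,
               n_conditions = length(contrib))
  })
  structure(do.call(rbind, rows), class = c("aligned_weights", "data.frame"))
}

#' Shuffle control for the light-onset-aligned regression
#'
#' Permutes the condition labels across light-on trials (destroying the
#' association between light timing and evidence weighting while keeping
#' everything else intact), then reruns the per-condition regressions and
#' the light-onset alignment. On genuinely impaired data the shuffled
#' aligned weights are flat across lags.
#'
#' @param ts A [trial_set()] spanning at least two sub-cue light-timing
#'   conditions.
#' @param n_bins,n_boot,ridge As in [fit_choice_regression()].
#' @return An `aligned_weights` object for the shuffled data.
#' @export
shuffle_control <- function(ts, n_bins = 3, n_boot = 100, ridge = FALSE) {
  stopifnot(inherits(ts, "trial_set"))
  third_conds <- c("first-third", "middle-third", "last-third")
  labels <- vapply(ts$trials, `[[`, character(1), "condition_label")
  on_idx <- which(labels %in% third_conds)
  present <- unique(labels[on_idx])
  if (length(present) < 2)
    stop("need light-on trials from at least 2 light-timing conditions",
         call. = FALSE)
  shuffled <- ts
  new_labels <- sample(labels[on_idx])
  for (j in seq_along(on_idx))
    shuffled$trials[[on_idx[j]]]$condition_label <- new_labels[j]
  fits <- lapply(present, function(cond)
    fit_choice_regression(shuffled, n_bins = n_bins, n_boot = n_boot,
                          ridge = ridge, condition = cond))
  names(fits) <- present
  align_weights_to_light(fits)
}
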