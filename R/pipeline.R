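#' Reference parameter sets for the synthetic study
#'
#' `baseline_ddm_params()` describes well-trained baseline behavior: a
#' long memory time constant (tau about 6.7 s, lambda about -0.15 /s),
#' modest accumulator diffusion noise, per-pulse noise near 1, no bias and
#' a small lapse rate. `impaired_ddm_params()` describes behavior under
#' cue-period cerebellar disruption: a roughly tenfold shorter time
#' constant (tau about 0.72 s) and increased diffusion noise.
#'
#' @return A [ddm_params()].
#' @export
baseline_ddm_params <- function() {
  ddm_params(lambda = -1 / 6.7, sigma_a2 = 0.5, sigma_s2 = 1,
             bias = 0, lapse = 0.05)
}

#' @rdname baseline_ddm_params
#' @export
impaired_ddm_params <- function() {
  ddm_params(lambda = -1 / 0.72, sigma_a2 = 2, sigma_s2 = 1,
             bias = 0, lapse = 0.1)
}

write_manifest <- function(dir, seed, extra = list()) {
  manifest <- c(list(
    package = "puffddm",
    version = as.character(utils::packageVersion("puffddm")),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = as.character(getRversion())
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate trials and write them to a run directory
#'
#' Generates sessions with the configured condition mix, simulates choices
#' with the requested agent, and writes `trials.csv` plus a manifest
#' recording the seed and counts.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [task_config()].
#' @param n_trials Total number of trials.
#' @param agent `"ddm"` (default; choices from [ddm_agent_choices()] at
#'   `params`) or `"psychometric"` (choices from [apply_impairment()] at
#'   `curve`/`scenario`).
#' @param params A [ddm_params()] for the DDM agent.
#' @param curve,scenario Psychometric curve and [impairment_scenario()]
#'   for the psychometric agent.
#' @param seed Integer seed; all randomness in the run flows from it.
#' @param force Overwrite existing outputs (default `FALSE`).
#' @return The generated [trial_set()], invisibly; side effect: files
#'   under `out_dir`.
#' @export
simulate_study <- function(out_dir, config = task_config(), n_trials = 1000,
                           agent = c("ddm", "psychometric"),
                           params = baseline_ddm_params(),
                           curve = psychometric_curve(),
                           scenario = impairment_scenario("none"),
                           seed = 1, force = FALSE) {
  agent <- match.arg(agent)
  trials_path <- file.path(out_dir, "trials.csv")
  if (file.exists(trials_path) && !force)
    stop("output exists (use force = TRUE): ", trials_path, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  ts <- generate_session(config, n_trials = n_trials)
  ts <- if (agent == "ddm") ddm_agent_choices(ts, params) else
    apply_impairment(ts, scenario, curve)
  write_trials(ts, trials_path)
  labels <- vapply(ts$trials, `[[`, character(1), "condition_label")
  write_manifest(out_dir, seed, list(
    stage = "simulate", agent = agent, n_trials = n_trials,
    condition_counts = as.list(table(labels))))
  invisible(ts)
}

#' Fit the accumulator model per condition and tabulate model comparison
#'
#' Runs [fit_ddm()] on each requested condition of a trial file or trial
#' set (the published protocol fits light-off, full-cue-period light, and
#' delay-period light), evaluates the reduced model variants on the
#' light-off condition, and writes per-condition fit summaries and a
#' relative-BIC table as JSON.
#'
#' @param trials A [trial_set()] or a path readable by [read_trials()].
#' @param out_dir Output directory.
#' @param conditions Condition labels to fit (those present are used).
#' @param n_reps Fit repetitions per condition.
#' @param variants Named list of [model_variant()]s to compare on the
#'   first condition (default full, no-lapse, no-bias).
#' @param seed Integer seed.
#' @return Named list of `ddm_fit` objects (plus `delta_bic` table),
#'   invisibly; side effect: JSON files under `out_dir`.
#' @export
fit_study_ddm <- function(trials, out_dir,
                          conditions = c("light-off", "full-cue", "delay"),
                          n_reps = 20,
                          variants = list(
                            full = model_variant(),
                            no_lapse = model_variant("lapse"),
                            no_bias = model_variant("bias")),
                          seed = 1) {
  ts <- if (inherits(trials, "trial_set")) trials else read_trials(trials)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  labels <- vapply(ts$trials, `[[`, character(1), "condition_label")
  conditions <- intersect(conditions, unique(labels))
  fits <- list()
  for (cond in conditions) {
    sub <- filter_trials(ts, condition = cond)
    fits[[cond]] <- fit_ddm(sub, n_reps = n_reps)
    q <- fits[[cond]]$quantiles
    tau <- tau_from_lambda(fits[[cond]]$median_params$lambda)
    jsonlite::write_json(list(
      condition = cond,
      parameters = apply(q, 1, as.list),
      tau_s = tau$tau, regime = tau$regime,
      n_trials = fits[[cond]]$n_trials,
      n_accepted = fits[[cond]]$n_accepted,
      cv_accuracy = as.list(fits[[cond]]$cv_accuracy),
      loglik_full = fits[[cond]]$loglik_full,
      bic_convention = "lnL - k*ln(n)/2 (larger favored)"
    ), file.path(out_dir, paste0("fit_", gsub("[^a-z0-9]+", "_", cond),
                                 ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  base_cond <- conditions[1]
  sub <- filter_trials(ts, condition = base_cond)
  vfits <- lapply(variants, function(v)
    fit_ddm(sub, variant = v, n_reps = max(3, ceiling(n_reps / 4)),
            hessian_filter = FALSE))
  dbic <- vapply(vfits, function(v) relative_bic(v, vfits$full), numeric(1))
  delta_bic <- data.frame(variant = names(variants),
                          k = vapply(variants, `[[`, integer(1), "k"),
                          delta_bic = dbic)
  jsonlite::write_json(delta_bic,
                       file.path(out_dir, "delta_bic.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA)
  write_manifest(out_dir, seed, list(stage = "fit-ddm",
                                     conditions = conditions,
                                     n_reps = n_reps))
  invisible(c(fits, list(delta_bic = delta_bic)))
}

#' Per-condition choice regression, alignment and shuffle control
#'
#' Runs the binned-evidence choice regression on each light condition
#' present, with bootstrap SDs and k-fold accuracy, the light-onset
#' aligned averaging across sub-cue-period conditions, and the label
#' shuffle control; writes a flat CSV of weights and a JSON summary.
#'
#' @param trials A [trial_set()] or a path readable by [read_trials()].
#' @param out_dir Output directory.
#' @param n_boot Bootstrap resamples (default 100).
#' @param k Cross-validation folds (default 3).
#' @param seed Integer seed.
#' @return List with `fits`, `aligned`, `shuffle`, `cv`, invisibly; side
#'   effect: files under `out_dir`.
#' @export
regress_study <- function(trials, out_dir, n_boot = 100, k = 3, seed = 1) {
  ts <- if (inherits(trials, "trial_set")) trials else read_trials(trials)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  labels <- vapply(ts$trials, `[[`, character(1), "condition_label")
  conds <- intersect(condition_labels(), unique(labels))
  conds <- setdiff(conds, "guided")
  fits <- lapply(conds, function(cond)
    fit_choice_regression(ts, n_boot = n_boot, condition = cond))
  names(fits) <- conds
  cv <- vapply(conds, function(cond)
    cv_regression_accuracy(filter_trials(ts, condition = cond), k = k),
    numeric(1))
  third_conds <- intersect(c("first-third", "middle-third", "last-third"),
                           conds)
  aligned <- NULL
  shuffle <- NULL
  if (length(third_conds) >= 1)
    aligned <- align_weights_to_light(fits[third_conds])
  if (length(third_conds) >= 2)
    shuffle <- shuffle_control(ts, n_boot = n_boot)
  rows <- do.call(rbind, lapply(conds, function(cond) {
    f <- fits[[cond]]
    data.frame(condition = cond, bin = seq_len(f$n_bins),
               weight = unname(f$weights), se = unname(f$se),
               ci_low = unname(f$ci[, "low"]), ci_high = unname(f$ci[, "high"]),
               boot_sd = if (is.null(f$boot_sd)) NA_real_ else
                 unname(f$boot_sd),
               n = f$n, cv_accuracy = cv[[cond]])
  }))
  utils::write.csv(rows, file.path(out_dir, "regression_weights.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    weights = rows,
    aligned = aligned, shuffle = shuffle
  ), file.path(out_dir, "regression.json"), dataframe = "rows",
  pretty = TRUE, digits = NA, na = "null")
  write_manifest(out_dir, seed, list(stage = "regress", n_boot = n_boot,
                                     k = k, conditions = conds))
  invisible(list(fits = fits, aligned = aligned, shuffle = shuffle, cv = cv))
}

#' Reproduce the synthetic study end to end at desk scale
#'
#' Chains the pipeline on synthetic data: simulates baseline behavior with
#' the accumulator agent, fits the psychometric curve, simulates
#' light-condition behavior (baseline vs shortened-memory parameters),
#' runs the accumulator fits with model comparison, simulates the
#' retention-impairment scenario and runs the regression branch with
#' alignment and shuffle control. Problem sizes default to a reduced
#' profile that finishes at desk scale; see the arguments.
#'
#' @param out_dir Run directory; subdirectories `trials/`, `fits/`,
#'   `regression/` are created.
#' @param seed Integer seed for the whole run.
#' @param n_trials Trials per simulated condition (default 4000).
#' @param n_reps Fit repetitions per condition (default 10).
#' @param n_boot Bootstrap resamples (default 100).
#' @param force Overwrite an existing run directory.
#' @return List of stage results, invisibly.
#' @export
reproduce_synthetic_study <- function(out_dir, seed = 1, n_trials = 4000,
                                      n_reps = 10, n_boot = 100,
                                      force = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_base <- task_config(light_fraction = 0, p_long = 1)
  cfg_mix <- task_config(light_fraction = 0.25, p_long = 1,
                         light_schedule = c("full-cue" = 1))
  base <- simulate_study(file.path(out_dir, "trials"), cfg_base,
                         n_trials = n_trials, agent = "ddm",
                         params = baseline_ddm_params(), seed = seed,
                         force = force)
  curve <- fit_psychometric(base)
  set.seed(seed + 1)
  light <- generate_session(task_config(light_fraction = 1, p_long = 1),
                            n_trials = n_trials)
  light <- ddm_agent_choices(light, impaired_ddm_params())
  both <- trial_set(c(base$trials, light$trials), validate = FALSE)
  fits <- fit_study_ddm(both, file.path(out_dir, "fits"),
                        conditions = c("light-off", "full-cue"),
                        n_reps = n_reps, seed = seed + 2)
  set.seed(seed + 3)
  cfg_thirds <- task_config(light_fraction = 0.5, p_long = 1,
                            light_schedule = c("first-third" = 1 / 3,
                                               "middle-third" = 1 / 3,
                                               "last-third" = 1 / 3))
  thirds <- generate_session(cfg_thirds, n_trials = 2 * n_trials)
  thirds <- apply_impairment(thirds, impairment_scenario("retention"), curve)
  reg <- regress_study(thirds, file.path(out_dir, "regression"),
                       n_boot = n_boot, seed = seed + 4)
  invisible(list(baseline = base, curve = curve, fits = fits,
                 regression = reg))
}
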