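#' Construct a single behavioral trial
#'
#' A trial records the stimulus a mouse received (independent streams of
#' left/right whisker air puffs during a cue period), the timing structure
#' (cue period and delay), an optional optogenetic light window, and the
#' outcome (first-lick choice). All times are in seconds from cue onset;
#' events during the delay are indexed as `cue_duration + offset`.
#'
#' A puff's time is its onset. Puff width (40 ms in the task) is never used
#' by any analysis in this package.
#'
#' @param puffs_left,puffs_right Numeric vectors of puff onset times (s).
#' @param cue_duration Cue period duration (s); the task uses 3.8 s (85% of
#'   trials) or 1.5 s (15%).
#' @param delay_duration Delay between cue offset and response (s); 0.8 s in
#'   the standard task.
#' @param light_window `NULL` for light-off trials, otherwise a list with
#'   elements `start`, `end` (s) and `side` (one of `"left"`, `"right"`,
#'   `"bilateral"`).
#' @param guided Logical; guided non-memory trials have puffs on one side
#'   only during the cue period plus regular guide puffs during the delay,
#'   and are rewarded independent of choice.
#' @param choice `"left"`, `"right"`, or `"none"` (no decision lick).
#' @param correct_side `"left"` or `"right"`; the side with strictly more
#'   cue-period puffs.
#' @param decision_latency Optional latency (s) from end of delay to the
#'   first (decision) lick; `NA` if unknown.
#' @param subject_id,session_id,condition_label Optional metadata labels.
#' @param trial_index Optional integer index within the session.
#' @return An object of class `puff_trial`.
#' @seealso [validate_trial()], [bin_evidence()], [trial_set()]
#' @export
trial <- function(puffs_left = numeric(), puffs_right = numeric(),
                  cue_duration = 3.8, delay_duration = 0.8,
                  light_window = NULL, guided = FALSE,
                  choice = "none", correct_side = NULL,
                  decision_latency = NA_real_,
                  subject_id = "sim", session_id = "sim",
                  condition_label = "light-off", trial_index = NA_integer_) {
  puffs_left <- as.numeric(puffs_left)
  puffs_right <- as.numeric(puffs_right)
  if (is.null(correct_side)) {
    nl <- sum(puffs_left < cue_duration)
    nr <- sum(puffs_right < cue_duration)
    correct_side <- if (nr > nl) "right" else if (nl > nr) "left" else NA_character_
  }
  structure(
    list(
      puffs_left = puffs_left, puffs_right = puffs_right,
      cue_duration = as.numeric(cue_duration),
      delay_duration = as.numeric(delay_duration),
      light_window = light_window, guided = isTRUE(guided),
      choice = choice, correct_side = correct_side,
      decision_latency = as.numeric(decision_latency),
      subject_id = subject_id, session_id = session_id,
      condition_label = condition_label,
      trial_index = as.integer(trial_index)
    ),
    class = "puff_trial"
  )
}

#' Closed vocabulary of light-delivery condition labels
#'
#' @return Character vector of the recognized condition labels.
#' @export
condition_labels <- function() {
  c("light-off", "full-cue", "first-third", "middle-third", "last-third",
    "delay", "delay-200ms", "delay-500ms", "guided")
}

#' Validate a trial against the task invariants
#'
#' Checks, without throwing, every structural invariant of a trial: puff
#' times within the cue period (guided trials may also carry delay-period
#' guide puffs), per-side times strictly increasing with gaps of at least
#' the minimum inter-puff interval, a well-formed light window inside
#' `[0, cue + delay]`, a defined correct side (ties are disallowed on
#' non-guided trials), and single-sided cue puffs on guided trials.
#'
#' @param x A `puff_trial`.
#' @param min_gap Minimum inter-puff interval (s); the task enforces 200 ms.
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_trial <- function(x, min_gap = 0.2) {
  stopifnot(inherits(x, "puff_trial"))
  v <- character()
  cue <- x$cue_duration
  total <- cue + x$delay_duration
  if (!is.finite(cue) || cue <= 0) {
    v <- c(v, "cue_duration must be positive and finite")
    return(v)
  }
  lim <- if (x$guided) total else cue
  for (side in c("left", "right")) {
    p <- x[[paste0("puffs_", side)]]
    if (length(p) == 0) next
    if (any(!is.finite(p))) {
      v <- c(v, sprintf("%s puff times contain non-finite values", side))
      next
    }
    if (any(p < 0) || any(p >= lim))
      v <- c(v, sprintf("%s puff times outside [0, %.3f)", side, lim))
    if (length(p) > 1) {
      gaps <- diff(p)
      if (any(gaps <= 0))
        v <- c(v, sprintf("%s puff times not strictly increasing", side))
      else if (any(gaps < min_gap - 1e-9))
        v <- c(v, sprintf("%s puffs violate minimum %.0f-ms inter-puff interval",
                          side, 1000 * min_gap))
    }
  }
  nl <- sum(x$puffs_left < cue)
  nr <- sum(x$puffs_right < cue)
  if (!x$guided && nl == nr)
    v <- c(v, "tie (#R = #L) on non-guided trial: correct side undefined")
  if (x$guided && nl > 0 && nr > 0)
    v <- c(v, "guided trial has cue-period puffs on both sides")
  if (!is.null(x$light_window)) {
    lw <- x$light_window
    if (!all(c("start", "end", "side") %in% names(lw))) {
      v <- c(v, "light window must have start, end, side")
    } else {
      if (!(lw$start >= 0 && lw$start < lw$end && lw$end <= total + 1e-9))
        v <- c(v, sprintf("light window [%.3f, %.3f] not within 0 <= start < end <= %.3f",
                          lw$start, lw$end, total))
      if (!lw$side %in% c("left", "right", "bilateral"))
        v <- c(v, "light window side must be left, right, or bilateral")
    }
  }
  if (!x$choice %in% c("left", "right", "none"))
    v <- c(v, "choice must be left, right, or none")
  if (!x$guided && !identical(x$correct_side, "left") &&
      !identical(x$correct_side, "right"))
    v <- c(v, "correct_side must be left or right")
  if (!x$condition_label %in% condition_labels())
    v <- c(v, sprintf("unknown condition label '%s'", x$condition_label))
  v
}

#' Construct an ordered collection of trials
#'
#' @param trials List of `puff_trial` objects.
#' @param subject_id,session_id Optional set-level labels (per-trial labels
#'   are kept on each trial; these default to the unique per-trial value
#'   when consistent).
#' @param validate Logical; if `TRUE` (default) every trial is validated and
#'   an error listing all violations is thrown if any fail.
#' @param min_gap Minimum inter-puff interval (s) used in validation.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, subject_id = NULL, session_id = NULL,
                      validate = TRUE, min_gap = 0.2) {
  stopifnot(is.list(trials))
  if (length(trials) > 0)
    stopifnot(all(vapply(trials, inherits, logical(1), "puff_trial")))
  if (validate && length(trials) > 0) {
    bad <- lapply(seq_along(trials), function(i) {
      vi <- validate_trial(trials[[i]], min_gap = min_gap)
      if (length(vi)) sprintf("trial %d: %s", i, vi) else character()
    })
    bad <- unlist(bad)
    if (length(bad))
      stop("trial validation failed:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
  }
  one_of <- function(field, fallback) {
    u <- unique(vapply(trials, `[[`, character(1), field))
    if (length(u) == 1) u else fallback
  }
  if (is.null(subject_id))
    subject_id <- if (length(trials)) one_of("subject_id", "mixed") else "empty"
  if (is.null(session_id))
    session_id <- if (length(trials)) one_of("session_id", "mixed") else "empty"
  structure(list(trials = trials, subject_id = subject_id,
                 session_id = session_id),
            class = "trial_set")
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' @export
print.trial_set <- function(x, ...) {
  n <- length(x$trials)
  cond <- table(vapply(x$trials, `[[`, character(1), "condition_label"))
  cat(sprintf("<trial_set> %d trials (subject %s, session %s)\n",
              n, x$subject_id, x$session_id))
  if (n) print(cond)
  invisible(x)
}

#' @export
print.puff_trial <- function(x, ...) {
  cat(sprintf(
    "<puff_trial> cue %.1fs + delay %.1fs | #L=%d #R=%d | %s | choice=%s correct=%s\n",
    x$cue_duration, x$delay_duration,
    length(x$puffs_left), length(x$puffs_right),
    x$condition_label, x$choice, x$correct_side))
  invisible(x)
}

#' Subset a trial set by analysis filters
#'
#' Standard inclusion rules used throughout: keep only trials with a
#' decision lick, optionally only the primary 3.8-s cue period, optionally
#' by condition label, optionally dropping guided trials.
#'
#' @param ts A `trial_set`.
#' @param condition Optional character vector of condition labels to keep.
#' @param cue_duration Optional cue duration to keep (with tolerance 1e-6).
#' @param decided If `TRUE`, keep only trials where a choice was made.
#' @param guided If `FALSE` (default `NA` = keep all), drop guided trials;
#'   if `TRUE`, keep only guided trials.
#' @return A `trial_set` (possibly empty; not revalidated).
#' @export
filter_trials <- function(ts, condition = NULL, cue_duration = NULL,
                          decided = TRUE, guided = NA) {
  stopifnot(inherits(ts, "trial_set"))
  keep <- rep(TRUE, length(ts$trials))
  for (i in seq_along(ts$trials)) {
    tr <- ts$trials[[i]]
    if (decided && tr$choice == "none") keep[i] <- FALSE
    if (!is.null(condition) && !tr$condition_label %in% condition) keep[i] <- FALSE
    if (!is.null(cue_duration) &&
        abs(tr$cue_duration - cue_duration) > 1e-6) keep[i] <- FALSE
    if (!is.na(guided) && tr$guided != guided) keep[i] <- FALSE
  }
  trial_set(ts$trials[keep], subject_id = ts$subject_id,
            session_id = ts$session_id, validate = FALSE)
}

#' Per-trial puff counts and evidence
#'
#' Counts cue-period puffs per side and the signed evidence #R - #L.
#'
#' @param x A `puff_trial` or `trial_set`.
#' @return For a trial, a named numeric vector `c(n_left, n_right, delta)`;
#'   for a trial set, a data.frame with one row per trial plus `choice`,
#'   `correct_side`, `condition_label`, `guided`.
#' @export
puff_counts <- function(x) {
  if (inherits(x, "puff_trial")) {
    nl <- sum(x$puffs_left < x$cue_duration)
    nr <- sum(x$puffs_right < x$cue_duration)
    return(c(n_left = nl, n_right = nr, delta = nr - nl))
  }
  stopifnot(inherits(x, "trial_set"))
  rows <- lapply(x$trials, function(tr) {
    pc <- puff_counts(tr)
    data.frame(n_left = pc[["n_left"]], n_right = pc[["n_right"]],
               delta = pc[["delta"]], choice = tr$choice,
               correct_side = tr$correct_side,
               condition_label = tr$condition_label, guided = tr$guided,
               cue_duration = tr$cue_duration,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bin a trial's evidence into temporally uniform bins of the cue period
#'
#' Partitions `[0, cue_duration)` into `n_bins` half-open bins
#' `[t_i, t_{i+1})` (a puff exactly at an interior edge belongs to the later
#' bin) and counts #R - #L puffs per bin. Edges are `i * cue/n_bins` in full
#' precision; for the standard 3.8-s cue with 3 bins these are the
#' 0-1.27 s, 1.27-2.53 s, 2.53-3.8 s windows used by the choice regression.
#'
#' @param x A `puff_trial`.
#' @param n_bins Number of bins (default 3).
#' @return An object of class `evidence_bins`: list with `counts`
#'   (#R - #L per bin) and `edges` (length `n_bins + 1`).
#' @export
bin_evidence <- function(x, n_bins = 3) {
  stopifnot(inherits(x, "puff_trial"))
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 1 ||
      n_bins != round(n_bins))
    stop("n_bins must be a positive integer", call. = FALSE)
  cue <- x$cue_duration
  if (!(cue > 0)) stop("cue_duration must be positive", call. = FALSE)
  edges <- seq(0, cue, length.out = n_bins + 1)
  idx <- function(p) {
    p <- p[p >= 0 & p < cue]
    # half-open bins: floor(p / width), clamped for numerical safety
    pmin(floor(p * n_bins / cue), n_bins - 1) + 1
  }
  counts <- tabulate(idx(x$puffs_right), nbins = n_bins) -
    tabulate(idx(x$puffs_left), nbins = n_bins)
  structure(list(counts = counts, edges = edges), class = "evidence_bins")
}

#' Evidence-bin design matrix for a trial set
#'
#' @param ts A `trial_set`.
#' @param n_bins Number of bins.
#' @return Numeric matrix, one row per trial, columns `E1..En`.
#' @export
evidence_matrix <- function(ts, n_bins = 3) {
  stopifnot(inherits(ts, "trial_set"))
  E <- vapply(ts$trials, function(tr) bin_evidence(tr, n_bins)$counts,
              numeric(n_bins))
  E <- if (n_bins == 1) matrix(E, ncol = 1) else t(E)
  colnames(E) <- paste0("E", seq_len(n_bins))
  E
}
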