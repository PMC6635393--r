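#' Read trials from the tabular trial schema
#'
#' The CSV schema has one row per trial with columns: `subject_id`,
#' `session_id`, `trial_index`, `condition_label`, `cue_duration_s`,
#' `delay_duration_s`, `puffs_left_s`, `puffs_right_s` (semicolon-delimited
#' decimal event times), `light_start_s`, `light_end_s` (empty when light
#' off), `light_side` in `{L,R,B,none}`, `guided` in `{0,1}`, `choice` in
#' `{L,R,none}`, `correct_side` in `{L,R}`, `decision_latency_s` (optional).
#' The JSON format is an array of objects with the same field names. UTF-8,
#' `"."` decimal separator.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @param validate Validate all trials after parsing (default `TRUE`).
#' @return A [trial_set()].
#' @export
read_trials <- function(path, format = c("auto", "csv", "json"),
                        validate = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = character())
  } else {
    as.data.frame(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  stringsAsFactors = FALSE)
  }
  required <- c("subject_id", "session_id", "trial_index", "condition_label",
                "cue_duration_s", "delay_duration_s", "puffs_left_s",
                "puffs_right_s", "light_start_s", "light_end_s", "light_side",
                "guided", "choice", "correct_side")
  if (nrow(df) == 0 && ncol(df) == 0) return(trial_set(list()))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n <- nrow(df)
  num_field <- function(value, row, col, allow_empty = FALSE) {
    s <- as.character(value)
    if (allow_empty && (is.na(s) || !nzchar(s))) return(NA_real_)
    out <- suppressWarnings(as.numeric(s))
    if (is.na(out))
      stop(sprintf("parse error at row %d, column %s: '%s'", row, col, s),
           call. = FALSE)
    out
  }
  parse_times <- function(s, row, col) {
    s <- as.character(s)
    if (is.na(s) || !nzchar(trimws(s))) return(numeric())
    parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
    out <- suppressWarnings(as.numeric(parts))
    if (any(is.na(out)))
      stop(sprintf("parse error at row %d, column %s: '%s'", row, col, s),
           call. = FALSE)
    out
  }
  side_of <- function(code) switch(code, L = "left", R = "right",
                                   B = "bilateral", none = NA_character_,
                                   NA_character_)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    ls_ <- num_field(df$light_start_s[i], i, "light_start_s", allow_empty = TRUE)
    le_ <- num_field(df$light_end_s[i], i, "light_end_s", allow_empty = TRUE)
    lw <- NULL
    if (!is.na(ls_) || !is.na(le_)) {
      if (is.na(ls_) || is.na(le_))
        stop(sprintf("row %d: light_start_s/light_end_s must both be set or both empty", i),
             call. = FALSE)
      sd <- side_of(as.character(df$light_side[i]))
      if (is.na(sd))
        stop(sprintf("parse error at row %d, column light_side: '%s'",
                     i, df$light_side[i]), call. = FALSE)
      lw <- list(start = ls_, end = le_, side = sd)
    }
    ch <- as.character(df$choice[i])
    ch <- switch(ch, L = "left", R = "right", none = "none",
                 stop(sprintf("parse error at row %d, column choice: '%s'", i, ch),
                      call. = FALSE))
    cs <- as.character(df$correct_side[i])
    cs <- if (is.na(cs) || !nzchar(cs)) NA_character_ else
      switch(cs, L = "left", R = "right",
             stop(sprintf("parse error at row %d, column correct_side: '%s'",
                          i, cs), call. = FALSE))
    lat <- if ("decision_latency_s" %in% names(df))
      num_field(df$decision_latency_s[i], i, "decision_latency_s",
                allow_empty = TRUE) else NA_real_
    trials[[i]] <- trial(
      puffs_left = parse_times(df$puffs_left_s[i], i, "puffs_left_s"),
      puffs_right = parse_times(df$puffs_right_s[i], i, "puffs_right_s"),
      cue_duration = num_field(df$cue_duration_s[i], i, "cue_duration_s"),
      delay_duration = num_field(df$delay_duration_s[i], i, "delay_duration_s"),
      light_window = lw,
      guided = as.integer(df$guided[i]) == 1L,
      choice = ch, correct_side = cs,
      decision_latency = lat,
      subject_id = as.character(df$subject_id[i]),
      session_id = as.character(df$session_id[i]),
      condition_label = as.character(df$condition_label[i]),
      trial_index = as.integer(df$trial_index[i])
    )
  }
  trial_set(trials, validate = validate)
}

#' Write trials to the tabular trial schema
#'
#' Event times are serialized with 17 significant digits so that a
#' write/read round trip reproduces the trial set bit-exactly (well beyond
#' the 6-decimal-digit schema guarantee).
#'
#' @param ts A [trial_set()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ts, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(ts, "trial_set"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  fmt_times <- function(p) paste(sprintf("%.17g", p),
                                 collapse = ";")
  code_of <- function(side) switch(side, left = "L", right = "R",
                                   bilateral = "B", "none")
  rows <- lapply(seq_along(ts$trials), function(i) {
    tr <- ts$trials[[i]]
    lw <- tr$light_window
    data.frame(
      subject_id = tr$subject_id, session_id = tr$session_id,
      trial_index = if (is.na(tr$trial_index)) i else tr$trial_index,
      condition_label = tr$condition_label,
      cue_duration_s = tr$cue_duration, delay_duration_s = tr$delay_duration,
      puffs_left_s = fmt_times(tr$puffs_left),
      puffs_right_s = fmt_times(tr$puffs_right),
      light_start_s = if (is.null(lw)) "" else sprintf("%.17g", lw$start),
      light_end_s = if (is.null(lw)) "" else sprintf("%.17g", lw$end),
      light_side = if (is.null(lw)) "none" else code_of(lw$side),
      guided = as.integer(tr$guided),
      choice = switch(tr$choice, left = "L", right = "R", "none"),
      correct_side = if (is.na(tr$correct_side)) "" else
        switch(tr$correct_side, left = "L", right = "R"),
      decision_latency_s = if (is.na(tr$decision_latency)) "" else
        sprintf("%.17g", tr$decision_latency),
      stringsAsFactors = FALSE
    )
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 15)),
                    c("subject_id", "session_id", "trial_index",
                      "condition_label", "cue_duration_s", "delay_duration_s",
                      "puffs_left_s", "puffs_right_s", "light_start_s",
                      "light_end_s", "light_side", "guided", "choice",
                      "correct_side", "decision_latency_s"))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  if (format == "csv") {
    utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  } else {
    writeLines(jsonlite::toJSON(df, dataframe = "rows", digits = NA,
                                pretty = TRUE), con)
  }
  invisible(path)
}
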