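# Reading, writing and validating the trial-log CSV.
#
# Schema (one row per stimulus presentation):
#   participant_id, condition, probe_type, block, trial_index, item_id,
#   stimulus_type, category, rt_ms, responded, correct
# rt_ms is empty when no response was made within the 1500 ms window; such
# trials carry responded = FALSE and correct = FALSE.

trial_columns <- function() {
  c("participant_id", "condition", "probe_type", "block", "trial_index",
    "item_id", "stimulus_type", "category", "rt_ms", "responded", "correct")
}

#' Validate a trial table
#'
#' Checks the trial-log schema: required columns, enumerated values
#' (`condition`, `probe_type`, `stimulus_type`, `category`), RTs inside the
#' (0, 1500] response window, and the miss encoding (RT absent exactly when
#' `responded` is `FALSE`, and missed trials never `correct`). Errors name the
#' first offending row and column.
#'
#' @param trials Data frame to check.
#' @return The input, invisibly, if valid.
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(trial_columns(), names(trials))
  if (length(missing_cols)) {
    abort_parse(sprintf("missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  enums <- list(
    condition = cit_conditions(),
    probe_type = c("names", "cities"),
    stimulus_type = cit_stimulus_types(),
    category = c("name", "city")
  )
  for (col in names(enums)) {
    bad <- which(!trials[[col]] %in% enums[[col]])
    if (length(bad)) {
      abort_parse(sprintf("row %d, column '%s': invalid value '%s'",
                          bad[1], col, trials[[col]][bad[1]]))
    }
  }
  if (!is.numeric(trials$rt_ms)) abort_parse("column 'rt_ms' must be numeric")
  for (col in c("responded", "correct")) {
    if (!is.logical(trials[[col]]) || anyNA(trials[[col]])) {
      abort_parse(sprintf("column '%s' must be TRUE/FALSE", col))
    }
  }
  rt <- trials$rt_ms
  bad <- which(!is.na(rt) & (rt <= 0 | rt > 1500))
  if (length(bad)) {
    abort_parse(sprintf(
      "row %d, column 'rt_ms': %s outside the (0, 1500] ms response window",
      bad[1], format(rt[bad[1]])))
  }
  bad <- which(is.na(rt) != !trials$responded)
  if (length(bad)) {
    abort_parse(sprintf(
      "row %d, column 'rt_ms': RT must be present exactly when responded",
      bad[1]))
  }
  bad <- which(!trials$responded & trials$correct)
  if (length(bad)) {
    abort_parse(sprintf(
      "row %d, column 'correct': a missed trial cannot be correct", bad[1]))
  }
  invisible(trials)
}

#' Write / read a trial-log CSV
#'
#' `write_trials()` serialises a trial table; `read_trials()` parses and
#' validates one. The pair round-trips exactly (RTs are recorded to 0.1 ms):
#' `read_trials(write_trials(x, p))` is identical to `x`. An empty `rt_ms`
#' field encodes a miss.
#'
#' @param trials Trial table in the schema of [validate_trials()].
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   the validated trial table.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  keep <- c(trial_columns(), intersect("isi_ms", names(trials)))
  utils::write.csv(trials[keep], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("no such trial log: %s", path))
  classes <- c(participant_id = "character", condition = "character",
               probe_type = "character", block = "integer",
               trial_index = "integer", item_id = "character",
               stimulus_type = "character", category = "character",
               rt_ms = "numeric", responded = "logical", correct = "logical")
  trials <- tryCatch(
    utils::read.csv(path, colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) abort_parse(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e))))
  missing_cols <- setdiff(names(classes), names(trials))
  if (length(missing_cols)) {
    abort_parse(sprintf("missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  for (col in names(classes)) {
    v <- trials[[col]]
    if (col == "rt_ms") {
      v[!is.na(v) & v == ""] <- NA
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "")
      if (length(bad)) {
        abort_parse(sprintf("row %d, column 'rt_ms': not a number: '%s'",
                            bad[1], v[bad[1]]))
      }
      trials[[col]] <- vn
    } else if (classes[col] == "integer") {
      vn <- suppressWarnings(as.integer(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        abort_parse(sprintf("row %d, column '%s': not an integer: '%s'",
                            bad[1], col, v[bad[1]]))
      }
      trials[[col]] <- vn
    } else if (classes[col] == "logical") {
      vl <- as.logical(v)
      bad <- which(is.na(vl))
      if (length(bad)) {
        abort_parse(sprintf("row %d, column '%s': not TRUE/FALSE: '%s'",
                            bad[1], col, v[bad[1]]))
      }
      trials[[col]] <- vl
    } else {
      trials[[col]] <- as.character(v)
    }
  }
  validate_trials(trials)
  trials
}
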