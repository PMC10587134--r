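# Preregistered trial- and participant-level exclusions and per-participant
# scoring.
#
# Trial filters (applied before averaging): wrong-button presses, presses
# faster than 150 ms, presses slower than 800 ms, and misses are removed.
# Participant exclusions (applied to the unfiltered trials): >= 50% wrong
# responses to any stimulus type, incomplete sessions, and participants who
# performed the task more than once.
#
# Scores: the RT-CIT effect is the mean filtered probe RT minus the mean
# filtered irrelevant RT; dCIT standardises it by the within-participant
# sample SD of filtered irrelevant RTs.

#' Apply the preregistered trial filters
#'
#' Keeps only correct button presses with 150 ms <= RT <= 800 ms: wrong
#' presses, presses under 150 ms, presses above 800 ms, and misses are
#' dropped. Boundary values (exactly 150 or 800 ms) are retained, reading
#' "under"/"above" strictly. Row order is preserved and the input is not
#' modified; filtering is idempotent.
#'
#' @param trials Trial table (see [validate_trials()] for the schema).
#' @return The retained rows, possibly zero of them.
#' @export
#' @examples
#' t <- generate_cohort(cit_config(n_per_condition = 1, seed = 1))$trials
#' nrow(filter_trials(t))
filter_trials <- function(trials) {
  keep <- trials$responded & trials$correct &
    !is.na(trials$rt_ms) & trials$rt_ms >= 150 & trials$rt_ms <= 800
  trials[keep, , drop = FALSE]
}

#' Participant-level quality control
#'
#' Applies the preregistered participant exclusions on the *unfiltered*
#' trials, in order of precedence: `duplicate` (a participant id holding more
#' than `expected_n` presented trials, i.e. more than one session — all its
#' sessions are removed), `incomplete` (fewer than `expected_n` presented
#' trials), and `high_error` (wrong-button rate >= 0.5 for at least one of the
#' three stimulus types, computed over all presented trials of that type).
#' Misses count in the denominator; whether they also count as errors is
#' controlled by `misses_as_errors` (default: they do not).
#'
#' @param trials Trial table covering one or more participants.
#' @param expected_n Presented trials per complete session (protocol: 288).
#' @param misses_as_errors If `TRUE`, trials without a response count as
#'   errors in the 50% criterion.
#' @return One row per participant: presented-trial count, per-type error
#'   rates, `excluded`, and `exclusion_reason` in
#'   `c("none", "high_error", "incomplete", "duplicate")`.
#' @export
participant_qc <- function(trials, expected_n = 288L,
                           misses_as_errors = FALSE) {
  ids <- unique(trials$participant_id)
  f <- factor(trials$participant_id, levels = ids)
  st <- factor(trials$stimulus_type, levels = cit_stimulus_types())
  n_tab <- table(f, st)
  if (any(n_tab == 0)) {
    miss <- which(n_tab == 0, arr.ind = TRUE)[1, ]
    abort_data(sprintf(
      "participant %s: no presented trials of stimulus type '%s'",
      ids[miss[1]], cit_stimulus_types()[miss[2]]))
  }
  wrong <- if (misses_as_errors) !trials$correct
    else trials$responded & !trials$correct
  w_tab <- tapply(wrong, list(f, st), sum)
  rates <- w_tab / unclass(n_tab)
  n <- as.integer(rowSums(n_tab))
  reason <- ifelse(n > expected_n, "duplicate",
            ifelse(n < expected_n, "incomplete",
            ifelse(apply(rates, 1, max) >= 0.5, "high_error", "none")))
  data.frame(participant_id = ids,
             condition = trials$condition[match(ids, trials$participant_id)],
             n_presented = n,
             error_rate_probe = rates[, "probe"],
             error_rate_irrelevant = rates[, "irrelevant"],
             error_rate_target = rates[, "target"],
             excluded = reason != "none", exclusion_reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarise one participant's filtered trials
#'
#' Computes per-stimulus-type means and valid-trial counts, the
#' within-participant sample SD (n - 1 denominator) of irrelevant RTs pooled
#' across categories and blocks, the RT-CIT effect (mean probe RT minus mean
#' irrelevant RT, ms), and dCIT (the effect divided by `sd_irrelevant`,
#' dimensionless). Requires at least one filtered probe trial, at least two
#' filtered irrelevant trials, and a non-zero irrelevant SD.
#'
#' @param trials *Filtered* trials (see [filter_trials()]) of one participant.
#' @param probe_type Stratum label recorded in the output (`"names+cities"`
#'   for the pooled summary, `"names"` or `"cities"` for a single-category
#'   one); trials are not re-subset by it.
#' @return One-row data frame (a participant summary).
#' @export
#' @examples
#' tr <- data.frame(
#'   participant_id = "p1", condition = "conflict",
#'   stimulus_type = rep(c("probe", "irrelevant"), c(2, 4)),
#'   rt_ms = c(500, 520, 460, 480, 470, 490))
#' summarize_participant(tr)$rt_cit_effect  # 35 ms
summarize_participant <- function(trials, probe_type = "names+cities") {
  pid <- trials$participant_id[1]
  rt <- split(trials$rt_ms, factor(trials$stimulus_type,
                                   levels = cit_stimulus_types()))
  n_probe <- length(rt$probe); n_irr <- length(rt$irrelevant)
  if (n_probe < 1) {
    abort_data(sprintf("participant %s: no filtered probe trials", pid))
  }
  if (n_irr < 2) {
    abort_data(sprintf(
      "participant %s: fewer than 2 filtered irrelevant trials", pid))
  }
  sd_irr <- stats::sd(rt$irrelevant)
  if (sd_irr == 0) {
    abort_data(sprintf(
      "participant %s: zero variance among irrelevant RTs, dCIT undefined",
      pid))
  }
  effect <- mean(rt$probe) - mean(rt$irrelevant)
  data.frame(
    participant_id = pid,
    condition = if ("condition" %in% names(trials)) trials$condition[1] else NA,
    probe_type = probe_type,
    mean_rt_probe = mean(rt$probe),
    mean_rt_irrelevant = mean(rt$irrelevant),
    mean_rt_target = if (length(rt$target)) mean(rt$target) else NA_real_,
    n_valid_probe = n_probe,
    n_valid_irrelevant = n_irr,
    n_valid_target = length(rt$target),
    sd_irrelevant = sd_irr,
    rt_cit_effect = effect,
    dcit = effect / sd_irr,
    stringsAsFactors = FALSE
  )
}

#' Cohort-level preprocessing
#'
#' Runs [participant_qc()], drops excluded participants, applies
#' [filter_trials()], and summarises every retained participant with
#' [summarize_participant()] — pooled across categories and, optionally, for
#' the names and cities strata separately.
#'
#' @inheritParams participant_qc
#' @param by_probe_type If `TRUE`, per-stratum (`names`, `cities`) summaries
#'   are appended to the pooled (`names+cities`) ones.
#' @return A list: `summaries` (one row per retained participant x stratum)
#'   and `qc` (the [participant_qc()] table, the exclusion audit).
#' @export
cit_summaries <- function(trials, expected_n = 288L, by_probe_type = TRUE,
                          misses_as_errors = FALSE) {
  validate_trials(trials)
  qc <- participant_qc(trials, expected_n = expected_n,
                       misses_as_errors = misses_as_errors)
  keep_ids <- qc$participant_id[!qc$excluded]
  filtered <- filter_trials(trials[trials$participant_id %in% keep_ids, ,
                                   drop = FALSE])
  strata <- list("names+cities" = c("names", "cities"))
  if (by_probe_type) strata <- c(strata, list(names = "names",
                                              cities = "cities"))
  idx <- split(seq_len(nrow(filtered)),
               factor(filtered$participant_id, levels = keep_ids))
  rows <- list()
  for (pid in keep_ids) {
    fp <- filtered[idx[[pid]], , drop = FALSE]
    for (lab in names(strata)) {
      sub <- fp[fp$probe_type %in% strata[[lab]], , drop = FALSE]
      rows[[length(rows) + 1L]] <- summarize_participant(sub, probe_type = lab)
    }
  }
  list(summaries = do.call(rbind, rows), qc = qc)
}

#' Probe-minus-irrelevant significance difference score
#'
#' Post-test ratings of item significance (integers 1-9) are scored per
#' participant as the mean probe rating minus the mean irrelevant rating.
#'
#' @param ratings Data frame with columns `participant_id`, `role`
#'   (`"probe"` or `"irrelevant"`), and `rating` (integer 1-9).
#' @return Data frame with one `score` per participant.
#' @export
significance_difference_score <- function(ratings) {
  need <- c("participant_id", "role", "rating")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) {
    abort_data(sprintf("ratings table lacks column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  if (any(!ratings$role %in% c("probe", "irrelevant"))) {
    abort_data("ratings role must be 'probe' or 'irrelevant'")
  }
  r <- ratings$rating
  if (any(!is.finite(r)) || any(r != round(r)) || any(r < 1 | r > 9)) {
    abort_data("ratings must be integers in [1, 9]")
  }
  ids <- unique(ratings$participant_id)
  score <- vapply(ids, function(pid) {
    rp <- ratings[ratings$participant_id == pid, , drop = FALSE]
    m <- tapply(rp$rating, factor(rp$role, c("probe", "irrelevant")), mean)
    if (anyNA(m)) {
      abort_data(sprintf(
        "participant %s: needs at least one probe and one irrelevant rating",
        pid))
    }
    m[["probe"]] - m[["irrelevant"]]
  }, numeric(1))
  data.frame(participant_id = ids, score = unname(score),
             stringsAsFactors = FALSE)
}

#' Recruitment bookkeeping: analysed sample size
#'
#' Given a per-batch recruitment record with the number recruited and the
#' counts removed by each exclusion category, returns the per-batch retained
#' counts and the final analysed sample size.
#'
#' @param batches Data frame with column `n_recruited` plus any number of
#'   exclusion-count columns (e.g. `not_approved`, `incomplete`, `duplicate`,
#'   `high_error`).
#' @return A list: `per_batch` (retained count per batch) and `n_analyzed`.
#' @export
#' @examples
#' rec <- data.frame(n_recruited = c(147, 160, 172),
#'                   not_approved = c(13, 0, 0),
#'                   incomplete = c(21, 57, 57),
#'                   duplicate = c(0, 11, 10),
#'                   high_error = c(8, 3, 7))
#' analyzed_n(rec)$n_analyzed  # 292
analyzed_n <- function(batches) {
  if (!"n_recruited" %in% names(batches)) {
    abort_data("batches must have a column 'n_recruited'")
  }
  excl <- batches[setdiff(names(batches), "n_recruited")]
  excl <- excl[vapply(excl, is.numeric, logical(1))]
  per_batch <- batches$n_recruited -
    (if (ncol(excl)) rowSums(excl) else 0)
  if (any(per_batch < 0)) abort_data("exclusions exceed recruitment in a batch")
  list(per_batch = per_batch, n_analyzed = sum(per_batch))
}
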