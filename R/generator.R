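# Synthetic trial-level RT-CIT cohort generator.
#
# The simulated task follows the multiple probes protocol (MPP): two semantic
# categories (names and cities) are intermixed within every block; each
# category contributes 1 probe, 1 target and 4 irrelevant items, so a block
# presents 12 distinct items 6 times each (72 trials), and a session has 4
# blocks (288 trials). Two consecutive presentations of the same item never
# occur, including across block boundaries. Responses are collected within a
# 1500 ms window.

#' Condition labels used throughout the package
#'
#' The between-subjects response-conflict factor: in the `conflict` condition
#' the response buttons emphasise familiarity of the items; in the
#' `no_conflict` condition they emphasise categorical membership.
#'
#' @return Character vector of the two condition labels.
#' @export
cit_conditions <- function() c("conflict", "no_conflict")

#' Stimulus-type labels
#' @return Character vector `c("probe", "irrelevant", "target")`.
#' @export
cit_stimulus_types <- function() c("probe", "irrelevant", "target")

# Fixed item roster of one MPP session: per category one probe, one target,
# four irrelevants.
item_roster <- function() {
  cat <- rep(c("name", "city"), each = 6L)
  stim <- rep(c("probe", "target", paste0("irrelevant")), times = c(1L, 1L, 4L))
  stim <- rep(stim, 2L)
  idx <- unlist(lapply(c("name", "city"), function(cg) c("", "", 1:4)),
                use.names = FALSE)
  data.frame(
    item_id = paste0(cat, "_", sub("irrelevant", "irr", stim), idx),
    category = cat,
    probe_type = ifelse(cat == "name", "names", "cities"),
    stimulus_type = stim,
    stringsAsFactors = FALSE
  )
}

#' Configure the synthetic cohort generator
#'
#' Defaults are calibrated to a large two-condition online validation study of
#' the response-conflict account of the RT-CIT effect (final n = 292): the
#' per-condition probe-minus-irrelevant slowing and participant-level
#' irrelevant-RT baselines match that study's summary table. Fields that may
#' differ between conditions accept either a scalar (applied to both) or a
#' vector named `conflict` / `no_conflict`.
#'
#' @param n_per_condition Participants per condition (scalar or named vector).
#' @param probe_effect_mean_ms Population mean of the true per-participant
#'   probe-minus-irrelevant slowing, in ms.
#' @param probe_effect_sd_ms Between-participant SD of the true slowing (ms).
#'   Note this parameterises the *true* effects; observed per-participant
#'   effects additionally carry trial-sampling noise.
#' @param baseline_mean_ms,baseline_sd_ms Population distribution of the
#'   participant-level mean irrelevant RT (ms).
#' @param trial_sd_ms Within-participant trial-to-trial RT SD (ms).
#' @param target_shift_ms Added latency of target items (ms); targets require
#'   the alternative button and are slower in practice.
#' @param error_rate_by_type Named probabilities (`probe`, `irrelevant`,
#'   `target`) of pressing the wrong button on a responded trial.
#' @param miss_rate Probability of no button press within the 1500 ms window.
#' @param knowledgeable If `FALSE`, participants are simulated as naive: their
#'   true probe effect is forced to 0 so probe and irrelevant RTs share one
#'   distribution.
#' @param n_contaminated Number of participants (taken from the start of the
#'   roster, conflict condition first) engineered to fail the 50%-error
#'   exclusion: they always respond to probes and always press the wrong
#'   button on them.
#' @param record_isi If `TRUE`, an `isi_ms` column (250/500/750 ms, uniform)
#'   is added for protocol fidelity; the analysis ignores it.
#' @param seed Integer RNG seed consumed by [generate_cohort()].
#' @return A validated list of class `cit_config`.
#' @export
#' @examples
#' cfg <- cit_config(n_per_condition = 4, seed = 7)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$trials)  # 8 participants x 288 trials
cit_config <- function(n_per_condition = c(conflict = 131L, no_conflict = 161L),
                       probe_effect_mean_ms = c(conflict = 35.84, no_conflict = 23.40),
                       probe_effect_sd_ms = c(conflict = 34.14, no_conflict = 32.04),
                       baseline_mean_ms = c(conflict = 472.88, no_conflict = 487.85),
                       baseline_sd_ms = c(conflict = 43.96, no_conflict = 55.28),
                       trial_sd_ms = 100,
                       target_shift_ms = 60,
                       error_rate_by_type = c(probe = 0.05, irrelevant = 0.04,
                                              target = 0.15),
                       miss_rate = 0.02,
                       knowledgeable = TRUE,
                       n_contaminated = 0L,
                       record_isi = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_per_condition = n_per_condition,
    probe_effect_mean_ms = probe_effect_mean_ms,
    probe_effect_sd_ms = probe_effect_sd_ms,
    baseline_mean_ms = baseline_mean_ms,
    baseline_sd_ms = baseline_sd_ms,
    trial_sd_ms = trial_sd_ms,
    target_shift_ms = target_shift_ms,
    error_rate_by_type = error_rate_by_type,
    miss_rate = miss_rate,
    knowledgeable = isTRUE(knowledgeable),
    n_contaminated = as.integer(n_contaminated),
    record_isi = isTRUE(record_isi),
    seed = as.integer(seed)
  )
  class(cfg) <- "cit_config"
  validate_cit_config(cfg)
  cfg
}

validate_cit_config <- function(cfg) {
  for (cond in cit_conditions()) {
    n <- cond_param(cfg$n_per_condition, cond, "n_per_condition")
    if (!is.finite(n) || n < 1) {
      abort_config("n_per_condition must be >= 1 for every condition")
    }
    for (f in c("probe_effect_sd_ms", "baseline_sd_ms")) {
      if (cond_param(cfg[[f]], cond, f) < 0) {
        abort_config(sprintf("%s must be non-negative", f))
      }
    }
    if (cond_param(cfg$baseline_mean_ms, cond, "baseline_mean_ms") <= 0) {
      abort_config("baseline_mean_ms must be positive")
    }
  }
  if (cfg$trial_sd_ms < 0) abort_config("trial_sd_ms must be non-negative")
  need <- cit_stimulus_types()
  if (!all(need %in% names(cfg$error_rate_by_type))) {
    abort_config("error_rate_by_type must name probe, irrelevant and target")
  }
  probs <- c(cfg$error_rate_by_type[need], miss_rate = cfg$miss_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort_config("all probabilities must lie in [0, 1]")
  }
  if (cfg$n_contaminated < 0) abort_config("n_contaminated must be >= 0")
  total <- sum(vapply(cit_conditions(), function(cond)
    cond_param(cfg$n_per_condition, cond, "n_per_condition"), numeric(1)))
  if (cfg$n_contaminated > total) {
    abort_config("n_contaminated exceeds the number of participants")
  }
  invisible(cfg)
}

# Draw a presentation order of n_items distinct items, each repeated `reps`
# times, with no two consecutive occurrences of the same item; `prev` is the
# item shown immediately before the sequence starts (0 = none), so the
# constraint also holds across block boundaries. Items are drawn one at a
# time, weighted by their remaining repetition counts and excluding the
# previous item; the rare dead end (only the previous item left) restarts the
# draw.
no_repeat_sequence <- function(n_items, reps, prev = 0L) {
  total <- n_items * reps
  repeat {
    counts <- rep.int(reps, n_items)
    out <- integer(total)
    p <- prev
    ok <- TRUE
    for (i in seq_len(total)) {
      cand <- which(counts > 0L)
      cand <- cand[cand != p]
      if (!length(cand)) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else
        cand[sample.int(length(cand), 1L, prob = counts[cand])]
      out[i] <- pick
      counts[pick] <- counts[pick] - 1L
      p <- pick
    }
    if (ok) return(out)
  }
}

#' Simulate one RT-CIT session
#'
#' Generates the 288 trials of a single participant under the MPP structure
#' (4 blocks x 72 trials, per block 12 probe / 48 irrelevant / 12 target
#' presentations, no immediate item repeats). Trial RT is participant baseline
#' + stimulus-type shift + Gaussian trial noise, redrawn until it falls in the
#' response window (0, 1500], and recorded to 0.1 ms. Consumes the current RNG
#' stream; seed management belongs to the caller (see [generate_cohort()]).
#'
#' @param config A [cit_config()] object.
#' @param participant_id Identifier written into every record.
#' @param condition `"conflict"` or `"no_conflict"`.
#' @param knowledgeable Overrides `config$knowledgeable` for this participant;
#'   naive participants get a true probe effect of exactly 0.
#' @param contaminated If `TRUE`, the participant always responds to probes
#'   and always errs on them, guaranteeing a wrong-button rate >= 0.5 for the
#'   probe stimulus type.
#' @return A list with `trials` (data frame of 288 records) and
#'   `true_effect_ms` (the participant's true probe slowing).
#' @export
generate_session <- function(config, participant_id, condition,
                             knowledgeable = config$knowledgeable,
                             contaminated = FALSE) {
  validate_cit_config(config)
  if (!condition %in% cit_conditions()) {
    abort_config(sprintf("unknown condition '%s'", condition))
  }
  roster <- item_roster()
  n_items <- nrow(roster)                      # 12
  reps <- 6L
  n_blocks <- 4L
  per_block <- n_items * reps                  # 72

  baseline <- stats::rnorm(1,
    cond_param(config$baseline_mean_ms, condition, "baseline_mean_ms"),
    cond_param(config$baseline_sd_ms, condition, "baseline_sd_ms"))
  true_effect <- if (knowledgeable) {
    stats::rnorm(1,
      cond_param(config$probe_effect_mean_ms, condition, "probe_effect_mean_ms"),
      cond_param(config$probe_effect_sd_ms, condition, "probe_effect_sd_ms"))
  } else 0

  # Presentation order, block by block, no-repeat across block boundaries.
  prev <- 0L
  order_idx <- integer(0)
  for (b in seq_len(n_blocks)) {
    s <- no_repeat_sequence(n_items, reps, prev)
    order_idx <- c(order_idx, s)
    prev <- s[length(s)]
  }

  stim <- roster$stimulus_type[order_idx]
  shift <- ifelse(stim == "probe", true_effect,
                  ifelse(stim == "target", config$target_shift_ms, 0))
  n <- n_blocks * per_block
  rt <- round(baseline + shift + stats::rnorm(n, 0, config$trial_sd_ms), 1)
  bad <- rt <= 0 | rt > 1500
  while (any(bad)) {
    rt[bad] <- round(baseline + shift[bad] +
                       stats::rnorm(sum(bad), 0, config$trial_sd_ms), 1)
    bad <- rt <= 0 | rt > 1500
  }

  responded <- stats::runif(n) >= config$miss_rate
  err_p <- unname(config$error_rate_by_type[stim])
  correct <- responded & (stats::runif(n) >= err_p)
  if (contaminated) {
    is_probe <- stim == "probe"
    responded[is_probe] <- TRUE
    correct[is_probe] <- FALSE
  }
  rt[!responded] <- NA_real_

  out <- data.frame(
    participant_id = participant_id,
    condition = condition,
    probe_type = roster$probe_type[order_idx],
    block = rep(seq_len(n_blocks), each = per_block),
    trial_index = rep(seq_len(per_block), times = n_blocks),
    item_id = roster$item_id[order_idx],
    stimulus_type = stim,
    category = roster$category[order_idx],
    rt_ms = rt,
    responded = responded,
    correct = correct,
    stringsAsFactors = FALSE
  )
  if (config$record_isi) {
    out$isi_ms <- sample(c(250L, 500L, 750L), n, replace = TRUE)
  }
  list(trials = out, true_effect_ms = true_effect)
}

#' Simulate a full two-condition cohort
#'
#' Runs [generate_session()] for every participant of both conditions under
#' `config$seed`, so identical configurations yield byte-identical tables. The
#' first `n_contaminated` participants of the roster (conflict condition
#' first) are engineered to exceed the 50%-error exclusion criterion.
#'
#' @param config A [cit_config()] object.
#' @return A list with `trials` (one row per presentation, schema of
#'   [write_trials()]) and `truth` (per participant: `participant_id`,
#'   `condition`, `knowledgeable`, `true_effect_ms`, `contaminated`).
#' @export
generate_cohort <- function(config) {
  validate_cit_config(config)
  with_seed(config$seed, {
    trials <- vector("list", 0L)
    truth <- vector("list", 0L)
    slot <- 0L
    for (cond in cit_conditions()) {
      n <- as.integer(cond_param(config$n_per_condition, cond, "n_per_condition"))
      for (i in seq_len(n)) {
        slot <- slot + 1L
        pid <- sprintf("%s_%03d", cond, i)
        contam <- slot <= config$n_contaminated
        ses <- generate_session(config, pid, cond,
                                knowledgeable = config$knowledgeable,
                                contaminated = contam)
        trials[[slot]] <- ses$trials
        truth[[slot]] <- data.frame(
          participant_id = pid, condition = cond,
          knowledgeable = config$knowledgeable,
          true_effect_ms = ses$true_effect_ms,
          contaminated = contam, stringsAsFactors = FALSE)
      }
    }
    list(trials = do.call(rbind, trials), truth = do.call(rbind, truth))
  })
}

#' Practice-phase pass criteria
#'
#' The task's three successive practice phases admit a participant to the next
#' phase when (1) no more than 50% of presses are wrong (all phases), (2) mean
#' RT exceeds 150 ms (phases 2-3), and (3) mean RT is below 800 ms (phase 3).
#' The generator does not simulate practice trials; this predicate exposes the
#' criteria for testing QC logic.
#'
#' @param error_rate Wrong-button proportion in the practice phase.
#' @param mean_rt_ms Mean practice RT in ms.
#' @param phase Practice phase, 1, 2 or 3.
#' @return `TRUE` if the phase is passed.
#' @export
practice_pass <- function(error_rate, mean_rt_ms, phase) {
  if (!phase %in% 1:3) abort_config("phase must be 1, 2 or 3")
  ok <- error_rate <= 0.5
  if (phase >= 2) ok <- ok && mean_rt_ms > 150
  if (phase >= 3) ok <- ok && mean_rt_ms < 800
  ok
}
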