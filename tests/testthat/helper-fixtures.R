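# Shared fixtures: small generator configurations and hand-built trial
# tables used across the test files.

small_config <- function(...) {
  cit_config(n_per_condition = c(conflict = 3L, no_conflict = 3L),
             seed = 11L, ...)
}

# A minimal but schema-complete trial table built by hand. `stimulus_type`,
# `rt_ms`, `responded`, `correct` are recycled against each other.
make_trials <- function(participant_id = "p1", condition = "conflict",
                        stimulus_type = "irrelevant", rt_ms = 400,
                        responded = TRUE, correct = TRUE) {
  n <- max(length(stimulus_type), length(rt_ms), length(responded),
           length(correct))
  st <- rep_len(stimulus_type, n)
  data.frame(
    participant_id = rep_len(participant_id, n),
    condition = rep_len(condition, n),
    probe_type = "names",
    block = 1L,
    trial_index = seq_len(n),
    item_id = paste0("name_", ifelse(st == "irrelevant", "irr1",
                                     sub("irrelevant", "irr", st))),
    stimulus_type = st,
    category = "name",
    rt_ms = rep_len(rt_ms, n),
    responded = rep_len(responded, n),
    correct = rep_len(correct, n),
    stringsAsFactors = FALSE
  )
}

# A complete single-participant session with controlled per-type wrong-button
# counts: `n_each` presented trials per stimulus type, of which `wrong[type]`
# are wrong presses.
make_session_trials <- function(participant_id = "p1", n_each = 96L,
                                wrong = c(probe = 0L, irrelevant = 0L,
                                          target = 0L)) {
  parts <- lapply(cit_stimulus_types(), function(st) {
    w <- wrong[[st]]
    make_trials(participant_id, stimulus_type = rep(st, n_each),
                rt_ms = 400,
                correct = rep(c(FALSE, TRUE), c(w, n_each - w)))
  })
  out <- do.call(rbind, parts)
  out$trial_index <- seq_len(nrow(out))
  out
}
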