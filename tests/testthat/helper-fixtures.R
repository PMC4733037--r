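# Shared fixture builders. Everything is generated in code; no stored data.

# A single hand-built completed compound trial starting at `t0`.
make_trial <- function(t0 = 10, trial_index = 1L, trial_type = "upshift",
                       reward_size = "large", completed = TRUE,
                       compound = TRUE) {
  data.frame(
    trial_index = trial_index, trial_type = trial_type,
    t_light_on = t0, t_port_entry = t0 + 0.8, t_odor_on = t0 + 0.85,
    t_novel_odor_on = if (compound) t0 + 1.05 else NA_real_,
    t_odor_off = t0 + 1.85, t_well_entry = t0 + 2.4, t_reward = t0 + 2.45,
    t_well_exit = t0 + 4.5, reward_size = reward_size,
    completed = completed, stringsAsFactors = FALSE)
}

# Minimal valid session: one trial, one unit with three spikes.
tiny_session <- function() {
  tr <- make_trial()
  u <- unit_recording("u1", "rat1", "s1", "1", c(0.5, 11.0, 12.2))
  session(tr, list(u), metadata = list(session_end = 20))
}

# Trials laid out every `gap` seconds; useful for long homogeneous tests.
regular_trials <- function(n, gap = 10, trial_type = "blocked",
                           reward_size = "medium") {
  do.call(rbind, lapply(seq_len(n), function(i)
    make_trial(t0 = 3 + (i - 1) * gap, trial_index = i,
               trial_type = trial_type, reward_size = reward_size)))
}

# Fake one-unit screen rows for exercising the classification decision order.
fake_screen <- function(sig, unit_id = "u", eligible = TRUE,
                        baseline = 3) {
  odors <- c("initial", "blocked", "upshift", "downshift")
  out <- data.frame(unit_id = unit_id, odor = odors, n_trials = 23L,
                    t = ifelse(sig[odors], 4, 0),
                    p = ifelse(sig[odors], 1e-4, 0.5),
                    direction = "up", significant = unname(sig[odors]),
                    baseline_mean = baseline, eligible = eligible,
                    analyzable = TRUE, stringsAsFactors = FALSE)
  attr(out, "odors") <- odors
  out
}

fake_value <- function(flag, unit_id = "u") {
  data.frame(unit_id = unit_id, p_up_vs_same = NA_real_,
             p_down_vs_same = NA_real_, any_excitatory = TRUE,
             value_coding = flag, stringsAsFactors = FALSE)
}

# Generator config at asymptote (learning complete from trial 1).
asymptotic_config <- function(...) {
  generator_config(learning_midpoint_trial = -50, ...)
}

# Hand-made pseudo-trial object (bypasses sessions) for decoder tests.
make_pt <- function(X, y, bin_starts = NULL, bin_width_s = 0.1) {
  if (is.null(bin_starts))
    bin_starts <- 0.2 + (seq_len(dim(X)[2]) - 1) * bin_width_s
  structure(list(X = X, y = factor(y), bin_starts = bin_starts,
                 bin_width_s = bin_width_s,
                 unit_ids = sprintf("u%d", seq_len(dim(X)[3])),
                 n_per_class = sum(y == y[1]), excluded = character(0)),
            class = "unblk_pseudotrials")
}
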