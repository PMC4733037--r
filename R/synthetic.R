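# Synthetic unblocking sessions: ground-truth-labelled units with
# inhomogeneous-Poisson spiking, logistic learning dynamics, and behavior.

UNIT_CATEGORIES <- c("nonresponsive", "sensory", "value", "upshift_only",
                     "downshift_only", "blocked_only", "predictive",
                     "salience", "initial_only",
                     ## control-variant synonyms for the cue-tuned profiles
                     "large_only", "small_only", "medium_only")

#' Default number of units per ground-truth category
#'
#' The mix qualitatively mirrors the published taxonomy: cue-tuned populations
#' of comparable size, a sizeable salience group, and value-coding cells rare.
#' @return named integer vector.
#' @export
default_unit_mix <- function() {
  c(nonresponsive = 30L, sensory = 12L, value = 5L, upshift_only = 19L,
    downshift_only = 16L, blocked_only = 16L, predictive = 16L,
    salience = 10L, initial_only = 6L)
}

#' Generator configuration
#'
#' Defaults encode the study conditions the analyses assume: 30 trials per
#' novel odor per learning session (task range 20-40), ~2 spikes/s added to the
#' preferred cue(s) at asymptote, baseline rates lognormal with median 3 Hz
#' (mostly < 10 Hz), a logistic learning factor that is near zero on the first
#' day-1 trial and near asymptote through day 2, and probe-day time-in-well
#' ordered upshift > blocked > downshift early in extinction.
#'
#' @param task_variant \code{"blocking"} or \code{"control"}.
#' @param n_units_per_category named integer vector over
#'   \code{\link{default_unit_mix}} names (control variant: tuned categories
#'   are mapped to the corresponding reward-size cues).
#' @param n_trials_per_novel_odor trials with each novel odor per learning
#'   session; must lie in 20-40.
#' @param n_reminder_trials initial-odor reminder trials per learning session.
#' @param n_probe_trials_per_odor unrewarded novel-odor presentations on the
#'   probe day (max 10).
#' @param iti_range_s uniform inter-trial-interval range, seconds.
#' @param baseline_meanlog,baseline_sdlog lognormal baseline-rate parameters
#'   (Hz); defaults give median 3 Hz.
#' @param modulation peak added rate (Hz) on the preferred cue(s).
#' @param learning_midpoint_trial per-cue trial index at which the logistic
#'   learning factor reaches 0.5 (day 2 continues day 1's count).
#' @param learning_slope logistic scale in trials.
#' @param peak_jitter_sd optional per-unit jitter (s) of the modulation window
#'   onset, default 0 (off).
#' @param latency_meanlog,latency_sdlog lognormal baseline latency
#'   (well entry minus odor offset), seconds.
#' @param novelty_latency_s added latency on the first novel-odor trials,
#'   decaying with \code{novelty_decay_trials}; scaled by
#'   \code{novelty_day2_factor} on day 2.
#' @param probe_tiw_mean named means (s) of time-in-well on the first probe
#'   extinction trials, one per novel cue.
#' @param probe_tiw_floor,probe_tiw_decay extinction floor (s) and exponential
#'   decay rate per trial of the cue effect.
#' @param probe_tiw_sd trial-level noise sd (s); \code{probe_tiw_rat_sd} is the
#'   between rat-round intercept sd.
#' @param seed default master seed used when none is passed to the generator.
#' @return a list of class \code{unblk_config}.
#' @export
generator_config <- function(task_variant = "blocking",
                             n_units_per_category = default_unit_mix(),
                             n_trials_per_novel_odor = 30L,
                             n_reminder_trials = 30L,
                             n_probe_trials_per_odor = 10L,
                             iti_range_s = c(4, 8),
                             baseline_meanlog = log(3),
                             baseline_sdlog = 0.5,
                             modulation = 2.0,
                             learning_midpoint_trial = 25,
                             learning_slope = 5,
                             peak_jitter_sd = 0,
                             latency_meanlog = log(0.5),
                             latency_sdlog = 0.4,
                             novelty_latency_s = 1.0,
                             novelty_decay_trials = 3,
                             novelty_day2_factor = 0.3,
                             probe_tiw_mean = NULL,
                             probe_tiw_floor = 1.0,
                             probe_tiw_decay = 0.15,
                             probe_tiw_sd = 0.8,
                             probe_tiw_rat_sd = 0.3,
                             seed = 1L) {
  task_variant <- match.arg(task_variant, names(TRIAL_TYPES))
  if (n_trials_per_novel_odor < 20L || n_trials_per_novel_odor > 40L)
    stop("n_trials_per_novel_odor must lie in [20, 40]")
  if (n_probe_trials_per_odor > 10L)
    stop("n_probe_trials_per_odor must be <= 10")
  stopifnot(all(n_units_per_category >= 0),
            n_reminder_trials > 0, modulation >= 0)
  bad <- setdiff(names(n_units_per_category), UNIT_CATEGORIES)
  if (length(bad)) stop("unknown unit category: ", bad[1])
  if (is.null(probe_tiw_mean)) {
    novel <- TRIAL_TYPES[[task_variant]][-1]
    ## ordering: more-reward cue > same > less (upshift > blocked > downshift)
    probe_tiw_mean <- switch(task_variant,
      blocking = c(upshift = 4.0, blocked = 3.0, downshift = 2.0),
      control  = c(large = 4.0, medium = 3.0, small = 2.0))
  }
  cfg <- list(task_variant = task_variant,
              n_units_per_category = n_units_per_category,
              n_trials_per_novel_odor = as.integer(n_trials_per_novel_odor),
              n_reminder_trials = as.integer(n_reminder_trials),
              n_probe_trials_per_odor = as.integer(n_probe_trials_per_odor),
              iti_range_s = iti_range_s,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              modulation = modulation,
              learning_midpoint_trial = learning_midpoint_trial,
              learning_slope = learning_slope,
              peak_jitter_sd = peak_jitter_sd,
              latency_meanlog = latency_meanlog,
              latency_sdlog = latency_sdlog,
              novelty_latency_s = novelty_latency_s,
              novelty_decay_trials = novelty_decay_trials,
              novelty_day2_factor = novelty_day2_factor,
              probe_tiw_mean = probe_tiw_mean,
              probe_tiw_floor = probe_tiw_floor,
              probe_tiw_decay = probe_tiw_decay,
              probe_tiw_sd = probe_tiw_sd,
              probe_tiw_rat_sd = probe_tiw_rat_sd,
              seed = as.integer(seed))
  class(cfg) <- "unblk_config"
  cfg
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "")
  r <- as.integer(charToRaw(s))
  sprintf("%08x", sum(r * (seq_along(r) %% 97 + 1)) %% .Machine$integer.max)
}

#' Logistic learning factor
#'
#' Fraction of asymptotic cue modulation expressed on the k-th trial with a
#' given cue, counted cumulatively across learning days.
#'
#' @param k per-cue cumulative trial index (day 2 continues day 1's count).
#' @param config an \code{unblk_config}.
#' @return numeric in (0, 1), monotone nondecreasing in \code{k}.
#' @export
learning_factor <- function(k, config) {
  stats::plogis((k - config$learning_midpoint_trial) / config$learning_slope)
}

## Trial types (beyond initial) that a category's modulation applies to, with
## multipliers of `modulation`. Value cells scale +0/+1/+2 across the cue that
## predicts less / the same / more reward. Sensory and initial-only cells are
## present from trial 1 (no learning ramp).
category_modulation <- function(category, variant) {
  types <- TRIAL_TYPES[[variant]]
  init <- types[1]
  if (variant == "blocking") {
    less <- "downshift"; same <- "blocked"; more <- "upshift"
  } else {
    less <- "small"; same <- "medium"; more <- "large"
  }
  mult <- switch(category,
    nonresponsive = numeric(0),
    sensory = stats::setNames(rep(1, 4), types),
    value = stats::setNames(c(0, 1, 2), c(less, same, more)),
    upshift_only = stats::setNames(1, more),
    downshift_only = stats::setNames(1, less),
    blocked_only = stats::setNames(1, same),
    large_only = stats::setNames(1, more),
    small_only = stats::setNames(1, less),
    medium_only = stats::setNames(1, same),
    predictive = stats::setNames(c(1, 1), c(more, less)),
    salience = stats::setNames(c(1, 1, 1), c(less, same, more)),
    initial_only = stats::setNames(1, init),
    stop("unknown category ", category))
  mult[mult > 0]
}

## no learning ramp for responses present from the start of training
category_has_ramp <- function(category) {
  !category %in% c("sensory", "initial_only")
}

draw_unit_profiles <- function(config, round_id) {
  n <- config$n_units_per_category
  n <- n[n > 0]
  cats <- rep(names(n), n)
  k <- length(cats)
  if (k == 0L)
    return(data.frame(unit_id = character(0), category = character(0),
                      baseline_rate = numeric(0), modulation = numeric(0),
                      peak_jitter = numeric(0), stringsAsFactors = FALSE))
  data.frame(
    unit_id = sprintf("r%03d_u%03d", round_id, seq_len(k)),
    category = cats,
    baseline_rate = stats::rlnorm(k, config$baseline_meanlog,
                                  config$baseline_sdlog),
    modulation = config$modulation,
    peak_jitter = if (config$peak_jitter_sd > 0)
      stats::rnorm(k, 0, config$peak_jitter_sd) else rep(0, k),
    stringsAsFactors = FALSE)
}

## Homogeneous Poisson spikes on [0, t_end); exact via exponential gaps.
sim_poisson_spikes <- function(rate, t_end) {
  if (rate <= 0 || t_end <= 0) return(numeric(0))
  n_guess <- stats::qpois(1 - 1e-12, rate * t_end) + 10L
  gaps <- stats::rexp(n_guess, rate)
  s <- cumsum(gaps)
  while (s[length(s)] < t_end) {
    gaps <- stats::rexp(n_guess, rate)
    s <- c(s, s[length(s)] + cumsum(gaps))
  }
  s[s < t_end]
}

## Build trial rows for one day; returns the trials data.frame plus per-trial
## behavioral draws. Latencies are lognormal plus a decaying novelty term on
## novel-cue trials; probe extinction time-in-well carries the cue ordering.
build_trials <- function(config, day, rat_effect = 0) {
  types <- TRIAL_TYPES[[config$task_variant]]
  init <- types[1]
  novel <- types[-1]
  if (day %in% c("1", "2")) {
    seq_types <- sample(c(rep(init, config$n_reminder_trials),
                          rep(novel, each = config$n_trials_per_novel_odor)))
    is_ext <- rep(FALSE, length(seq_types))
  } else {
    ## probe day: 10 reminder trials of each type, then the extinction block of
    ## unrewarded novel-odor presentations interleaved with rewarded initials
    reminders <- sample(rep(types, each = min(10L, config$n_reminder_trials)))
    ext <- sample(c(rep(novel, each = config$n_probe_trials_per_odor),
                    rep(init, config$n_probe_trials_per_odor)))
    seq_types <- c(reminders, ext)
    is_ext <- c(rep(FALSE, length(reminders)), rep(TRUE, length(ext)))
  }
  n <- length(seq_types)
  compound <- config$task_variant == "blocking" & seq_types != init
  type_ord <- stats::ave(seq_len(n), seq_types, FUN = seq_along)
  ## ordinal among extinction trials only, for probe behavior
  ext_ord <- integer(n)
  for (ty in types) {
    idx <- which(seq_types == ty & is_ext)
    ext_ord[idx] <- seq_along(idx)
  }

  iti <- stats::runif(n, config$iti_range_s[1], config$iti_range_s[2])
  port_delay <- stats::runif(n, 0.3, 1.5)
  base_lat <- stats::rlnorm(n, config$latency_meanlog, config$latency_sdlog)
  nov_amp <- config$novelty_latency_s *
    switch(day, "1" = 1, "2" = config$novelty_day2_factor, "probe" = 0)
  novelty <- ifelse(seq_types != init,
                    nov_amp * exp(-(type_ord - 1) / config$novelty_decay_trials),
                    0)
  latency <- base_lat + novelty

  reward_size <- rep("medium", n)
  if (config$task_variant == "blocking") {
    reward_size[seq_types == "upshift"] <- "large"
    reward_size[seq_types == "downshift"] <- "small"
  } else {
    reward_size[seq_types %in% c("large", "small")] <-
      seq_types[seq_types %in% c("large", "small")]
  }
  rewarded <- !(is_ext & seq_types != init)
  reward_size[!rewarded] <- "none"

  ## time in well: consumption on rewarded trials; on probe extinction trials
  ## it indexes learned reward expectation with cue ordering and decay
  tiw <- numeric(n)
  cons_mean <- c(none = 0, small = 1.5, medium = 2.0, large = 2.5)
  tiw[rewarded] <- pmax(0.3, stats::rnorm(sum(rewarded),
                                          cons_mean[reward_size[rewarded]],
                                          0.3))
  ext_idx <- which(!rewarded)
  if (length(ext_idx)) {
    mu <- config$probe_tiw_floor +
      (config$probe_tiw_mean[seq_types[ext_idx]] - config$probe_tiw_floor) *
        exp(-config$probe_tiw_decay * (ext_ord[ext_idx] - 1))
    tiw[ext_idx] <- pmax(0.2, stats::rnorm(length(ext_idx),
                                           mu + rat_effect,
                                           config$probe_tiw_sd))
  }

  occupied <- port_delay + 1.0 + latency + 0.05 + tiw + 0.5
  t_light <- cumsum(iti + c(0, occupied[-n]))
  t_port <- t_light + port_delay
  t_odor_on <- t_port + 0.05    # olfactometer delivery lag
  t_novel <- ifelse(compound, t_odor_on + 0.2, NA_real_)
  t_odor_off <- t_odor_on + 1.0
  t_well <- t_odor_off + latency
  t_reward <- ifelse(rewarded, t_well + 0.05, NA_real_)
  t_exit <- pmax(ifelse(rewarded, t_reward, t_well) + 0.1, t_well + tiw)

  data.frame(trial_index = seq_len(n), trial_type = seq_types,
             t_light_on = t_light, t_port_entry = t_port,
             t_odor_on = t_odor_on, t_novel_odor_on = t_novel,
             t_odor_off = t_odor_off, t_well_entry = t_well,
             t_reward = t_reward, t_well_exit = t_exit,
             reward_size = reward_size, completed = TRUE,
             type_ordinal = type_ord, extinction = !rewarded,
             ext_ordinal = ext_ord,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic session with ground truth
#'
#' Trial types are interleaved in randomized order; spikes are drawn from an
#' inhomogeneous Poisson process (homogeneous baseline plus added rate during
#' the cue analysis window of the unit's preferred trial types, scaled by the
#' logistic learning factor of the per-cue cumulative trial count, so that
#' day 2 continues day 1's learning). Deterministic given \code{seed}.
#'
#' @param config an \code{\link{generator_config}}.
#' @param day \code{"1"}, \code{"2"} or \code{"probe"}.
#' @param seed integer seed (default \code{config$seed}); the same seed yields
#'   the same units across days of one round.
#' @param round_id integer round identifier (unit ids are unique per round).
#' @param rat_id rat identifier.
#' @return list with elements \code{session} (an \code{unblk_session}) and
#'   \code{ground_truth} (data.frame \code{unit_id}, \code{category},
#'   \code{baseline_rate}, ...).
#' @export
generate_session <- function(config, day = c("1", "2", "probe"),
                             seed = config$seed, round_id = 1L,
                             rat_id = sprintf("rat%02d", round_id)) {
  day <- match.arg(as.character(day), c("1", "2", "probe"))
  stopifnot(inherits(config, "unblk_config"))
  ## unit profiles are drawn from a day-independent stream so the same round
  ## has the same units on every day
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  profiles <- draw_unit_profiles(config, round_id)
  ## day-specific stream for trials and spikes
  set.seed((seed + 7919L * match(day, c("1", "2", "probe"))) %%
             .Machine$integer.max)
  rat_effect <- stats::rnorm(1, 0, config$probe_tiw_rat_sd)
  tr <- build_trials(config, day, rat_effect = rat_effect)
  type_ord <- tr$type_ordinal
  ext <- tr$extinction
  tr_public <- tr[setdiff(names(tr), c("type_ordinal", "extinction",
                                       "ext_ordinal"))]
  session_end <- max(tr$t_well_exit) + 2

  ## cumulative per-cue learning index: day 2 continues after day 1's trials;
  ## the probe day follows both learning days
  ord_offset <- switch(day, "1" = 0L, "2" = config$n_trials_per_novel_odor,
                       "probe" = 2L * config$n_trials_per_novel_odor)

  session_id <- sprintf("r%03d_d%s", round_id, day)
  units <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    spikes <- sim_poisson_spikes(p$baseline_rate, session_end)
    mult <- category_modulation(p$category, config$task_variant)
    if (length(mult) && p$modulation > 0) {
      ramp <- category_has_ramp(p$category)
      for (ty in names(mult)) {
        idx <- which(tr$trial_type == ty & tr$completed)
        if (!length(idx)) next
        L <- if (ramp) learning_factor(type_ord[idx] + ord_offset, config)
             else rep(1, length(idx))
        add_rate <- p$modulation * mult[[ty]] * L
        ## modulation occupies the 1 s analysis window of the odor period
        w0 <- tr$t_odor_on[idx] + 0.3 + p$peak_jitter
        n_extra <- stats::rpois(length(idx), add_rate * 1.0)
        if (sum(n_extra)) {
          extra <- stats::runif(sum(n_extra)) + rep(w0, n_extra)
          spikes <- c(spikes, extra)
        }
      }
      spikes <- sort(spikes)
    }
    spikes <- unique(round_time(spikes))
    spikes <- spikes[spikes < session_end]
    units[[i]] <- unit_recording(p$unit_id, rat_id, session_id, day, spikes)
  }

  meta <- list(session_end = round_time(session_end), seed = as.integer(seed),
               day = day, round_id = as.integer(round_id), rat_id = rat_id,
               config_hash = config_hash(config), synthetic = TRUE)
  s <- session(tr_public, units, task_variant = config$task_variant,
               metadata = meta)
  gt <- profiles[c("unit_id", "category", "baseline_rate", "modulation")]
  gt$learning_midpoint_trial <- rep(config$learning_midpoint_trial, nrow(gt))
  gt$learning_slope <- rep(config$learning_slope, nrow(gt))
  list(session = s, ground_truth = gt)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a multi-round study (day 1, day 2, probe per round)
#'
#' Each round gets an independent seed derived from the master seed and a
#' fresh set of units (electrodes are advanced between rounds, so units are
#' new), with unit ids unique across rounds.
#'
#' @param config an \code{\link{generator_config}}.
#' @param n_rounds number of unblocking rounds.
#' @param seed master seed (default \code{config$seed}).
#' @return list of rounds; each round is a list with \code{day1}, \code{day2},
#'   \code{probe} sessions, \code{ground_truth}, \code{round_id},
#'   \code{rat_id}.
#' @export
generate_study <- function(config, n_rounds = 1L, seed = config$seed) {
  stopifnot(n_rounds >= 1)
  round_seeds <- (as.integer(seed) + 104729L * seq_len(n_rounds)) %%
    .Machine$integer.max
  lapply(seq_len(n_rounds), function(r) {
    d1 <- generate_session(config, "1", seed = round_seeds[r], round_id = r)
    d2 <- generate_session(config, "2", seed = round_seeds[r], round_id = r)
    pr <- generate_session(config, "probe", seed = round_seeds[r],
                           round_id = r)
    list(day1 = d1$session, day2 = d2$session, probe = pr$session,
         ground_truth = d1$ground_truth, round_id = r,
         rat_id = d1$session$metadata$rat_id)
  })
}
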