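# Synthetic session generator: Poisson machinery, learning dynamics,
# trial structure, determinism, and behavioral ordering.

test_that("homogeneous Poisson spike counts match the Poisson oracle", {
  # 5 Hz for 200 s: count ~ Poisson(1000); |count - 1000| < 3*sqrt(1000)
  set.seed(41)
  s <- unblockr:::sim_poisson_spikes(5, 200)
  expect_true(abs(length(s) - 1000) < 3 * sqrt(1000))
  expect_false(is.unsorted(s))
  expect_true(all(s >= 0 & s < 200))
})

test_that("interspike intervals of a constant-rate unit are exponential", {
  # KS test against the exponential passes at alpha = 0.01 in >= 95% of seeds
  pass <- vapply(1:20, function(seed) {
    set.seed(seed)
    s <- unblockr:::sim_poisson_spikes(8, 120)
    stats::ks.test(diff(s), "pexp", rate = 8)$p.value > 0.01
  }, TRUE)
  expect_gte(sum(pass), 19)
})

test_that("nonresponsive units show no cue-epoch modulation", {
  cfg <- generator_config(n_units_per_category = c(nonresponsive = 1L))
  g <- generate_session(cfg, "1", seed = 5)
  st <- epoch_stats(g$session)          # 120 trials across the four types
  expect_gte(nrow(st), 100)
  se <- sd(st$normalized) / sqrt(nrow(st))
  expect_lt(abs(mean(st$normalized)), 3 * se)
})

test_that("value-profile units rank the cues with ~2 Hz steps at asymptote", {
  cfg <- asymptotic_config(n_units_per_category = c(value = 4L),
                           baseline_sdlog = 0)
  # pool two sessions -> >= 200 trials per cue across units
  st <- rbind(epoch_stats(generate_session(cfg, "1", seed = 7)$session),
              epoch_stats(generate_session(cfg, "1", seed = 8)$session))
  m <- tapply(st$epoch_rate, st$trial_type, mean)
  n <- tapply(st$epoch_rate, st$trial_type, length)
  expect_gte(min(n[c("downshift", "blocked", "upshift")]), 200)
  expect_lt(m[["downshift"]], m[["blocked"]])
  expect_lt(m[["blocked"]], m[["upshift"]])
  # each gap ~2 Hz within sampling error (rate var ~ rate / n per cue)
  se_gap <- sqrt(m[["upshift"]] / n[["upshift"]] +
                   m[["blocked"]] / n[["blocked"]])
  expect_lt(abs((m[["upshift"]] - m[["blocked"]]) - 2), 4 * se_gap)
  expect_lt(abs((m[["blocked"]] - m[["downshift"]]) - 2), 4 * se_gap)
})

test_that("the learning factor is monotone and near zero on trial 1", {
  cfg <- generator_config()
  L <- learning_factor(1:60, cfg)
  expect_true(all(diff(L) >= 0))
  expect_lte(L[1], 0.1)                     # <= 10% of asymptote at trial 1
  expect_gt(learning_factor(60, cfg), 0.99) # near asymptote through day 2
})

test_that("generation is deterministic and unit ids are unique per round", {
  cfg <- generator_config(
    n_units_per_category = c(nonresponsive = 5L, salience = 5L),
    n_trials_per_novel_odor = 20L, n_reminder_trials = 5L)
  a <- generate_session(cfg, "2", seed = 3)
  b <- generate_session(cfg, "2", seed = 3)
  expect_identical(a, b)

  st1 <- generate_study(cfg, n_rounds = 1, seed = 2)
  expect_length(st1, 1)
  expect_named(st1[[1]], c("day1", "day2", "probe", "ground_truth",
                           "round_id", "rat_id"), ignore.order = TRUE)

  st6 <- generate_study(cfg, n_rounds = 6, seed = 2)
  ids <- unlist(lapply(st6, function(r) r$ground_truth$unit_id))
  expect_length(unique(ids), 60)

  st6b <- generate_study(cfg, n_rounds = 6, seed = 2)
  expect_identical(st6, st6b)
})

test_that("trial structure matches the task design", {
  cfg <- generator_config(n_units_per_category = c(nonresponsive = 1L))
  s1 <- generate_session(cfg, "1", seed = 9)$session
  tr <- s1$trials
  expect_equal(sum(tr$trial_type == "initial"), 30)
  expect_equal(unname(table(tr$trial_type)[c("blocked", "upshift",
                                             "downshift")]),
               rep(30L, 3), ignore_attr = TRUE)
  cmp <- tr$trial_type != "initial"
  expect_true(all(!is.na(tr$t_novel_odor_on[cmp])))
  expect_true(all(is.na(tr$t_novel_odor_on[!cmp])))
  expect_equal(tr$t_novel_odor_on[cmp] - tr$t_odor_on[cmp],
               rep(0.2, sum(cmp)), tolerance = 1e-9)

  # probe day: unrewarded novel-odor presentations exist
  pr <- generate_session(cfg, "probe", seed = 9)$session$trials
  unrew <- is.na(pr$t_reward)
  expect_equal(sum(unrew), 3 * cfg$n_probe_trials_per_odor)
  expect_true(all(pr$trial_type[unrew] != "initial"))

  # control variant: no compound cue anywhere
  cc <- generator_config(task_variant = "control",
                         n_units_per_category = c(large_only = 1L))
  sc <- generate_session(cc, "1", seed = 4)$session
  expect_true(all(is.na(sc$trials$t_novel_odor_on)))
  expect_setequal(unique(sc$trials$trial_type),
                  c("initial", "medium", "large", "small"))
})

test_that("probe behavior orders time-in-well upshift > blocked > downshift", {
  study <- generate_study(
    generator_config(n_units_per_category = c(nonresponsive = 1L)),
    n_rounds = 8, seed = 31)
  bt <- behavior_table(study)
  early <- bt[bt$measure == "time_in_well_s" & bt$trial_index <= 4, ]
  m <- tapply(early$value, early$trial_type, mean)
  expect_gt(m[["upshift"]], m[["blocked"]])
  expect_gt(m[["blocked"]], m[["downshift"]])
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_trials_per_novel_odor = 10), "20")
  expect_error(generator_config(n_probe_trials_per_odor = 12), "10")
  expect_error(generator_config(
    n_units_per_category = c(wiggly = 3L)), "unknown")
})
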