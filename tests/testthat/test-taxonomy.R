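# Responsiveness screens, value-coding definition, category assignment,
# tuned-count uniformity, and latency correlations.

test_that("chi-squared uniformity test matches the closed-form oracle", {
  # published worked example: counts 19/16/16 -> 0.353, p = 0.84
  r <- category_uniformity_test(c(19, 16, 16))
  expect_equal(round(r$statistic, 3), 0.353)
  expect_equal(r$df, 2)
  expect_equal(round(r$p_value, 2), 0.84)

  expect_equal(category_uniformity_test(c(17, 17, 17))$statistic, 0)

  # independent hand formula sum((o - e)^2 / e) on a lopsided case
  o <- c(51, 0, 0); e <- rep(mean(o), 3)
  expect_equal(category_uniformity_test(o)$statistic, sum((o - e)^2 / e))
  expect_equal(category_uniformity_test(o)$statistic, 102)
})

test_that("classification follows the decision order", {
  sig <- function(...) {
    x <- c(initial = FALSE, blocked = FALSE, upshift = FALSE,
           downshift = FALSE)
    x[c(...)] <- TRUE
    x
  }
  cls <- function(s, value = FALSE)
    classify_units(fake_screen(s), fake_value(value))$category

  expect_equal(cls(sig()), "nonresponsive")
  expect_equal(cls(sig("initial", "blocked", "upshift", "downshift")),
               "sensory")
  expect_equal(cls(sig("initial", "blocked", "upshift", "downshift"),
                   value = TRUE), "value")
  expect_equal(cls(sig("blocked", "upshift"), value = TRUE), "value")
  expect_equal(cls(sig("initial")), "initial_only")
  expect_equal(cls(sig("upshift")), "upshift_only")
  expect_equal(cls(sig("downshift")), "downshift_only")
  expect_equal(cls(sig("blocked")), "blocked_only")
  expect_equal(cls(sig("upshift", "downshift")), "predictive")
  expect_equal(cls(sig("blocked", "upshift", "downshift")), "salience")
  expect_equal(cls(sig("initial", "upshift")), "other_mixed")
  expect_equal(cls(sig("blocked", "upshift")), "other_mixed")

  # ineligible baseline dominates everything
  expect_equal(
    classify_units(fake_screen(sig("upshift"), eligible = FALSE,
                               baseline = 12),
                   fake_value(FALSE))$category,
    "ineligible")
})

test_that("classification is order-independent across units", {
  s2 <- rbind(fake_screen(c(initial = FALSE, blocked = FALSE,
                            upshift = TRUE, downshift = FALSE), "a"),
              fake_screen(c(initial = FALSE, blocked = TRUE,
                            upshift = TRUE, downshift = TRUE), "b"))
  attr(s2, "odors") <- c("initial", "blocked", "upshift", "downshift")
  v2 <- rbind(fake_value(FALSE, "a"), fake_value(FALSE, "b"))
  fwd <- classify_units(s2, v2)
  rev_ <- classify_units(s2[rev(seq_len(nrow(s2))), ], v2)
  expect_equal(fwd$category[fwd$unit_id == "a"],
               rev_$category[rev_$unit_id == "a"])
  expect_equal(fwd$category[fwd$unit_id == "b"],
               rev_$category[rev_$unit_id == "b"])
})

test_that("the screen detects tuned units and respects the baseline cutoff", {
  # power: asymptotic upshift-only units should be called upshift-and-only-
  # upshift in >= 80% of draws
  cfg <- asymptotic_config(n_units_per_category = c(upshift_only = 10L))
  hits <- 0; total <- 0
  for (seed in 1:2) {
    g <- generate_session(cfg, "2", seed = seed)
    cl <- classify_session(g$session)
    total <- total + nrow(cl$taxonomy)
    hits <- hits + sum(cl$taxonomy$category == "upshift_only")
  }
  expect_gte(hits / total, 0.8)

  # baseline >= 10 Hz -> ineligible regardless of modulation
  cfg_hi <- asymptotic_config(n_units_per_category = c(upshift_only = 3L),
                              baseline_meanlog = log(14), baseline_sdlog = 0)
  g <- generate_session(cfg_hi, "2", seed = 1)
  scr <- classify_session(g$session)
  expect_true(all(!scr$screen$eligible))
  expect_true(all(scr$taxonomy$category == "ineligible"))
})

test_that("the value-coding definition separates value from tuned units", {
  # value units are flagged well above the alpha level; upshift-only units
  # are flagged at ~alpha (their downshift firing matches blocked firing)
  cfg_v <- asymptotic_config(n_units_per_category = c(value = 10L))
  cfg_u <- asymptotic_config(n_units_per_category = c(upshift_only = 10L))
  v_flags <- u_flags <- 0; n <- 0
  for (seed in 1:3) {
    gv <- generate_session(cfg_v, "2", seed = seed)
    gu <- generate_session(cfg_u, "2", seed = seed)
    v_flags <- v_flags + sum(classify_session(gv$session)$value$value_coding)
    u_flags <- u_flags + sum(classify_session(gu$session)$value$value_coding)
    n <- n + 10
  }
  expect_gte(v_flags / n, 0.4)   # both one-sided 1% tests must reject
  expect_lte(u_flags / n, 0.15)
  # a flat unit is never value-coding
  cfg_0 <- generator_config(n_units_per_category = c(nonresponsive = 5L))
  g0 <- generate_session(cfg_0, "2", seed = 4)
  expect_false(any(classify_session(g0$session)$value$value_coding))
})

test_that("insufficient trials are flagged unanalyzable, never dropped", {
  tr <- rbind(make_trial(5, 1L, "initial", "medium"),
              make_trial(15, 2L, "blocked", "medium"),
              make_trial(25, 3L, "upshift", "large"),
              make_trial(35, 4L, "downshift", "small"))
  tr$t_novel_odor_on[1] <- NA
  s <- session(tr, list(unit_recording("u", "r", "s", "1", c(1, 2, 3))))
  scr <- screen_responsive(s, min_trial = 1)
  expect_equal(nrow(scr), 4)       # unit still present, one row per odor
  expect_true(all(!scr$analyzable))
  tax <- classify_units(scr, is_value_coding(s, screen = scr))
  expect_equal(tax$category, "unanalyzable")
})

test_that("latency correlations recover engineered dependence", {
  # build a session whose latency is an affine function of the unit's
  # odor-epoch rate -> r ~ 1 on every trial type
  cfg <- asymptotic_config(n_units_per_category = c(salience = 1L),
                           n_trials_per_novel_odor = 35L)
  g <- generate_session(cfg, "2", seed = 6)
  s <- g$session
  st <- epoch_stats(s, min_trial = 1)
  tr <- s$trials
  rate <- st$epoch_rate[match(tr$trial_index, st$trial_index)]
  rate[is.na(rate)] <- 0
  lat <- 0.2 + 0.05 * rate
  tr$t_well_entry <- tr$t_odor_off + lat
  tr$t_reward <- ifelse(is.na(tr$t_reward), NA, tr$t_well_entry + 0.05)
  tr$t_well_exit <- tr$t_well_entry + 0.5
  s2 <- session(tr, s$units,
                metadata = list(session_end = max(s$metadata$session_end,
                                                  max(tr$t_well_exit) + 2)))
  lc <- latency_firing_correlation(s2, trials = 5:30)
  expect_true(all(lc$analyzable))
  expect_true(all(lc$r > 0.95))

  # anticorrelated construction -> r ~ -1
  tr$t_well_entry <- tr$t_odor_off + 2.0 - 0.05 * rate
  tr$t_reward <- ifelse(is.na(tr$t_reward), NA, tr$t_well_entry + 0.05)
  tr$t_well_exit <- tr$t_well_entry + 0.5
  s3 <- session(tr, s$units,
                metadata = list(session_end = max(s$metadata$session_end,
                                                  max(tr$t_well_exit) + 2)))
  lc3 <- latency_firing_correlation(s3, trials = 5:30)
  expect_true(all(lc3$r < -0.95))

  # degenerate: fewer than three usable trials
  lc2 <- latency_firing_correlation(s2, trials = 5:6)
  expect_true(all(!lc2$analyzable))
})

test_that("latency correlations are calibrated under independence", {
  cfg <- generator_config(n_units_per_category = c(nonresponsive = 15L))
  rates <- NULL
  for (seed in 1:4) {
    g <- generate_session(cfg, "2", seed = 40 + seed)
    lc <- latency_firing_correlation(g$session, trials = 5:30)
    rates <- c(rates, lc$p[lc$analyzable] < 0.05)
  }
  expect_gte(length(rates), 200)
  expect_lt(mean(rates), 0.12)    # ~ alpha = 0.05 under the null
})
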