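# Epoch rates, PSTHs, sliding windows, smoothing.

test_that("epoch rates are spike counts over window length", {
  tr <- make_trial(10)  # odor on at 10.85; odor epoch [11.15, 12.15)
  odor <- default_epochs()$odor
  iti <- default_epochs()$iti

  expect_equal(epoch_rate(numeric(0), tr, odor), 0)
  expect_equal(epoch_rate(seq(11.2, 12.1, length.out = 8), tr, odor), 8)
  # ITI window is [8, 10): 10 spikes over 2 s -> 5 Hz
  expect_equal(epoch_rate(seq(8.05, 9.95, length.out = 10), tr, iti), 5)
  # half-open: spike exactly at the epoch end is excluded
  expect_equal(epoch_rate(c(11.15, 12.15), tr, odor), 1)
  # absent anchor -> NA
  tr2 <- make_trial(); tr2$t_light_on <- NA
  expect_true(is.na(epoch_rate(c(1, 2), tr2, iti)))
})

test_that("normalized firing is the exact difference and is mean-zero under
          the null", {
  expect_equal(normalized_firing(8, 5), 3)
  expect_equal(normalized_firing(4.2, 4.2), 0)
  # homogeneous unit over 500 trials: mean normalized ~ 0 within 3 SE
  tr <- regular_trials(500, gap = 8)
  set.seed(20)
  spikes <- unique(round_time(
    unblockr:::sim_poisson_spikes(6, max(tr$t_well_exit) + 2)))
  s <- session(tr, list(unit_recording("u", "r", "s", "1", spikes)))
  st <- epoch_stats(s)
  expect_equal(nrow(st), 500)
  se <- sd(st$normalized) / sqrt(nrow(st))
  expect_lt(abs(mean(st$normalized)), 3 * se)
})

test_that("epoch_stats honors completion, the trial filter, and purity", {
  tr <- regular_trials(10)
  tr$completed[3] <- FALSE
  tr$t_odor_off[3] <- NA  # incomplete trial need not satisfy the odor hold
  s <- session(tr, list(unit_recording("u", "r", "s", "1", c(5, 15))))
  st <- epoch_stats(s)
  expect_false(3 %in% st$trial_index)
  st8 <- epoch_stats(s, min_trial = 8)
  expect_true(all(st8$type_ordinal >= 8))
  expect_identical(epoch_stats(s), epoch_stats(s))  # pure function
})

test_that("psth bins follow the half-open 50 ms convention", {
  # single spike at a bin center: exactly one bin at 1/bin_width
  m <- psth(c(10.125), anchors = 10, bin_width_s = 0.05, span = c(0, 1))
  expect_equal(ncol(m), 20)
  expect_equal(sum(m > 0), 1)
  expect_equal(m[1, 3], 20)  # bin [0.10, 0.15)
  # spike exactly on a boundary goes to the later bin
  m2 <- psth(c(10.15), anchors = 10, bin_width_s = 0.05, span = c(0, 1))
  expect_equal(unname(which(m2[1, ] > 0)), 4)
})

test_that("psth means match the Poisson oracle for a constant-rate unit", {
  set.seed(77)
  anchors <- seq(5, by = 4, length.out = 1000)
  spikes <- unblockr:::sim_poisson_spikes(10, max(anchors) + 3)
  m <- psth(spikes, anchors, bin_width_s = 0.05, span = c(0, 1))
  bin_means <- colMeans(m)
  # each bin mean ~ 10 Hz within 3 SE (var of a bin rate = rate/bin_width)
  se <- sqrt(10 / 0.05 / nrow(m))
  expect_true(all(abs(bin_means - 10) < 3.5 * se))
  expect_lt(abs(mean(bin_means) - 10), 3 * se / sqrt(ncol(m) / 3))
})

test_that("spike totals are conserved across non-overlapping bins", {
  set.seed(3)
  spikes <- sort(runif(200, 0, 30))
  tr <- make_trial(10)
  odor <- default_epochs()$odor
  total <- epoch_rate(spikes, tr, odor) * 1.0
  m <- psth(spikes, anchors = tr$t_odor_on + 0.3, bin_width_s = 0.05,
            span = c(0, 1))
  expect_equal(sum(m[1, ] * 0.05), total)
})

test_that("sliding windows follow the count formula and a brute-force
          recount", {
  expect_equal(ncol(sliding_window_rates(numeric(0), 0, span = c(0, 1))), 18)
  expect_equal(ncol(sliding_window_rates(numeric(0), 0, window = 0.15,
                                         span = c(0, 0.15))), 1)
  set.seed(8)
  spikes <- sort(runif(300, 0, 20))
  anchors <- c(2, 9.5)
  w <- sliding_window_rates(spikes, anchors, window = 0.15, step = 0.05,
                            span = c(0, 1))
  starts <- attr(w, "window_starts")
  # brute-force recount oracle
  for (i in seq_along(anchors))
    for (j in seq_along(starts)) {
      lo <- anchors[i] + starts[j]
      expect_equal(w[i, j], sum(spikes >= lo & spikes < lo + 0.15) / 0.15)
    }
})

test_that("smooth_bins is a trailing moving average with shortened output", {
  expect_equal(smooth_bins(rep(2.5, 10), 4), rep(2.5, 7))
  expect_equal(smooth_bins(c(0, 0, 0, 4), 4), 1)
  ramp <- seq(1, 10)
  sm <- smooth_bins(ramp, 3)
  expect_equal(sm, seq(2, 9))          # linear ramp stays linear
  expect_length(sm, 8)
  m <- matrix(1:12, nrow = 2, byrow = TRUE)
  expect_equal(dim(smooth_bins(m, 3)), c(2, 4))
  expect_error(smooth_bins(1:3, 5), "k must")
})

test_that("epoch definitions are data: the alternative odor window is
          honored", {
  alt <- default_epochs("post_novel")
  expect_equal(alt$odor$start_offset_s, 0.2)
  tr <- make_trial(0)  # odor on 0.85 -> alt window [1.05, 2.05)
  expect_equal(epoch_rate(c(1.06, 2.04), tr, alt$odor), 2)
  expect_error(epoch_definition("x", "t_odor_on", 1, 1), "end <= start")
  expect_error(epoch_definition("x", "nope", 0, 1), "unknown anchor")
})
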