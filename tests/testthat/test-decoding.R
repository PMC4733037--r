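# Pseudo-trial construction, the shrinkage-LDA decoder, and binomial
# significance.

test_that("binomial p-values equal the exhaustive tail sum", {
  expect_equal(binomial_significance(8, 8, 0.25), 0.25^8)
  # k at exactly chance*n is never significant at 0.05
  for (n in c(4, 8, 20, 40))
    expect_gt(binomial_significance(n / 4, n, 0.25), 0.05)
  # oracle equivalence for n <= 50: brute-force tail summation
  set.seed(2)
  for (i in 1:25) {
    n <- sample(1:50, 1)
    k <- sample(0:n, 1)
    oracle <- sum(dbinom(k:n, n, 0.25))
    expect_equal(binomial_significance(k, n, 0.25), oracle,
                 tolerance = 1e-12)
  }
  # minimal significant k at n = 20 found by exhaustive search
  ks <- 0:20
  tails <- vapply(ks, function(k) sum(dbinom(k:20, 20, 0.25)), 0)
  k_min <- min(ks[tails < 0.05])
  expect_lt(binomial_significance(k_min, 20, 0.25), 0.05)
  expect_gte(binomial_significance(k_min - 1, 20, 0.25), 0.05)
})

test_that("pseudo-trial matrices have the documented shape and alignment", {
  cfg <- generator_config(n_units_per_category = c(nonresponsive = 1L),
                          n_trials_per_novel_odor = 20L,
                          n_reminder_trials = 20L)
  s1 <- generate_session(cfg, "1", seed = 1, round_id = 1)$session
  s2 <- generate_session(cfg, "1", seed = 2, round_id = 2)$session
  pt <- build_pseudotrials(list(s1, s2))
  expect_equal(dim(pt$X), c(80, 20, 2))      # 20 trials x 4 classes; 2 units
  expect_equal(as.vector(table(pt$y)), rep(20L, 4))
  expect_equal(pt$n_per_class, 20)

  # single unit: rows are exactly that unit's own binned trials
  pt1 <- build_pseudotrials(s1)
  tr <- s1$trials
  up_idx <- which(tr$trial_type == "upshift")
  m <- psth(s1$units[[1]]$spikes, tr$t_odor_on[up_idx], bin_width_s = 0.1,
            span = c(-0.5, 1.5))
  rows_up <- which(pt1$y == "upshift")
  expect_equal(pt1$X[rows_up, , 1], unclass(m)[seq_along(rows_up), ],
               ignore_attr = TRUE)
})

test_that("a perfectly separable unit decodes with accuracy 1", {
  n <- 12
  X <- array(0, dim = c(2 * n, 5, 1))
  X[seq_len(n), , 1] <- matrix(rnorm(n * 5, 0, 0.1), n)        # class A ~ 0
  X[n + seq_len(n), , 1] <- matrix(rnorm(n * 5, 100, 0.1), n)  # class B ~ 100
  pt <- make_pt(X, rep(c("A", "B"), each = n))
  dr <- decode_over_time(pt, accuracy_window = c(0.2, 0.7))
  expect_equal(dr$window_accuracy, 1)
  expect_equal(dr$chance, 0.5)
  expect_lt(dr$window_p, 1e-10)
})

test_that("label shuffling drives accuracy to chance", {
  set.seed(30)
  X <- array(rnorm(40 * 5 * 6, 5, 1), dim = c(40, 5, 6))
  pt <- make_pt(X, rep(c("a", "b", "c", "d"), each = 10))
  sh <- shuffle_control(pt, n_shuffles = 30)
  se <- sd(sh) / sqrt(length(sh))
  expect_lt(abs(mean(sh) - 0.25), max(2 * se, 0.03))
})

test_that("adding a perfectly informative unit does not hurt accuracy", {
  set.seed(9)
  accs <- vapply(1:5, function(i) {
    X <- array(rnorm(40 * 5 * 4), dim = c(40, 5, 4))
    y <- rep(c("a", "b", "c", "d"), each = 10)
    pt0 <- make_pt(X, y)
    Xp <- array(0, dim = c(40, 5, 5))
    Xp[, , 1:4] <- X
    Xp[, , 5] <- 100 * as.integer(factor(y))   # perfect class code
    pt1 <- make_pt(Xp, y)
    a0 <- decode_over_time(pt0)$window_accuracy
    a1 <- decode_over_time(pt1)$window_accuracy
    a1 - a0
  }, 0)
  expect_true(all(accs >= 0))
})

test_that("trial-window decoding covers the session and degenerates to one
          window", {
  cfg <- asymptotic_config(
    n_units_per_category = c(upshift_only = 4L, downshift_only = 4L,
                             blocked_only = 4L),
    n_trials_per_novel_odor = 20L, n_reminder_trials = 20L)
  pt <- build_pseudotrials(generate_session(cfg, "2", seed = 3)$session)
  dtr <- decode_over_trials(pt, trial_window = 10)
  expect_equal(nrow(dtr$windows), 11)       # 20 - 10 + 1 sliding positions
  expect_equal(unique(dtr$windows$n), 40)   # 10 trials x 4 classes scored
  expect_length(dtr$smoothed_accuracy, 9)
  dall <- decode_over_trials(pt, trial_window = 20)
  expect_equal(nrow(dall$windows), 1)
  expect_equal(dall$windows$n, 80)
  expect_error(decode_over_trials(pt, trial_window = 21), "exceeds")
})

test_that("the shrinkage LDA agrees with reference LDA when well-
          conditioned", {
  skip_if_not_installed("MASS")
  set.seed(14)
  n <- 150; p <- 3
  X <- rbind(matrix(rnorm(n * p, 0), n), matrix(rnorm(n * p, 1.2), n))
  y <- factor(rep(c("a", "b"), each = n))
  fit <- unblockr:::fit_shrinkage_lda(X, y, lambda = 1e-9)
  ours <- unblockr:::predict_shrinkage_lda(fit, X)
  ref <- as.character(predict(MASS::lda(X, y))$class)
  expect_gte(mean(ours == ref), 0.99)
})

test_that("decoder input contracts are enforced", {
  X <- array(rnorm(8 * 3 * 2), dim = c(8, 3, 2))
  pt_one <- make_pt(X, rep("a", 8))
  expect_error(decode_over_time(pt_one), "2 classes")
  pt_small <- make_pt(X, rep(c("a", "b"), c(6, 2)))
  expect_error(decode_over_time(pt_small), "4 pseudo-trials")
})
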