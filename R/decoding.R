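# Pseudo-ensemble decoding of trial type: pseudo-trial construction,
# shrinkage linear-discriminant classification with leave-one-out
# cross-validation, time-resolved and trial-resolved accuracy, and exact
# binomial significance.

#' Build a pseudo-trial matrix from units recorded in separate sessions
#'
#' Units recorded in different sessions are combined as if simultaneous:
#' pseudo-trial j of class c concatenates every unit's j-th trial of type c
#' (alignment by within-type trial index, so learning stage is preserved).
#' Classes are truncated to the common per-class trial count across units.
#'
#' @param sessions an \code{unblk_session} or list of them.
#' @param unit_ids units to include (default: all in the sessions).
#' @param bin_width_s feature bin width in seconds (default 0.1).
#' @param span seconds around the alignment anchor (odor onset;
#'   default \code{c(-0.5, 1.5)}).
#' @param pairing \code{"index"} (default, deterministic) or \code{"random"}
#'   within-type pairing (ablation; uses the current RNG state).
#' @param min_trials drop units with fewer trials of any type (default: use
#'   the minimum available, but at least 4); excluded units are recorded in
#'   the \code{excluded} attribute.
#' @return object of class \code{unblk_pseudotrials}: list with \code{X}
#'   (array trial x bin x unit of rates in Hz), \code{y} (factor of trial
#'   types), \code{bin_starts}, \code{unit_ids}.
#' @export
build_pseudotrials <- function(sessions, unit_ids = NULL, bin_width_s = 0.1,
                               span = c(-0.5, 1.5),
                               pairing = c("index", "random"),
                               min_trials = 4L) {
  pairing <- match.arg(pairing)
  if (inherits(sessions, "unblk_session")) sessions <- list(sessions)
  variant <- sessions[[1]]$task_variant
  classes <- TRIAL_TYPES[[variant]]
  ## per unit: matrix of binned rates per trial of each class
  unit_tables <- list()
  for (s in sessions) {
    tr <- s$trials
    tr$type_ordinal <- stats::ave(seq_len(nrow(tr)), tr$trial_type,
                                  FUN = seq_along)
    for (u in s$units) {
      if (!is.null(unit_ids) && !u$unit_id %in% unit_ids) next
      per_class <- lapply(classes, function(cl) {
        idx <- which(tr$trial_type == cl & tr$completed)
        idx <- idx[order(tr$type_ordinal[idx])]
        psth(u$spikes, tr$t_odor_on[idx], bin_width_s = bin_width_s,
             span = span)
      })
      names(per_class) <- classes
      unit_tables[[u$unit_id]] <- per_class
    }
  }
  if (!length(unit_tables)) stop("no units to build pseudo-trials from")
  counts <- vapply(unit_tables, function(pc)
    min(vapply(pc, nrow, 0L)), 0L)
  excluded <- names(counts)[counts < min_trials]
  unit_tables <- unit_tables[counts >= min_trials]
  if (!length(unit_tables))
    stop("all units fall below the minimum per-type trial count")
  n_common <- min(counts[counts >= min_trials])
  n_bins <- ncol(unit_tables[[1]][[1]])
  n_units <- length(unit_tables)
  X <- array(0, dim = c(n_common * length(classes), n_bins, n_units),
             dimnames = list(NULL, NULL, names(unit_tables)))
  y <- factor(rep(classes, each = n_common), levels = classes)
  for (k in seq_len(n_units)) {
    pc <- unit_tables[[k]]
    for (ci in seq_along(classes)) {
      m <- pc[[classes[ci]]]
      rows <- if (pairing == "index") seq_len(n_common)
              else sample(nrow(m), n_common)
      X[(ci - 1) * n_common + seq_len(n_common), , k] <- m[rows, ,
                                                           drop = FALSE]
    }
  }
  structure(list(X = X, y = y,
                 bin_starts = attr(unit_tables[[1]][[1]], "bin_starts"),
                 bin_width_s = bin_width_s, unit_ids = names(unit_tables),
                 n_per_class = n_common, excluded = excluded),
            class = "unblk_pseudotrials")
}

#' @export
print.unblk_pseudotrials <- function(x, ...) {
  cat(sprintf("<unblk_pseudotrials> %d x %d bins x %d units (%d/class)\n",
              length(x$y), length(x$bin_starts), length(x$unit_ids),
              x$n_per_class))
  invisible(x)
}

## Shrinkage linear discriminant: pooled within-class covariance shrunk
## toward its diagonal plus a small ridge, equal priors. Behaves like
## ordinary LDA when n >> p and lambda -> 0, but stays well-posed for the
## small-n pseudo-ensemble settings used here.
fit_shrinkage_lda <- function(X, y, lambda = 0.5) {
  y <- droplevels(y)
  cls <- levels(y)
  p <- ncol(X)
  vap <- vapply(cls, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                numeric(p))
  mu <- if (p == 1) matrix(vap, ncol = 1) else t(vap)
  S <- matrix(0, p, p)
  for (cl in cls) {
    Xc <- X[y == cl, , drop = FALSE]
    Xc <- sweep(Xc, 2, colMeans(Xc))
    S <- S + crossprod(Xc)
  }
  S <- S / max(1, nrow(X) - length(cls))
  S <- (1 - lambda) * S + lambda * diag(diag(S), p)
  diag(S) <- diag(S) + 1e-6 * max(mean(diag(S)), 1e-12)
  W <- solve(S, t(mu))                  # p x k discriminant directions
  b <- -0.5 * colSums(t(mu) * W)        # per-class intercepts
  list(W = W, b = b, classes = cls)
}

predict_shrinkage_lda <- function(fit, X) {
  scores <- X %*% fit$W + matrix(fit$b, nrow(X), length(fit$b), byrow = TRUE)
  fit$classes[max.col(scores, ties.method = "first")]
}

## multinomial-logistic alternative (config switch); requires nnet
fit_predict_multinom <- function(Xtr, ytr, Xte) {
  if (!requireNamespace("nnet", quietly = TRUE))
    stop("method = 'multinom' requires the nnet package")
  df <- data.frame(y = ytr, Xtr)
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200)
  as.character(stats::predict(fit, newdata = data.frame(Xte)))
}

## leave-one-pseudo-trial-out predictions for one feature matrix
loo_predict <- function(X, y, method = "lda", lambda = 0.5) {
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    if (method == "lda") {
      fit <- fit_shrinkage_lda(X[-i, , drop = FALSE], y[-i], lambda = lambda)
      pred[i] <- predict_shrinkage_lda(fit, X[i, , drop = FALSE])
    } else {
      pred[i] <- fit_predict_multinom(X[-i, , drop = FALSE], y[-i],
                                      X[i, , drop = FALSE])
    }
  }
  pred
}

#' Exact binomial tail probability for decoding accuracy
#'
#' Upper-tail probability P(X >= k) for X ~ Binomial(n, chance): the
#' probability of at least the observed number of correct classifications
#' under chance performance.
#'
#' @param k_correct observed number of correct predictions.
#' @param n_effective number of scored predictions.
#' @param chance chance accuracy (1 / number of classes).
#' @return p-value.
#' @export
binomial_significance <- function(k_correct, n_effective, chance) {
  stopifnot(k_correct >= 0, k_correct <= n_effective, chance > 0, chance < 1)
  stats::pbinom(k_correct - 1, n_effective, chance, lower.tail = FALSE)
}

#' Time-resolved pseudo-ensemble decoding of trial type
#'
#' For every time bin, a linear classifier is trained on the across-unit rate
#' pattern in that bin and scored by leave-one-pseudo-trial-out
#' cross-validation. Within the stated accuracy window each bin of a held-out
#' pseudo-trial is scored as its own prediction (bins counted as additional
#' trials to offset the low trial count), so the effective n for the window's
#' binomial test is the number of pseudo-trials times the number of window
#' bins.
#'
#' @param pt an \code{\link{build_pseudotrials}} object.
#' @param accuracy_window numeric length-2, seconds relative to odor onset
#'   over which the summary accuracy is computed (default \code{c(0.2, 0.7)},
#'   the 500 ms following novel odor onset; use \code{c(0.2, 0.6)} for the
#'   400 ms all-cells convention).
#' @param method \code{"lda"} (shrinkage linear discriminant, default) or
#'   \code{"multinom"}.
#' @param lambda shrinkage weight toward the diagonal covariance (default
#'   0.5).
#' @param smooth_k bins in the trailing moving average applied to the
#'   reported accuracy curve (default 3; \code{1} disables).
#' @param alpha significance level for per-bin flags.
#' @return list of class \code{unblk_decoding}: per-bin data.frame
#'   (\code{bin_start}, \code{accuracy}, \code{p}, \code{significant}),
#'   smoothed curve, window summary (\code{window_accuracy},
#'   \code{n_effective}, \code{window_p}), \code{chance}.
#' @export
decode_over_time <- function(pt, accuracy_window = c(0.2, 0.7),
                             method = c("lda", "multinom"), lambda = 0.5,
                             smooth_k = 3L, alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(pt, "unblk_pseudotrials"))
  y <- pt$y
  if (nlevels(droplevels(y)) < 2) stop("need >= 2 classes to decode")
  if (min(table(y)) < 4) stop("need >= 4 pseudo-trials per class")
  n_bins <- dim(pt$X)[2]
  n <- length(y)
  chance <- 1 / nlevels(y)
  correct <- matrix(FALSE, n, n_bins)
  for (b in seq_len(n_bins)) {
    Xb <- pt$X[, b, , drop = TRUE]
    if (is.null(dim(Xb))) Xb <- matrix(Xb, ncol = 1)
    pred <- loo_predict(Xb, y, method = method, lambda = lambda)
    correct[, b] <- pred == as.character(y)
  }
  acc <- colMeans(correct)
  p_bin <- vapply(seq_len(n_bins), function(b)
    binomial_significance(sum(correct[, b]), n, chance), 0)
  in_win <- pt$bin_starts >= accuracy_window[1] - 1e-9 &
    pt$bin_starts + pt$bin_width_s <= accuracy_window[2] + 1e-9
  k_win <- sum(correct[, in_win])
  n_eff <- n * sum(in_win)            # bins counted as additional trials
  res <- data.frame(bin_start = pt$bin_starts, accuracy = acc, p = p_bin,
                    significant = p_bin < alpha)
  smoothed <- if (smooth_k > 1 && n_bins >= smooth_k)
    smooth_bins(acc, smooth_k) else acc
  structure(list(bins = res, smoothed_accuracy = smoothed,
                 smooth_k = smooth_k,
                 window_accuracy = k_win / n_eff, n_effective = n_eff,
                 window_p = binomial_significance(k_win, n_eff, chance),
                 accuracy_window = accuracy_window, chance = chance,
                 method = method),
            class = "unblk_decoding")
}

#' @export
print.unblk_decoding <- function(x, ...) {
  cat(sprintf(paste0("<unblk_decoding> chance %.3f; window [%g, %g) s: ",
                     "accuracy %.3f (n_eff %d, p %.3g)\n"),
              x$chance, x$accuracy_window[1], x$accuracy_window[2],
              x$window_accuracy, x$n_effective, x$window_p))
  invisible(x)
}

#' Decoding accuracy over a sliding window of trials
#'
#' Within each window of consecutive within-type trial indices, a linear
#' classifier on the per-unit mean rate in the accuracy window is scored by
#' leave-one-out cross-validation over the window's pseudo-trials. One
#' prediction is scored per pseudo-trial (no bin augmentation: bin votes are
#' correlated within a trial, and the windowed n is already the quantity the
#' binomial test should see). A trailing three-window moving average is
#' reported alongside the raw accuracies, and the Spearman rank correlation
#' between window index and raw accuracy summarizes learning.
#'
#' @param pt an \code{\link{build_pseudotrials}} object.
#' @param trial_window trials per sliding window (10 for the tuned-cell
#'   analysis, 4 for the all-cells supplement).
#' @param step window increment in trials (default 1).
#' @param accuracy_window seconds relative to odor onset (default
#'   \code{c(0.2, 0.7)}).
#' @param method,lambda classifier settings as in
#'   \code{\link{decode_over_time}}.
#' @param smooth_k trailing moving-average width over windows (default 3).
#' @param alpha significance level for per-window flags.
#' @return list of class \code{unblk_trial_decoding}: data.frame
#'   \code{windows} (\code{window_index}, \code{first_trial},
#'   \code{accuracy}, \code{n}, \code{p}, \code{significant}), smoothed
#'   accuracies, \code{rho}, \code{rho_p}, \code{chance}.
#' @export
decode_over_trials <- function(pt, trial_window = 10L, step = 1L,
                               accuracy_window = c(0.2, 0.7),
                               method = c("lda", "multinom"), lambda = 0.5,
                               smooth_k = 3L, alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(pt, "unblk_pseudotrials"))
  y <- pt$y
  n_per <- pt$n_per_class
  if (trial_window > n_per) stop("trial_window exceeds trials per class")
  chance <- 1 / nlevels(y)
  in_win <- pt$bin_starts >= accuracy_window[1] - 1e-9 &
    pt$bin_starts + pt$bin_width_s <= accuracy_window[2] + 1e-9
  ## per-trial feature: each unit's mean rate across the accuracy window
  feat <- apply(pt$X[, in_win, , drop = FALSE], c(1, 3), mean)
  ord <- rep(seq_len(n_per), times = nlevels(y))   # within-type index per row
  starts <- seq(1L, n_per - trial_window + 1L, by = step)
  rows <- lapply(starts, function(s0)
    which(ord >= s0 & ord < s0 + trial_window))
  acc <- n_used <- p <- numeric(length(starts))
  for (w in seq_along(starts)) {
    idx <- rows[[w]]
    pred <- loo_predict(feat[idx, , drop = FALSE], y[idx], method = method,
                        lambda = lambda)
    k <- sum(pred == as.character(y[idx]))
    n_used[w] <- length(idx)
    acc[w] <- k / length(idx)
    p[w] <- binomial_significance(k, length(idx), chance)
  }
  windows <- data.frame(window_index = seq_along(starts),
                        first_trial = starts, accuracy = acc, n = n_used,
                        p = p, significant = p < alpha)
  smoothed <- if (smooth_k > 1 && length(acc) >= smooth_k)
    smooth_bins(acc, smooth_k) else acc
  rho <- rho_p <- NA_real_
  if (length(acc) >= 3 && stats::sd(acc) > 0) {
    ct <- suppressWarnings(stats::cor.test(seq_along(acc), acc,
                                           method = "spearman",
                                           exact = FALSE))
    rho <- unname(ct$estimate)
    rho_p <- ct$p.value
  }
  structure(list(windows = windows, smoothed_accuracy = smoothed,
                 smooth_k = smooth_k, rho = rho, rho_p = rho_p,
                 chance = chance, trial_window = trial_window,
                 accuracy_window = accuracy_window, method = method),
            class = "unblk_trial_decoding")
}

#' @export
print.unblk_trial_decoding <- function(x, ...) {
  cat(sprintf(paste0("<unblk_trial_decoding> %d windows of %d trials; ",
                     "%d/%d significant; rho = %.2f\n"),
              nrow(x$windows), x$trial_window, sum(x$windows$significant),
              nrow(x$windows), x$rho))
  invisible(x)
}

#' Label-shuffle control for a pseudo-ensemble
#'
#' Recomputes the accuracy-window decoding accuracy with class labels
#' permuted, as a chance calibration.
#'
#' @param pt a pseudo-trial object.
#' @param n_shuffles number of label permutations (default 100).
#' @param accuracy_window,method,lambda as in \code{\link{decode_over_time}}.
#' @return numeric vector of shuffled window accuracies.
#' @export
shuffle_control <- function(pt, n_shuffles = 100L,
                            accuracy_window = c(0.2, 0.7),
                            method = c("lda", "multinom"), lambda = 0.5) {
  method <- match.arg(method)
  in_win <- pt$bin_starts >= accuracy_window[1] - 1e-9 &
    pt$bin_starts + pt$bin_width_s <= accuracy_window[2] + 1e-9
  feat <- apply(pt$X[, in_win, , drop = FALSE], c(1, 3), mean)
  vapply(seq_len(n_shuffles), function(i) {
    ys <- sample(pt$y)
    mean(loo_predict(feat, ys, method = method, lambda = lambda) ==
           as.character(ys))
  }, 0)
}
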