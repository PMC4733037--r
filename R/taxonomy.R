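# Functional taxonomy of odor-responsive units: per-odor t-test screens,
# the operational value-coding definition, category assignment, the
# chi-squared uniformity test on tuned-cell counts, and latency correlations.

#' Screen units for phasic odor responses
#'
#' Units with a mean baseline (ITI) rate below \code{max_baseline} are
#' screened per odor with a Welch two-sample t-test comparing trialwise
#' odor-epoch rates against trialwise ITI rates. The screen looks for
#' increases in firing, so the default test is one-sided
#' (\code{alternative = "greater"}); a unit is significant for an odor when
#' p < \code{alpha} and the direction is an increase. No multiple-comparison
#' correction is applied.
#'
#' @param session an \code{unblk_session}, or a precomputed
#'   \code{\link{epoch_stats}} data.frame (already filtered as desired).
#' @param alpha per-test significance level (default 0.01).
#' @param max_baseline units with baseline mean >= this rate (Hz) are flagged
#'   ineligible (default 10).
#' @param min_trial within-type ordinal of the first analyzed trial
#'   (default 8).
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @param baseline \code{"all"} (default): the ITI sample pools all analyzed
#'   trials, the ITI being cue-independent; \code{"same"}: only the ITI rates
#'   of that odor's trials.
#' @param paired use a paired (one-sample on normalized firing) test instead
#'   of the two-sample screen; requires \code{baseline = "same"}.
#' @param epochs epoch definitions passed to \code{\link{epoch_stats}}.
#' @param min_n minimum analyzable trials per odor (default 2); units below
#'   it are flagged unanalyzable, never silently dropped.
#' @return data.frame with one row per unit x odor: \code{unit_id},
#'   \code{odor}, \code{n_trials}, \code{t}, \code{p}, \code{direction},
#'   \code{significant}, plus unit-level \code{baseline_mean},
#'   \code{eligible}, \code{analyzable}.
#' @export
screen_responsive <- function(session, alpha = 0.01, max_baseline = 10,
                              min_trial = 8L,
                              alternative = c("greater", "two.sided"),
                              baseline = c("all", "same"), paired = FALSE,
                              epochs = default_epochs(), min_n = 2L) {
  alternative <- match.arg(alternative)
  baseline <- match.arg(baseline)
  if (paired && baseline != "same")
    stop("paired screen requires baseline = 'same'")
  if (inherits(session, "unblk_session")) {
    stats_df <- epoch_stats(session, epochs = epochs, min_trial = min_trial)
    odors <- TRIAL_TYPES[[session$task_variant]]
  } else {
    stats_df <- session
    odors <- unique(stats_df$trial_type)
  }
  units <- unique(stats_df$unit_id)
  rows <- vector("list", length(units))
  for (i in seq_along(units)) {
    su <- stats_df[stats_df$unit_id == units[i], ]
    baseline_mean <- mean(su$iti_rate)
    eligible <- baseline_mean < max_baseline
    per_odor <- lapply(odors, function(od) {
      so <- su[su$trial_type == od, ]
      iti_sample <- if (baseline == "all") su$iti_rate else so$iti_rate
      n <- nrow(so)
      if (n < min_n || (!paired && length(iti_sample) < min_n)) {
        return(data.frame(unit_id = units[i], odor = od, n_trials = n,
                          t = NA_real_, p = NA_real_,
                          direction = NA_character_, significant = NA,
                          stringsAsFactors = FALSE))
      }
      tt <- if (paired) {
        tryCatch(stats::t.test(so$normalized, mu = 0,
                               alternative = alternative),
                 error = function(e) NULL)
      } else {
        tryCatch(stats::t.test(so$epoch_rate, iti_sample,
                               alternative = alternative),
                 error = function(e) NULL)
      }
      if (is.null(tt)) {  # zero variance in both samples
        d <- mean(so$epoch_rate) - mean(iti_sample)
        return(data.frame(unit_id = units[i], odor = od, n_trials = n,
                          t = NA_real_, p = NA_real_,
                          direction = if (d >= 0) "up" else "down",
                          significant = FALSE, stringsAsFactors = FALSE))
      }
      d <- if (paired) mean(so$normalized) else
        mean(so$epoch_rate) - mean(iti_sample)
      direction <- if (d >= 0) "up" else "down"
      data.frame(unit_id = units[i], odor = od, n_trials = n,
                 t = unname(tt$statistic), p = tt$p.value,
                 direction = direction,
                 significant = tt$p.value < alpha && direction == "up",
                 stringsAsFactors = FALSE)
    })
    u <- do.call(rbind, per_odor)
    u$baseline_mean <- baseline_mean
    u$eligible <- eligible
    u$analyzable <- !any(is.na(u$significant))
    rows[[i]] <- u
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit_id = character(0), odor = character(0),
                      n_trials = integer(0), t = numeric(0), p = numeric(0),
                      direction = character(0), significant = logical(0),
                      baseline_mean = numeric(0), eligible = logical(0),
                      analyzable = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "odors") <- odors
  out
}

#' Test the operational value-coding definition per unit
#'
#' A unit is value-coding when it shows an excitatory response to at least one
#' odor (per the responsiveness screen) and its odor-epoch firing is
#' significantly greater on upshift than blocked trials and significantly
#' lower on downshift than blocked trials (between-trial-type t-tests,
#' directional, p < \code{alpha}).
#'
#' @param session an \code{unblk_session} or \code{\link{epoch_stats}} output.
#' @param screen output of \code{\link{screen_responsive}} for the same data;
#'   computed if missing.
#' @param alpha significance level (default 0.01).
#' @param min_trial first analyzed within-type trial (default 8).
#' @param epochs epoch definitions.
#' @return data.frame \code{unit_id}, \code{p_up_vs_same},
#'   \code{p_down_vs_same}, \code{any_excitatory}, \code{value_coding}.
#' @export
is_value_coding <- function(session, screen = NULL, alpha = 0.01,
                            min_trial = 8L, epochs = default_epochs()) {
  if (inherits(session, "unblk_session")) {
    stats_df <- epoch_stats(session, epochs = epochs, min_trial = min_trial)
    variant <- session$task_variant
  } else {
    stats_df <- session
    variant <- if ("upshift" %in% stats_df$trial_type) "blocking" else
      "control"
  }
  if (is.null(screen))
    screen <- screen_responsive(stats_df, alpha = alpha)
  more <- if (variant == "blocking") "upshift" else "large"
  same <- if (variant == "blocking") "blocked" else "medium"
  less <- if (variant == "blocking") "downshift" else "small"
  units <- unique(stats_df$unit_id)
  if (!length(units))
    return(data.frame(unit_id = character(0), p_up_vs_same = numeric(0),
                      p_down_vs_same = numeric(0), any_excitatory = logical(0),
                      value_coding = logical(0), stringsAsFactors = FALSE))
  out <- lapply(units, function(uid) {
    su <- stats_df[stats_df$unit_id == uid, ]
    up <- su$epoch_rate[su$trial_type == more]
    bl <- su$epoch_rate[su$trial_type == same]
    dn <- su$epoch_rate[su$trial_type == less]
    p_up <- p_dn <- NA_real_
    if (length(up) >= 2 && length(bl) >= 2)
      p_up <- tryCatch(stats::t.test(up, bl,
                                     alternative = "greater")$p.value,
                       error = function(e) NA_real_)
    if (length(dn) >= 2 && length(bl) >= 2)
      p_dn <- tryCatch(stats::t.test(dn, bl, alternative = "less")$p.value,
                       error = function(e) NA_real_)
    any_exc <- any(screen$significant[screen$unit_id == uid], na.rm = TRUE)
    data.frame(unit_id = uid, p_up_vs_same = p_up, p_down_vs_same = p_dn,
               any_excitatory = any_exc,
               value_coding = isTRUE(any_exc) && !is.na(p_up) &&
                 !is.na(p_dn) && p_up < alpha && p_dn < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign a functional category to every screened unit
#'
#' Decision order (first match wins): no significant odor -> nonresponsive;
#' all four odors significant and not value-coding -> sensory (excluded from
#' the associative populations); value-coding -> value; only the initial odor
#' -> initial_only; exactly one novel odor (initial not) -> that cue's tuned
#' category; upshift and downshift but not blocked (initial not) ->
#' predictive; all three novel odors (initial not) -> salience; anything else
#' -> other_mixed. Units failing the baseline-rate eligibility screen are
#' labelled \code{ineligible}; units with unanalyzable odors
#' \code{unanalyzable}.
#'
#' @param screen output of \code{\link{screen_responsive}}.
#' @param value output of \code{\link{is_value_coding}} for the same units.
#' @return data.frame \code{unit_id}, \code{category}, \code{provenance}.
#' @export
classify_units <- function(screen, value) {
  odors <- attr(screen, "odors")
  if (is.null(odors)) odors <- unique(screen$odor)
  init <- odors[1]
  variant <- if ("upshift" %in% odors) "blocking" else "control"
  more <- if (variant == "blocking") "upshift" else "large"
  same <- if (variant == "blocking") "blocked" else "medium"
  less <- if (variant == "blocking") "downshift" else "small"
  units <- unique(screen$unit_id)
  if (!length(units))
    return(data.frame(unit_id = character(0), category = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  vmap <- stats::setNames(value$value_coding, value$unit_id)
  out <- lapply(units, function(uid) {
    su <- screen[screen$unit_id == uid, ]
    sig <- stats::setNames(su$significant, su$odor)[odors]
    mk <- function(category, why)
      data.frame(unit_id = uid, category = category, provenance = why,
                 stringsAsFactors = FALSE)
    if (!su$eligible[1])
      return(mk("ineligible", sprintf("baseline %.1f Hz >= cutoff",
                                      su$baseline_mean[1])))
    if (any(is.na(sig))) return(mk("unanalyzable", "insufficient trials"))
    vflag <- isTRUE(unname(vmap[uid]))
    novel_sig <- sig[c(less, same, more)]
    tag <- paste(names(sig)[sig], collapse = "+")
    if (!any(sig)) return(mk("nonresponsive", "no significant odor"))
    if (all(sig) && !vflag) return(mk("sensory", "all four odors, not value"))
    if (vflag) return(mk("value", "pairwise value definition"))
    if (sig[init] && !any(novel_sig))
      return(mk("initial_only", "initial odor only"))
    if (sum(novel_sig) == 1 && !sig[init]) {
      ty <- names(novel_sig)[novel_sig]
      nm <- if (variant == "blocking") paste0(ty, "_only")
            else paste0(ty, "_only")
      return(mk(nm, paste0("tuned: ", tag)))
    }
    if (sig[more] && sig[less] && !sig[same] && !sig[init])
      return(mk("predictive", paste0("change cues: ", tag)))
    if (all(novel_sig) && !sig[init])
      return(mk("salience", paste0("all novel: ", tag)))
    mk("other_mixed", paste0("mixed: ", tag))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify every unit of a session (convenience wrapper)
#'
#' Runs \code{\link{screen_responsive}}, \code{\link{is_value_coding}} and
#' \code{\link{classify_units}} with shared settings.
#'
#' @inheritParams screen_responsive
#' @return list with \code{screen}, \code{value}, \code{taxonomy}.
#' @export
classify_session <- function(session, alpha = 0.01, max_baseline = 10,
                             min_trial = 8L, epochs = default_epochs(), ...) {
  stats_df <- epoch_stats(session, epochs = epochs, min_trial = min_trial)
  attr(stats_df, "variant") <- session$task_variant
  screen <- screen_responsive(stats_df, alpha = alpha,
                              max_baseline = max_baseline, ...)
  attr(screen, "odors") <- TRIAL_TYPES[[session$task_variant]]
  value <- is_value_coding(stats_df, screen = screen, alpha = alpha)
  list(screen = screen, value = value,
       taxonomy = classify_units(screen, value))
}

#' Chi-squared uniformity test on tuned-cell counts
#'
#' Goodness-of-fit of the observed counts of cue-tuned cells against a uniform
#' expectation across the novel cues (df = number of cues - 1). For the
#' published counts (19, 16, 16) the statistic is 0.353, p = 0.84.
#'
#' @param counts nonnegative integer vector (one count per tuned cue).
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
category_uniformity_test <- function(counts) {
  stopifnot(length(counts) >= 2, all(counts >= 0))
  ht <- suppressWarnings(stats::chisq.test(counts))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Correlate trialwise odor-epoch firing with behavioral latency
#'
#' Pearson correlation, per unit and trial type, between the odor-epoch firing
#' rate and the response latency (well entry minus odor offset) on the same
#' trial, computed over a trial range (the day-2 analysis uses trials 5-30).
#'
#' @param session an \code{unblk_session}.
#' @param trials within-type trial ordinals to analyze (default \code{5:30}).
#' @param epochs epoch definitions.
#' @param min_n minimum usable trials (default 3); below it the unit x type
#'   is flagged unanalyzable.
#' @return data.frame \code{unit_id}, \code{trial_type}, \code{n}, \code{r},
#'   \code{p}, \code{analyzable}.
#' @export
latency_firing_correlation <- function(session, trials = 5:30,
                                       epochs = default_epochs(),
                                       min_n = 3L) {
  stats_df <- epoch_stats(session, epochs = epochs, min_trial = 1L)
  tr <- session$trials
  lat <- stats::setNames(tr$t_well_entry - tr$t_odor_off, tr$trial_index)
  stats_df$latency <- lat[as.character(stats_df$trial_index)]
  stats_df <- stats_df[stats_df$type_ordinal %in% trials &
                         !is.na(stats_df$latency), ]
  if (!nrow(stats_df))
    return(data.frame(unit_id = character(0), trial_type = character(0),
                      n = integer(0), r = numeric(0), p = numeric(0),
                      analyzable = logical(0), stringsAsFactors = FALSE))
  grp <- split(stats_df, list(stats_df$unit_id, stats_df$trial_type),
               drop = TRUE)
  out <- lapply(grp, function(g) {
    n <- nrow(g)
    if (n < min_n || stats::sd(g$epoch_rate) == 0 ||
        stats::sd(g$latency) == 0)
      return(data.frame(unit_id = g$unit_id[1], trial_type = g$trial_type[1],
                        n = n, r = NA_real_, p = NA_real_, analyzable = FALSE,
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(g$epoch_rate, g$latency, method = "pearson")
    data.frame(unit_id = g$unit_id[1], trial_type = g$trial_type[1], n = n,
               r = unname(ct$estimate), p = ct$p.value, analyzable = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
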