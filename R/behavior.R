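# Behavioral analyses: probe-test time in the reward well and training
# response latencies, with factorial ANOVAs and planned comparisons.

#' Assemble the long-format behavior table for a study
#'
#' Latency is well entry minus odor offset on completed learning-day trials;
#' time in well is well entry to well exit on probe extinction trials
#' (cumulative occupancy of the reward well while reward is withheld).
#'
#' @param study output of \code{\link{generate_study}}, or a list of rounds
#'   each holding \code{day1}, \code{day2}, \code{probe} sessions plus
#'   \code{rat_id}/\code{round_id}.
#' @return data.frame with columns \code{rat}, \code{round}, \code{day},
#'   \code{trial_type}, \code{trial_index} (within-type ordinal; for probe
#'   rows the extinction-presentation ordinal), \code{measure}
#'   (\code{"latency_s"} or \code{"time_in_well_s"}), \code{value}.
#' @export
behavior_table <- function(study) {
  rows <- list()
  for (r in study) {
    for (day in c("day1", "day2")) {
      s <- r[[day]]
      if (is.null(s)) next
      tr <- s$trials[s$trials$completed & !is.na(s$trials$t_well_entry), ]
      ord <- stats::ave(seq_len(nrow(tr)), tr$trial_type, FUN = seq_along)
      rows[[length(rows) + 1L]] <- data.frame(
        rat = r$rat_id, round = r$round_id,
        day = if (day == "day1") "1" else "2",
        trial_type = tr$trial_type, trial_index = ord,
        measure = "latency_s", value = tr$t_well_entry - tr$t_odor_off,
        stringsAsFactors = FALSE)
    }
    s <- r$probe
    if (!is.null(s)) {
      tr <- s$trials
      ext <- tr[is.na(tr$t_reward) & !is.na(tr$t_well_entry) &
                  !is.na(tr$t_well_exit), ]
      if (nrow(ext)) {
        ord <- stats::ave(seq_len(nrow(ext)), ext$trial_type,
                          FUN = seq_along)
        rows[[length(rows) + 1L]] <- data.frame(
          rat = r$rat_id, round = r$round_id, day = "probe",
          trial_type = ext$trial_type, trial_index = ord,
          measure = "time_in_well_s",
          value = ext$t_well_exit - ext$t_well_entry,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(rat = character(0), round = integer(0),
                      day = character(0), trial_type = character(0),
                      trial_index = integer(0), measure = character(0),
                      value = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## two-way factorial ANOVA with interaction; trials pooled as replicates.
## F is reported as 0 when an effect's sum of squares is exactly 0 (the
## all-equal degenerate input would otherwise give 0/0).
two_way_anova <- function(value, f1, f2, names_out) {
  f1 <- factor(f1); f2 <- factor(f2)
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    stop("need >= 2 levels per factor")
  cells <- table(f1, f2)
  if (any(cells == 0))
    stop("empty design cells: ",
         paste(which(cells == 0, arr.ind = TRUE)[, 1], collapse = ", "))
  if (length(value) <= nlevels(f1) * nlevels(f2))
    stop("no residual degrees of freedom: the design needs replicates ",
         "(pool more rats/rounds)")
  fit <- stats::aov(value ~ f1 * f2)
  tab <- summary(fit)[[1]]
  eff <- data.frame(
    term = c(names_out, paste(names_out, collapse = " x ")),
    df = tab[1:3, "Df"], df_resid = tab[4, "Df"],
    F = tab[1:3, "F value"], p = tab[1:3, "Pr(>F)"],
    stringsAsFactors = FALSE)
  zero <- !is.na(tab[1:3, "Sum Sq"]) & tab[1:3, "Sum Sq"] < 1e-12
  eff$F[zero] <- 0
  eff$p[zero] <- 1
  rownames(eff) <- NULL
  eff
}

#' Probe-test ANOVA: time in well by odor and trial
#'
#' Two-way factorial ANOVA (with interaction) on probe extinction
#' time-in-well with odor (the three novel cues) and trial (1-10) as factors,
#' trials pooled across rats and rounds as replicates (matching the
#' trial-level residual df of the published analysis). A per-rat-round
#' aggregation mode is available because trial-level pooling inflates df.
#'
#' @param table a \code{\link{behavior_table}}.
#' @param aggregate average to per-(rat, round, odor, trial) means before
#'   testing (default \code{FALSE}, i.e. trial-level pooling).
#' @return data.frame with one row per term: \code{term}, \code{df},
#'   \code{df_resid}, \code{F}, \code{p}.
#' @export
probe_anova <- function(table, aggregate = FALSE) {
  d <- table[table$measure == "time_in_well_s" & table$day == "probe", ]
  d <- d[d$trial_type != "initial", ]
  if (!nrow(d)) stop("no probe time-in-well rows in table")
  if (aggregate)
    d <- stats::aggregate(value ~ rat + round + trial_type + trial_index,
                          data = d, FUN = mean)
  two_way_anova(d$value, d$trial_type, d$trial_index, c("odor", "trial"))
}

#' Planned comparisons on probe time in well
#'
#' The cue predicting more reward is compared with the same-reward cue within
#' the first four-trial block, and the cue predicting less reward with the
#' same-reward cue across all trials; both are paired t-tests on
#' per-rat-round means.
#'
#' @param table a \code{\link{behavior_table}}.
#' @param block trial ordinals forming the early block (default \code{1:4}).
#' @return data.frame \code{contrast}, \code{n}, \code{estimate}, \code{t},
#'   \code{p}, \code{analyzable}.
#' @export
planned_block_comparisons <- function(table, block = 1:4) {
  d <- table[table$measure == "time_in_well_s" & table$day == "probe", ]
  types <- unique(d$trial_type)
  more <- intersect(c("upshift", "large"), types)[1]
  same <- intersect(c("blocked", "medium"), types)[1]
  less <- intersect(c("downshift", "small"), types)[1]
  one <- function(a, b, trials, label) {
    dd <- d[d$trial_type %in% c(a, b) & d$trial_index %in% trials, ]
    m <- stats::aggregate(value ~ rat + round + trial_type, data = dd,
                          FUN = mean)
    wide <- stats::reshape(m, idvar = c("rat", "round"),
                           timevar = "trial_type", direction = "wide")
    xa <- wide[[paste0("value.", a)]]
    xb <- wide[[paste0("value.", b)]]
    ok <- stats::complete.cases(xa, xb)
    if (sum(ok) < 2)
      return(data.frame(contrast = label, n = sum(ok), estimate = NA_real_,
                        t = NA_real_, p = NA_real_, analyzable = FALSE,
                        stringsAsFactors = FALSE))
    tt <- stats::t.test(xa[ok], xb[ok], paired = TRUE)
    data.frame(contrast = label, n = sum(ok),
               estimate = mean(xa[ok] - xb[ok]), t = unname(tt$statistic),
               p = tt$p.value, analyzable = TRUE, stringsAsFactors = FALSE)
  }
  rbind(
    one(more, same, block, sprintf("%s vs %s, trials %d-%d", more, same,
                                   min(block), max(block))),
    one(less, same, sort(unique(d$trial_index)),
        sprintf("%s vs %s, all trials", less, same)))
}

#' Learning-session latency ANOVA
#'
#' Two-way factorial ANOVA (with interaction) on response latencies during
#' the learning sessions with trial (within-type ordinal, 1-30 by default)
#' and day (1 vs 2) as factors, trials pooled across rats, rounds and cues as
#' replicates.
#'
#' @param table a \code{\link{behavior_table}}.
#' @param trials trial ordinals included (default \code{1:30}).
#' @param novel_only restrict to novel-cue trials (default \code{FALSE}: all
#'   four trial types).
#' @return data.frame as \code{\link{probe_anova}}.
#' @export
latency_anova <- function(table, trials = 1:30, novel_only = FALSE) {
  d <- table[table$measure == "latency_s" & table$day %in% c("1", "2") &
               table$trial_index %in% trials, ]
  if (novel_only) d <- d[d$trial_type != "initial", ]
  if (!nrow(d)) stop("no learning-day latency rows in table")
  two_way_anova(d$value, d$trial_index, d$day, c("trial", "day"))
}
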