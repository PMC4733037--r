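# Trial-by-trial sliding-window firing maps and one-tailed significance maps.

#' Trialwise sliding-window population map
#'
#' For each of the first \code{n_trials} trials of a type, computes per unit
#' the sliding-window firing rates moving away from novel odor onset, baseline
#' corrects them, and averages across units. The companion significance map
#' holds one-tailed p-values (increase over baseline) computed across units
#' for each (trial, window) cell.
#'
#' @param session an \code{unblk_session}.
#' @param trial_type trial type mapped (e.g. \code{"upshift"}).
#' @param unit_ids units to include (default: all); units lacking
#'   \code{n_trials} trials of the type are excluded and listed in
#'   \code{excluded}.
#' @param n_trials number of trials (from trial 1) shown (default 10).
#' @param window,step sliding-window width and increment in seconds
#'   (defaults 0.150 and 0.050).
#' @param span seconds relative to novel odor onset (default \code{c(0, 1)}).
#' @param normalization \code{"iti"} (default): subtract the same trial's ITI
#'   rate; \code{"initial"}: subtract the unit's same-window mean rate over
#'   the initial-odor trials shown.
#' @param epochs epoch definitions (for the ITI window).
#' @return object of class \code{unblk_heatmap}: list with \code{values} and
#'   \code{p} matrices (trial x window), \code{window_starts},
#'   \code{n_units}, \code{excluded}.
#' @export
trialwise_heatmap <- function(session, trial_type, unit_ids = NULL,
                              n_trials = 10L, window = 0.150, step = 0.050,
                              span = c(0, 1), normalization = c("iti",
                                                                "initial"),
                              epochs = default_epochs()) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(session, "unblk_session"))
  tr <- session$trials
  tr$type_ordinal <- stats::ave(seq_len(nrow(tr)), tr$trial_type,
                                FUN = seq_along)
  ## anchor: novel odor onset; on trials without a compound cue the novel
  ## window begins 200 ms into the odor period
  anchor_time <- ifelse(is.na(tr$t_novel_odor_on), tr$t_odor_on + 0.2,
                        tr$t_novel_odor_on)
  sel <- which(tr$trial_type == trial_type & tr$completed &
                 tr$type_ordinal <= n_trials)
  sel <- sel[order(tr$type_ordinal[sel])]
  if (length(sel) < n_trials)
    stop("session has only ", length(sel), " completed '", trial_type,
         "' trials; ", n_trials, " requested")
  init_type <- TRIAL_TYPES[[session$task_variant]][1]
  sel_init <- which(tr$trial_type == init_type & tr$completed &
                      tr$type_ordinal <= n_trials)
  units <- session$units
  if (!is.null(unit_ids))
    units <- Filter(function(u) u$unit_id %in% unit_ids, units)
  iti <- epochs$iti
  iti_dur <- iti$end_offset_s - iti$start_offset_s
  per_unit <- list()
  excluded <- character(0)
  for (u in units) {
    w <- sliding_window_rates(u$spikes, anchor_time[sel], window = window,
                              step = step, span = span)
    base <- if (normalization == "iti") {
      a <- tr[[iti$anchor_event]][sel]
      matrix(count_spikes(u$spikes, a + iti$start_offset_s,
                          a + iti$end_offset_s) / iti_dur,
             nrow = length(sel), ncol = ncol(w))
    } else {
      if (!length(sel_init)) {
        excluded <- c(excluded, u$unit_id)
        next
      }
      wi <- sliding_window_rates(u$spikes, anchor_time[sel_init],
                                 window = window, step = step, span = span)
      matrix(colMeans(wi), nrow = length(sel), ncol = ncol(w), byrow = TRUE)
    }
    per_unit[[u$unit_id]] <- w - base
  }
  if (!length(per_unit)) stop("no units available for the heat map")
  arr <- simplify2array(per_unit)  # trial x window x unit
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  values <- apply(arr, c(1, 2), mean)
  p <- apply(arr, c(1, 2), one_tailed_greater_p)
  ws <- attr(sliding_window_rates(numeric(0), numeric(0), window = window,
                                  step = step, span = span), "window_starts")
  structure(list(values = values, p = p, window_starts = ws,
                 n_units = length(per_unit), trial_type = trial_type,
                 normalization = normalization, excluded = excluded),
            class = "unblk_heatmap")
}

## one-sample one-tailed (greater) t-test p across units; degenerate
## zero-variance cells: significant by convention when the mean is positive
one_tailed_greater_p <- function(x) {
  if (length(x) < 2) return(NA_real_)
  if (stats::sd(x) == 0) return(if (mean(x) > 0) 0 else 1)
  stats::t.test(x, mu = 0, alternative = "greater")$p.value
}

#' Threshold a heat map's p-values into a binary significance map
#'
#' Both printed thresholds of the source analyses (p < 0.001 for the
#' upshift-population map, p < 0.01 for the tuned-cell maps) are ordinary
#' values of \code{alpha}. Zero-variance cells were assigned p = 0 (mean > 0)
#' or 1 at map construction, with a warning here when any occur.
#'
#' @param map an \code{unblk_heatmap}.
#' @param alpha one-tailed significance level.
#' @return logical matrix (trial x window).
#' @export
significance_map <- function(map, alpha = 0.01) {
  stopifnot(inherits(map, "unblk_heatmap"))
  if (any(map$p == 0, na.rm = TRUE))
    warning("zero-variance cells present; flagged significant when mean > 0")
  !is.na(map$p) & map$p < alpha
}

#' @export
print.unblk_heatmap <- function(x, ...) {
  cat(sprintf(paste0("<unblk_heatmap> %s, %d trials x %d windows, %d units",
                     " (%s-normalized)\n"),
              x$trial_type, nrow(x$values), ncol(x$values), x$n_units,
              x$normalization))
  invisible(x)
}
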