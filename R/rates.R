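# Peri-event firing statistics: ITI baseline, odor-epoch rates, normalized
# firing, binned PSTHs, sliding windows, and moving-average smoothing.
#
# All windows are half-open [start, end): a spike exactly at a boundary
# belongs to the later bin/epoch.

#' Define an analysis epoch relative to a trial event
#'
#' @param name epoch label.
#' @param anchor_event trial column holding the anchor timestamp (e.g.
#'   \code{"t_odor_on"}).
#' @param start_offset_s,end_offset_s window offsets in seconds relative to
#'   the anchor; the window is half-open \code{[start, end)}.
#' @return list of class \code{unblk_epoch}.
#' @export
epoch_definition <- function(name, anchor_event, start_offset_s,
                             end_offset_s) {
  if (end_offset_s <= start_offset_s) stop("epoch ", name, ": end <= start")
  if (!anchor_event %in% EVENT_COLS)
    stop("epoch ", name, ": unknown anchor event '", anchor_event, "'")
  structure(list(name = name, anchor_event = anchor_event,
                 start_offset_s = start_offset_s,
                 end_offset_s = end_offset_s),
            class = "unblk_epoch")
}

#' Default analysis epochs
#'
#' The ITI baseline is the 2 s preceding house-light onset. The default
#' odor-period window is 300-1300 ms after (initial) odor onset, which tracks
#' the novel odor's time in the port on compound trials; the alternative
#' convention, 1 s from novel odor onset itself (200-1200 ms after initial
#' onset), is available via \code{novel_epoch = "post_novel"}.
#'
#' @param novel_epoch \code{"post_initial"} (default) or \code{"post_novel"}.
#' @return named list of \code{\link{epoch_definition}}s (\code{iti},
#'   \code{odor}).
#' @export
default_epochs <- function(novel_epoch = c("post_initial", "post_novel")) {
  novel_epoch <- match.arg(novel_epoch)
  odor <- if (novel_epoch == "post_initial")
    epoch_definition("odor", "t_odor_on", 0.3, 1.3)
  else
    epoch_definition("odor", "t_odor_on", 0.2, 1.2)
  list(iti = epoch_definition("iti", "t_light_on", -2, 0), odor = odor)
}

## spike counts in half-open windows [starts, ends); vectorized over windows
count_spikes <- function(spikes, starts, ends) {
  findInterval(ends - 1e-9, spikes) - findInterval(starts - 1e-9, spikes)
}

#' Firing rate of one unit in an epoch of one trial
#'
#' @param spikes sorted spike timestamps (s).
#' @param trial one-row data.frame (a row of \code{session$trials}).
#' @param epoch an \code{\link{epoch_definition}}.
#' @return rate in Hz (spike count in the half-open window divided by window
#'   length), or \code{NA} if the anchor event is absent on this trial.
#' @export
epoch_rate <- function(spikes, trial, epoch) {
  anchor <- trial[[epoch$anchor_event]]
  if (is.na(anchor)) return(NA_real_)
  dur <- epoch$end_offset_s - epoch$start_offset_s
  count_spikes(spikes, anchor + epoch$start_offset_s,
               anchor + epoch$end_offset_s) / dur
}

#' Normalized firing: epoch rate minus ITI rate
#'
#' @param epoch_rate,iti_rate rates in Hz on the same trial.
#' @return exact difference in Hz (may be negative).
#' @export
normalized_firing <- function(epoch_rate, iti_rate) epoch_rate - iti_rate

#' Per-unit, per-trial epoch statistics for a session
#'
#' Computes the ITI baseline rate, the odor-epoch rate and their difference
#' (normalized firing) for every unit and analyzable trial. Incomplete trials
#' are excluded from rate analyses; trials whose anchor is absent are skipped
#' with a reason recorded in the \code{skipped} attribute.
#'
#' @param session an \code{unblk_session}.
#' @param epochs list with \code{iti} and \code{odor}
#'   \code{\link{epoch_definition}}s (see \code{\link{default_epochs}}).
#' @param min_trial keep trials whose within-type ordinal is >=
#'   \code{min_trial} (the convention of showing odor-period data beginning
#'   with the 8th trial corresponds to \code{min_trial = 8}); default 1 keeps
#'   all.
#' @param completed_only exclude trials flagged incomplete (default TRUE).
#' @return data.frame with columns \code{unit_id}, \code{trial_index},
#'   \code{trial_type}, \code{type_ordinal}, \code{iti_rate},
#'   \code{epoch_rate}, \code{normalized}.
#' @export
epoch_stats <- function(session, epochs = default_epochs(), min_trial = 1L,
                        completed_only = TRUE) {
  stopifnot(inherits(session, "unblk_session"))
  tr <- session$trials
  tr$type_ordinal <- stats::ave(seq_len(nrow(tr)), tr$trial_type,
                                FUN = seq_along)
  keep <- rep(TRUE, nrow(tr))
  if (completed_only) keep <- keep & tr$completed
  keep <- keep & tr$type_ordinal >= min_trial
  skipped <- data.frame(trial_index = integer(0), reason = character(0))
  for (ep in epochs[c("iti", "odor")]) {
    absent <- keep & is.na(tr[[ep$anchor_event]])
    if (any(absent))
      skipped <- rbind(skipped, data.frame(
        trial_index = tr$trial_index[absent],
        reason = paste0("anchor ", ep$anchor_event, " absent")))
    keep <- keep & !is.na(tr[[ep$anchor_event]])
  }
  tr <- tr[keep, , drop = FALSE]
  iti <- epochs$iti
  odor <- epochs$odor
  iti_dur <- iti$end_offset_s - iti$start_offset_s
  odor_dur <- odor$end_offset_s - odor$start_offset_s
  res <- lapply(session$units, function(u) {
    if (nrow(tr) == 0L)
      return(data.frame(unit_id = character(0), trial_index = integer(0),
                        trial_type = character(0), type_ordinal = integer(0),
                        iti_rate = numeric(0), epoch_rate = numeric(0),
                        normalized = numeric(0), stringsAsFactors = FALSE))
    s <- u$spikes
    a_iti <- tr[[iti$anchor_event]]
    a_od <- tr[[odor$anchor_event]]
    ir <- count_spikes(s, a_iti + iti$start_offset_s,
                       a_iti + iti$end_offset_s) / iti_dur
    or <- count_spikes(s, a_od + odor$start_offset_s,
                       a_od + odor$end_offset_s) / odor_dur
    data.frame(unit_id = u$unit_id, trial_index = tr$trial_index,
               trial_type = tr$trial_type, type_ordinal = tr$type_ordinal,
               iti_rate = ir, epoch_rate = or, normalized = or - ir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(unit_id = character(0), trial_index = integer(0),
                      trial_type = character(0), type_ordinal = integer(0),
                      iti_rate = numeric(0), epoch_rate = numeric(0),
                      normalized = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- unique(skipped)
  out
}

#' Peri-event time histogram (per-trial binned rates)
#'
#' Bins are half-open and a spike exactly on a boundary falls into the later
#' bin. The bin count is \code{floor(span / bin_width)}.
#'
#' @param spikes sorted spike timestamps (s).
#' @param anchors numeric vector of alignment times, one per trial.
#' @param bin_width_s bin width in seconds (default 0.05, i.e. 50 ms).
#' @param span numeric length-2: window around the anchor in seconds.
#' @return matrix (trial x bin) of rates in Hz; bin left edges (relative to
#'   the anchor) in \code{attr(, "bin_starts")}.
#' @export
psth <- function(spikes, anchors, bin_width_s = 0.05, span = c(-1, 2)) {
  n_bins <- floor((span[2] - span[1]) / bin_width_s + 1e-9)
  starts_rel <- span[1] + (seq_len(n_bins) - 1) * bin_width_s
  out <- matrix(0, nrow = length(anchors), ncol = n_bins)
  for (i in seq_along(anchors)) {
    st <- anchors[i] + starts_rel
    out[i, ] <- count_spikes(spikes, st, st + bin_width_s) / bin_width_s
  }
  attr(out, "bin_starts") <- starts_rel
  out
}

#' Sliding-window firing rates
#'
#' Overlapping windows of width \code{window} advanced by \code{step} across
#' \code{span}; window count is \code{floor((span - window)/step) + 1}.
#'
#' @param spikes sorted spike timestamps (s).
#' @param anchors alignment times, one per trial.
#' @param window window width in seconds (default 0.150).
#' @param step increment in seconds (default 0.050).
#' @param span numeric length-2 window around the anchor.
#' @return matrix (trial x window) of rates in Hz; window start offsets in
#'   \code{attr(, "window_starts")}.
#' @export
sliding_window_rates <- function(spikes, anchors, window = 0.150,
                                 step = 0.050, span = c(0, 1)) {
  span_len <- span[2] - span[1]
  if (span_len < window) stop("span shorter than window")
  n_win <- floor((span_len - window) / step + 1e-9) + 1L
  starts_rel <- span[1] + (seq_len(n_win) - 1) * step
  out <- matrix(0, nrow = length(anchors), ncol = n_win)
  for (i in seq_along(anchors)) {
    st <- anchors[i] + starts_rel
    out[i, ] <- count_spikes(spikes, st, st + window) / window
  }
  attr(out, "window_starts") <- starts_rel
  out
}

#' Trailing moving average over bins or trials
#'
#' Averages \code{k} consecutive values; the output is shortened to
#' \code{length(x) - k + 1} rather than padding edges. Used with \code{k = 4}
#' for 50-ms rate bins, \code{k = 3} for 100-ms decoding bins, and
#' \code{k = 3} for trial curves.
#'
#' @param x numeric vector, or a matrix smoothed along rows.
#' @param k window length in bins.
#' @return smoothed vector (length \code{n - k + 1}) or matrix.
#' @export
smooth_bins <- function(x, k) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, smooth_bins, k = k))
    if (ncol(x) - k + 1 == 1) out <- matrix(out, nrow = nrow(x))
    return(out)
  }
  n <- length(x)
  if (k < 1 || k > n) stop("k must lie in [1, length(x)]")
  cs <- cumsum(c(0, x))
  (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) / k
}
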