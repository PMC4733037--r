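# Session container, validation, and on-disk schema (session.json + spikes.csv).

#' @keywords internal
"_PACKAGE"

## Trial types by task variant. In the blocking variant the three novel odors
## are presented in compound after 200 ms of the pre-trained initial odor; in
## the control variant each cue is a single odor preceded by 200 ms clean air.
TRIAL_TYPES <- list(
  blocking = c("initial", "blocked", "upshift", "downshift"),
  control  = c("initial", "medium", "large", "small")
)

REWARD_SIZES <- c("none", "small", "medium", "large")

## All timestamps are session-relative seconds stored at 0.1 ms resolution.
TIME_RESOLUTION_S <- 1e-4

## Trial event columns in their required temporal order.
EVENT_COLS <- c(
  "t_light_on", "t_port_entry", "t_odor_on", "t_novel_odor_on",
  "t_odor_off", "t_well_entry", "t_reward", "t_well_exit"
)

TRIAL_COLS <- c("trial_index", "trial_type", EVENT_COLS, "reward_size",
                "completed")

#' Round timestamps to the session time resolution (0.1 ms)
#'
#' @param x numeric vector of times in seconds.
#' @return numeric vector on the 0.1 ms grid.
#' @export
round_time <- function(x) round(x / TIME_RESOLUTION_S) * TIME_RESOLUTION_S

#' Construct a spike-train record for one isolated unit
#'
#' @param unit_id,rat_id,session_id character identifiers.
#' @param day one of \code{"1"}, \code{"2"}, \code{"probe"}.
#' @param spikes numeric vector of spike timestamps in seconds (session clock).
#'   Rounded to 0.1 ms; must be sorted, non-negative and duplicate-free at that
#'   resolution.
#' @return a list of class \code{unblk_unit}.
#' @export
unit_recording <- function(unit_id, rat_id, session_id, day, spikes) {
  day <- as.character(day)
  if (!day %in% c("1", "2", "probe"))
    stop("unit ", unit_id, ": day must be one of '1', '2', 'probe'")
  spikes <- round_time(as.numeric(spikes))
  structure(
    list(unit_id = as.character(unit_id), rat_id = as.character(rat_id),
         session_id = as.character(session_id), day = day, spikes = spikes),
    class = "unblk_unit")
}

#' Construct a validated session object
#'
#' A session bundles the behavioral trial table with the spike trains of all
#' units recorded in that session.
#'
#' @param trials data.frame with columns \code{trial_index}, \code{trial_type},
#'   the event timestamp columns (\code{t_light_on}, \code{t_port_entry},
#'   \code{t_odor_on}, \code{t_novel_odor_on}, \code{t_odor_off},
#'   \code{t_well_entry}, \code{t_reward}, \code{t_well_exit}; \code{NA} where
#'   an event did not occur), \code{reward_size} and \code{completed}.
#' @param units list of \code{\link{unit_recording}} objects.
#' @param task_variant \code{"blocking"} or \code{"control"}.
#' @param metadata named list; \code{session_end} (seconds) is added if absent.
#' @param validate run \code{\link{validate_session}} (default \code{TRUE}).
#' @return object of class \code{unblk_session}.
#' @export
session <- function(trials, units = list(), task_variant = "blocking",
                    metadata = list(), validate = TRUE) {
  task_variant <- match.arg(task_variant, names(TRIAL_TYPES))
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  if (nrow(trials) == 0L && length(trials) == 0L)
    trials <- empty_trials()
  missing_cols <- setdiff(TRIAL_COLS, names(trials))
  if (length(missing_cols))
    stop("trials: missing column(s) ", paste(missing_cols, collapse = ", "))
  trials <- trials[TRIAL_COLS]
  for (col in EVENT_COLS) trials[[col]] <- round_time(as.numeric(trials[[col]]))
  trials$trial_index <- as.integer(trials$trial_index)
  trials$trial_type <- as.character(trials$trial_type)
  trials$reward_size <- as.character(trials$reward_size)
  trials$completed <- as.logical(trials$completed)
  rownames(trials) <- NULL
  if (is.null(metadata$session_end)) {
    last <- suppressWarnings(max(unlist(trials[EVENT_COLS]), na.rm = TRUE))
    metadata$session_end <- round_time(if (is.finite(last)) last + 2 else 0)
  }
  x <- structure(
    list(trials = trials, units = units, task_variant = task_variant,
         metadata = metadata),
    class = "unblk_session")
  if (validate) validate_session(x)
  x
}

empty_trials <- function() {
  df <- data.frame(trial_index = integer(0), trial_type = character(0),
                   stringsAsFactors = FALSE)
  for (col in EVENT_COLS) df[[col]] <- numeric(0)
  df$reward_size <- character(0)
  df$completed <- logical(0)
  df
}

#' @export
print.unblk_session <- function(x, ...) {
  cat(sprintf("<unblk_session> %s task: %d trials, %d units, end %.1f s\n",
              x$task_variant, nrow(x$trials), length(x$units),
              x$metadata$session_end))
  if (nrow(x$trials)) {
    tab <- table(x$trials$trial_type)
    cat("  trials:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Validate a session against the schema invariants
#'
#' Checks per-trial event ordering, the 1 s odor hold on completed cue trials,
#' the 200 ms initial-odor lead on compound trials, non-overlapping trials,
#' and per-unit spike-train invariants (sorted, non-negative, duplicate-free at
#' 0.1 ms, within the session). Errors name the offending trial/unit and field
#' in JSON-pointer style.
#'
#' @param x an \code{unblk_session}.
#' @return \code{TRUE} invisibly, or an error.
#' @export
validate_session <- function(x) {
  stopifnot(inherits(x, "unblk_session"))
  trials <- x$trials
  types <- TRIAL_TYPES[[x$task_variant]]
  bad_type <- which(!trials$trial_type %in% types)
  if (length(bad_type))
    stop("/trials/", bad_type[1], "/trial_type: unknown type '",
         trials$trial_type[bad_type[1]], "'")
  bad_rs <- which(!trials$reward_size %in% REWARD_SIZES)
  if (length(bad_rs))
    stop("/trials/", bad_rs[1], "/reward_size: unknown size '",
         trials$reward_size[bad_rs[1]], "'")
  prev_end <- -Inf
  for (i in seq_len(nrow(trials))) {
    tt <- unlist(trials[i, EVENT_COLS])
    present <- !is.na(tt)
    v <- tt[present]
    if (any(diff(v) <= 0)) {
      j <- which(diff(v) <= 0)[1]
      stop("/trials/", i, "/", names(v)[j + 1],
           ": timestamps not strictly increasing (",
           names(v)[j + 1], " <= ", names(v)[j], ")")
    }
    if (length(v) && v[1] < prev_end)
      stop("/trials/", i, "/t_light_on: overlaps previous trial")
    if (length(v)) prev_end <- v[length(v)]
    if (isTRUE(trials$completed[i]) &&
        !is.na(tt["t_odor_on"]) && !is.na(tt["t_odor_off"])) {
      if (abs((tt["t_odor_off"] - tt["t_odor_on"]) - 1.0) > 1e-6)
        stop("/trials/", i, "/t_odor_off: odor hold must be 1.0 s on ",
             "completed cue trials")
    }
    if (!is.na(tt["t_novel_odor_on"])) {
      if (x$task_variant == "control")
        stop("/trials/", i, "/t_novel_odor_on: control trials have no ",
             "compound cue")
      if (abs((tt["t_novel_odor_on"] - tt["t_odor_on"]) - 0.2) > 1e-6)
        stop("/trials/", i, "/t_novel_odor_on: initial-odor lead must be ",
             "0.2 s on compound trials")
    }
  }
  send <- x$metadata$session_end
  ids <- vapply(x$units, function(u) u$unit_id, "")
  if (anyDuplicated(ids))
    stop("/units: duplicated unit_id '", ids[duplicated(ids)][1], "'")
  for (k in seq_along(x$units)) {
    u <- x$units[[k]]
    if (!inherits(u, "unblk_unit"))
      stop("/units/", k, ": not a unit_recording")
    s <- u$spikes
    if (length(s)) {
      if (any(s < 0))
        stop("/units/", k, "/spikes: negative timestamp (unit ", u$unit_id, ")")
      if (is.unsorted(s, strictly = TRUE))
        stop("/units/", k, "/spikes: unsorted or duplicated at 0.1 ms ",
             "resolution (unit ", u$unit_id, ")")
      if (!is.null(send) && s[length(s)] > send + 1e-9)
        stop("/units/", k, "/spikes: spike beyond session_end (unit ",
             u$unit_id, ")")
    }
  }
  invisible(TRUE)
}

#' Write a session to a directory (session.json + spikes.csv)
#'
#' @param x an \code{unblk_session} (validated before writing).
#' @param path directory to create/overwrite files in.
#' @return \code{path}, invisibly.
#' @export
write_session <- function(x, path) {
  validate_session(x)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  units_meta <- lapply(x$units, function(u)
    list(unit_id = u$unit_id, rat_id = u$rat_id, session_id = u$session_id,
         day = u$day, n_spikes = length(u$spikes)))
  obj <- list(schema = "unblockr-session-1",
              task_variant = x$task_variant,
              metadata = x$metadata,
              trials = x$trials,
              units = units_meta)
  jsonlite::write_json(obj, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = FALSE)
  sp <- data.frame(
    unit_id = rep(vapply(x$units, `[[`, "", "unit_id"),
                  vapply(x$units, function(u) length(u$spikes), 0L)),
    timestamp_s = unlist(lapply(x$units, `[[`, "spikes")),
    stringsAsFactors = FALSE)
  if (nrow(sp) == 0L)
    sp <- data.frame(unit_id = character(0), timestamp_s = numeric(0))
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and validate a session written by \code{\link{write_session}}
#'
#' Malformed files are rejected with an error locating the problem; nothing is
#' silently coerced.
#'
#' @param path directory containing \code{session.json} and \code{spikes.csv}.
#' @return an \code{unblk_session}.
#' @export
read_session <- function(path) {
  jpath <- file.path(path, "session.json")
  if (!file.exists(jpath)) stop("no session.json under ", path)
  obj <- jsonlite::fromJSON(jpath, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  if (!identical(obj$schema, "unblockr-session-1"))
    stop("/schema: not an unblockr session file")
  trials <- obj$trials
  if (is.null(trials) || (is.list(trials) && !is.data.frame(trials) &&
                          length(trials) == 0L)) {
    trials <- empty_trials()
  } else {
    trials <- as.data.frame(trials, stringsAsFactors = FALSE)
    missing_cols <- setdiff(TRIAL_COLS, names(trials))
    if (length(missing_cols))
      stop("/trials: missing field '", missing_cols[1], "'")
  }
  umeta <- obj$units
  units <- list()
  if (length(umeta)) {
    umeta <- as.data.frame(umeta, stringsAsFactors = FALSE)
    cpath <- file.path(path, "spikes.csv")
    if (!file.exists(cpath)) stop("no spikes.csv under ", path)
    sp <- utils::read.csv(cpath, stringsAsFactors = FALSE,
                          colClasses = c(unit_id = "character",
                                         timestamp_s = "numeric"))
    for (k in seq_len(nrow(umeta))) {
      s <- sp$timestamp_s[sp$unit_id == umeta$unit_id[k]]
      if (length(s) && is.unsorted(s, strictly = TRUE))
        stop("/units/", k, "/spikes: unsorted spike timestamps in spikes.csv")
      units[[k]] <- unit_recording(umeta$unit_id[k], umeta$rat_id[k],
                                   umeta$session_id[k], umeta$day[k], s)
    }
  }
  metadata <- obj$metadata
  if (is.null(metadata)) metadata <- list()
  session(trials, units, task_variant = obj$task_variant, metadata = metadata)
}
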