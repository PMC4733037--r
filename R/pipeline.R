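# End-to-end orchestration: simulate -> rates -> classify -> heatmap ->
# decode -> behavior -> report.

#' Pipeline configuration
#'
#' Bundles the generator configuration with the analysis settings so one
#' object (and one master seed) determines every pipeline output.
#'
#' @param generator an \code{\link{generator_config}}.
#' @param n_rounds rounds of unblocking to simulate.
#' @param alpha screen/test significance level (default 0.01).
#' @param heatmap_alpha significance-map threshold (default 0.01).
#' @param min_trial first analyzed within-type trial (default 8).
#' @param epochs epoch definitions (see \code{\link{default_epochs}}).
#' @param decoder list: \code{method}, \code{lambda},
#'   \code{accuracy_window}, \code{trial_window}.
#' @param seed master seed; per-stage and per-round seeds derive from it.
#' @return list of class \code{unblk_pipeline_config}.
#' @export
pipeline_config <- function(generator = generator_config(),
                            n_rounds = 1L, alpha = 0.01,
                            heatmap_alpha = 0.01, min_trial = 8L,
                            epochs = default_epochs(),
                            decoder = list(method = "lda", lambda = 0.5,
                                           accuracy_window = c(0.2, 0.7),
                                           trial_window = 10L),
                            seed = generator$seed) {
  structure(list(generator = generator, n_rounds = as.integer(n_rounds),
                 alpha = alpha, heatmap_alpha = heatmap_alpha,
                 min_trial = as.integer(min_trial), epochs = epochs,
                 decoder = decoder, seed = as.integer(seed)),
            class = "unblk_pipeline_config")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Simulates the study, writes session files (when \code{out_dir} is given),
#' computes epoch statistics, classifies every unit-day, tests tuned-count
#' uniformity, builds the upshift heat map, decodes trial type from the tuned
#' cells on each learning day, runs the behavioral analyses, and compares the
#' taxonomy with the generator's ground truth. Bit-identical outputs for
#' identical config and seed.
#'
#' @param config an \code{\link{pipeline_config}}.
#' @param out_dir optional directory; session files, stage CSVs and
#'   \code{report.json} are written beneath it.
#' @return report list with \code{category_counts}, \code{uniformity},
#'   \code{confusion}, \code{decoding}, \code{behavior}, \code{log}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "unblk_pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  study <- generate_study(config$generator, config$n_rounds,
                          seed = config$seed)
  note("simulated %d round(s), %d units each", length(study),
       nrow(study[[1]]$ground_truth))
  if (!is.null(out_dir)) {
    for (r in study)
      for (d in c("day1", "day2", "probe"))
        write_session(r[[d]], file.path(out_dir, sprintf("round%03d_%s",
                                                         r$round_id, d)))
  }

  variant <- config$generator$task_variant
  tuned_cats <- if (variant == "blocking")
    c("upshift_only", "downshift_only", "blocked_only")
  else c("large_only", "medium_only", "small_only")

  ## taxonomy per unit-day across all rounds
  tax_rows <- list()
  for (r in study) {
    for (d in c("day1", "day2")) {
      cl <- classify_session(r[[d]], alpha = config$alpha,
                             min_trial = config$min_trial,
                             epochs = config$epochs)
      tx <- cl$taxonomy
      tx$day <- rep(if (d == "day1") "1" else "2", nrow(tx))
      tx$round <- rep(r$round_id, nrow(tx))
      tx$truth <- r$ground_truth$category[match(tx$unit_id,
                                                r$ground_truth$unit_id)]
      tax_rows[[paste(r$round_id, d)]] <- tx
    }
  }
  taxonomy <- do.call(rbind, tax_rows)
  rownames(taxonomy) <- NULL
  n_total <- nrow(taxonomy)
  note("classified %d unit-days", n_total)

  counts <- table(taxonomy$category)
  tuned_counts <- vapply(tuned_cats, function(ct)
    sum(taxonomy$category == ct), 0L)
  uniformity <- if (all(tuned_counts == 0)) NULL else
    category_uniformity_test(tuned_counts)

  ## confusion vs ground truth on eligible, analyzable day-2 unit-days
  t2 <- taxonomy[taxonomy$day == "2" &
                   !taxonomy$category %in% c("ineligible", "unanalyzable"), ]
  confusion <- if (nrow(t2))
    table(truth = t2$truth, predicted = t2$category) else NULL

  ## heat map for the more-reward cue on day 1 of round 1
  more_cue <- if (variant == "blocking") "upshift" else "large"
  hm <- tryCatch(
    trialwise_heatmap(study[[1]]$day1, more_cue, epochs = config$epochs),
    error = function(e) {
      note("heatmap skipped: %s", conditionMessage(e)); NULL
    })

  ## decoding from day-2 tuned cells (and day 1 for the learning contrast)
  dec <- list()
  for (d in c("day1", "day2")) {
    dday <- if (d == "day1") "1" else "2"
    ids <- taxonomy$unit_id[taxonomy$day == dday &
                              taxonomy$category %in% tuned_cats]
    ids <- unique(ids)
    if (length(ids) < 2) {
      note("decoding %s skipped: %d tuned cells", d, length(ids))
      next
    }
    sess <- lapply(study, `[[`, d)
    pt <- build_pseudotrials(sess, unit_ids = ids)
    dec[[d]] <- list(
      over_time = decode_over_time(
        pt, accuracy_window = config$decoder$accuracy_window,
        method = config$decoder$method, lambda = config$decoder$lambda),
      over_trials = decode_over_trials(
        pt, trial_window = config$decoder$trial_window,
        accuracy_window = config$decoder$accuracy_window,
        method = config$decoder$method, lambda = config$decoder$lambda))
  }

  behav <- behavior_table(study)
  behavior <- list()
  if (nrow(behav)) {
    behavior$probe_anova <- tryCatch(probe_anova(behav),
                                     error = function(e) NULL)
    behavior$planned <- tryCatch(planned_block_comparisons(behav),
                                 error = function(e) NULL)
    behavior$latency_anova <- tryCatch(latency_anova(behav),
                                       error = function(e) NULL)
  }

  report <- list(config_hash = config_hash(config$generator),
                 seed = config$seed,
                 n_unit_days = n_total,
                 category_counts = as.list(counts),
                 tuned_counts = as.list(tuned_counts),
                 uniformity = uniformity,
                 confusion = confusion,
                 taxonomy = taxonomy,
                 heatmap = hm,
                 decoding = dec,
                 behavior = behavior,
                 log = log)
  if (!is.null(out_dir)) {
    utils::write.csv(taxonomy, file.path(out_dir, "taxonomy.csv"),
                     row.names = FALSE)
    if (nrow(behav))
      utils::write.csv(behav, file.path(out_dir, "behavior.csv"),
                       row.names = FALSE)
    summary_obj <- list(
      config_hash = report$config_hash, seed = report$seed,
      n_unit_days = n_total, category_counts = report$category_counts,
      tuned_counts = report$tuned_counts,
      uniformity = report$uniformity,
      confusion = if (!is.null(confusion))
        as.data.frame.matrix(confusion) else NULL,
      log = log)
    jsonlite::write_json(summary_obj, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Confusion-matrix diagonal recovery rates
#'
#' Fraction of units of each true category assigned to that category.
#'
#' @param confusion a truth x predicted contingency table.
#' @return named numeric vector of per-category recovery rates.
#' @export
confusion_diagonal <- function(confusion) {
  truths <- rownames(confusion)
  vapply(truths, function(tc) {
    n <- sum(confusion[tc, ])
    if (n == 0) return(NA_real_)
    hit <- if (tc %in% colnames(confusion)) confusion[tc, tc] else 0
    hit / n
  }, 0)
}
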