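# Observation-bout table handling and per-bout behavioural metrics.

# Event-level bout table schema (one row per perch event).
fp_event_cols <- function() {
  c("bout_id", "plot_id", "block_id", "treatment", "time_since_subsidy_min",
    "duration_min", "event_index", "height_cm", "dwell_min",
    "distance_to_seaweed_cm", "n_moves", "n_attacks", "stage", "marked_id")
}

#' Validate an event-level observation-bout table
#'
#' Checks the schema used throughout the pipeline: one row per perch
#' event, with bout-level fields (`duration_min`, `n_moves`, `n_attacks`,
#' covariates) repeated on each of the bout's rows. Heights are cm above
#' ground (ground = 0); dwell times are minutes. `distance_to_seaweed_cm`
#' and `marked_id` may be `NA` (e.g. control plots or unmarked animals).
#'
#' @param bouts A data.frame in the event-level schema.
#' @param max_duration_min Maximum allowed bout duration (default 20, the
#'   filming limit).
#' @param dwell_tol_min Slack allowed when checking that a bout's dwell
#'   times do not exceed its duration.
#' @return `bouts`, invisibly, if valid; otherwise an error.
#' @export
validate_bout_table <- function(bouts, max_duration_min = 20, dwell_tol_min = 0.5) {
  stopifnot(is.data.frame(bouts))
  missing_cols <- setdiff(fp_event_cols(), names(bouts))
  if (length(missing_cols) > 0)
    stop("bout table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(bouts) == 0) stop("bout table has no rows")
  if (!all(bouts$treatment %in% c("control", "treatment")))
    stop("`treatment` must be 'control' or 'treatment'")
  if (!all(bouts$stage %in% c("small", "large")))
    stop("`stage` must be 'small' or 'large'")
  if (any(!is.finite(bouts$height_cm)) || any(bouts$height_cm < 0))
    stop("`height_cm` must be finite and >= 0 (ground = 0)")
  if (any(!is.finite(bouts$dwell_min)) || any(bouts$dwell_min <= 0))
    stop("`dwell_min` must be finite and > 0")
  if (any(bouts$duration_min <= 0) || any(bouts$duration_min > max_duration_min))
    stop("`duration_min` must lie in (0, ", max_duration_min, "]")
  if (any(bouts$n_moves < 0) || any(bouts$n_attacks < 0))
    stop("move and attack counts must be >= 0")
  dw <- tapply(bouts$dwell_min, bouts$bout_id, sum)
  du <- tapply(bouts$duration_min, bouts$bout_id, function(x) x[1])
  bad <- names(dw)[dw > du[names(dw)] + dwell_tol_min]
  if (length(bad) > 0)
    stop("dwell times exceed bout duration for bout(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  per_bout <- c("plot_id", "block_id", "treatment", "time_since_subsidy_min",
                "duration_min", "n_moves", "n_attacks", "stage")
  for (col in per_bout) {
    k <- tapply(bouts[[col]], bouts$bout_id, function(x) length(unique(x)))
    if (any(k > 1))
      stop("bout-level column `", col, "` varies within a bout")
  }
  invisible(bouts)
}

#' Read an event-level bout table from CSV
#'
#' @param path Path to a UTF-8, comma-separated file with a header row in
#'   the event-level schema (see [validate_bout_table()]).
#' @param validate Validate the schema after reading (default `TRUE`).
#' @return A data.frame.
#' @examples
#' bouts <- read_bout_table(system.file("extdata", "example_bouts.csv",
#'                                      package = "foragepulse"))
#' head(summarize_bouts(bouts))
#' @export
read_bout_table <- function(path, validate = TRUE) {
  bouts <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (validate) validate_bout_table(bouts)
  bouts
}

#' Write an event-level bout table to CSV
#'
#' @param bouts A data.frame in the event-level schema.
#' @param path Output path.
#' @export
write_bout_table <- function(bouts, path) {
  utils::write.csv(bouts, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Time-weighted mean perch height
#'
#' The mean of perch heights weighted by the time spent at each height,
#' ground (0 cm) included: `sum(height * dwell) / sum(dwell)`. Weights are
#' normalized over the recorded dwells, so narration gaps shorter than the
#' bout do not bias the mean.
#'
#' @param height_cm Perch heights, cm (>= 0).
#' @param dwell_min Time spent at each height, minutes (> 0).
#' @return Time-weighted mean height, cm.
#' @examples
#' time_weighted_mean_perch(c(100, 0), c(10, 10))  # 50
#' @export
time_weighted_mean_perch <- function(height_cm, dwell_min) {
  if (length(height_cm) == 0) stop("bout has no perch events")
  if (length(height_cm) != length(dwell_min))
    stop("`height_cm` and `dwell_min` must have equal length")
  if (any(!is.finite(height_cm)) || any(height_cm < 0))
    stop("heights must be finite and >= 0")
  if (any(!is.finite(dwell_min)) || any(dwell_min <= 0))
    stop("dwell times must be finite and > 0")
  sum(height_cm * dwell_min) / sum(dwell_min)
}

#' Classify a bout's activity state from its movement rate
#'
#' A bout is classified ACTIVE when its movement rate strictly exceeds
#' 0.8 moves per minute (a break in the observed distribution of movement
#' rates); a rate of exactly 0.8 is INACTIVE.
#'
#' @param n_moves Number of moves in the bout.
#' @param duration_min Bout duration, minutes (> 0).
#' @param threshold Moves-per-minute threshold (default 0.8).
#' @return `"active"` or `"inactive"` (vectorized).
#' @examples
#' classify_activity(8, 10)  # exactly 0.8 -> "inactive"
#' classify_activity(9, 10)  # "active"
#' @export
classify_activity <- function(n_moves, duration_min, threshold = 0.8) {
  if (any(!is.finite(duration_min)) || any(duration_min <= 0))
    stop("`duration_min` must be finite and > 0")
  if (any(n_moves < 0)) stop("`n_moves` must be >= 0")
  ifelse(n_moves / duration_min > threshold, "active", "inactive")
}

#' Summarize an event-level bout table into per-bout metrics
#'
#' Collapses each bout's perch events into one row: time-weighted mean
#' perch height, movement and attack rates (counts per minute of
#' observation), activity classification, the dwell-weighted mean distance
#' to the subsidy (`NA` where distances were not recorded), and the
#' bout-level covariates.
#'
#' @param bouts A validated event-level bout table.
#' @param threshold Moves-per-minute activity threshold (default 0.8).
#' @return A data.frame with one row per bout: `bout_id`, `plot_id`,
#'   `block_id`, `treatment`, `time_since_subsidy_min`, `duration_min`,
#'   `stage`, `marked_id`, `n_moves`, `n_attacks`, `tw_mean_perch`,
#'   `move_rate`, `attack_rate`, `activity`, `mean_distance_cm`.
#' @export
summarize_bouts <- function(bouts, threshold = 0.8) {
  validate_bout_table(bouts)
  split_b <- split(bouts, bouts$bout_id)
  rows <- lapply(split_b, function(b) {
    b <- b[order(b$event_index), , drop = FALSE]
    dist <- if (all(is.na(b$distance_to_seaweed_cm))) NA_real_ else
      stats::weighted.mean(b$distance_to_seaweed_cm, b$dwell_min, na.rm = TRUE)
    data.frame(
      bout_id = b$bout_id[1], plot_id = b$plot_id[1], block_id = b$block_id[1],
      treatment = b$treatment[1],
      time_since_subsidy_min = b$time_since_subsidy_min[1],
      duration_min = b$duration_min[1], stage = b$stage[1],
      marked_id = b$marked_id[1],
      n_moves = b$n_moves[1], n_attacks = b$n_attacks[1],
      tw_mean_perch = time_weighted_mean_perch(b$height_cm, b$dwell_min),
      move_rate = b$n_moves[1] / b$duration_min[1],
      attack_rate = b$n_attacks[1] / b$duration_min[1],
      activity = classify_activity(b$n_moves[1], b$duration_min[1], threshold),
      mean_distance_cm = dist,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
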