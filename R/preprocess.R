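#' Remove whole blocks with low accuracy
#'
#' Drops every block whose mean accuracy falls strictly below `threshold`
#' (block accuracy is computed on the full block, before any trial-level
#' filtering). Participants whose blocks are all removed are thereby fully
#' excluded.
#'
#' @param data Trial data.frame with `participant`, `block` and `correct`
#'   (logical) columns.
#' @param threshold Minimum block accuracy to keep (default 0.75).
#' @return The filtered data.frame, with an attached `"exclusion_report"`
#'   attribute: list with `blocks_removed`, `trials_removed`,
#'   `fraction_removed` and `participants_excluded`.
#' @export
exclude_low_accuracy_blocks <- function(data, threshold = 0.75) {
  stopifnot(all(c("participant", "block", "correct") %in% names(data)))
  key <- interaction(data$participant, data$block, drop = TRUE)
  acc <- tapply(data$correct, key, mean)
  bad <- names(acc)[acc < threshold]
  drop <- key %in% bad
  out <- data[!drop, , drop = FALSE]
  before <- unique(data$participant)
  report <- list(
    blocks_removed = length(bad),
    trials_removed = sum(drop),
    fraction_removed = if (nrow(data)) sum(drop) / nrow(data) else 0,
    participants_excluded = setdiff(before, unique(out$participant)))
  attr(out, "exclusion_report") <- report
  out
}

#' Remove invalid trials (wrong digit report or over-long RT)
#'
#' Drops trials whose reported digit is not one of the two target digits
#' shown in the display, and trials with response times strictly longer
#' than `rt_max_ms`. Apply after [exclude_low_accuracy_blocks()], matching
#' the analysis sequencing (block filter first, then trial filters).
#'
#' @param data Trial data.frame with `correct` and `rt_ms` columns.
#' @param rt_max_ms RT cut-off in ms; trials with `rt_ms > rt_max_ms` are
#'   removed (default 5000, strict inequality, so a 5000 ms trial is
#'   kept).
#' @return Filtered data.frame with an `"exclusion_report"` attribute:
#'   list with `incorrect_removed`, `slow_removed`, `fraction_removed`.
#' @export
exclude_invalid_trials <- function(data, rt_max_ms = 5000) {
  stopifnot(all(c("correct", "rt_ms") %in% names(data)))
  incorrect <- !data$correct
  slow <- data$rt_ms > rt_max_ms
  keep <- !(incorrect | slow)
  out <- data[keep, , drop = FALSE]
  attr(out, "exclusion_report") <- list(
    incorrect_removed = sum(incorrect),
    slow_removed = sum(slow & !incorrect),
    fraction_removed = if (nrow(data)) mean(!keep) else 0)
  out
}

#' Remove anticipatory trials for fixation analyses
#'
#' Drops trials whose response time is strictly faster than `rt_min_ms`
#' (default 100 ms; a 100 ms trial is kept). Used only when preparing data
#' for fixation analyses.
#'
#' @param data Trial data.frame with an `rt_ms` column.
#' @param rt_min_ms Lower RT bound in ms.
#' @return Filtered data.frame with an `"exclusion_report"` attribute.
#' @export
exclude_fast_fixation_trials <- function(data, rt_min_ms = 100) {
  stopifnot("rt_ms" %in% names(data))
  fast <- data$rt_ms < rt_min_ms
  out <- data[!fast, , drop = FALSE]
  attr(out, "exclusion_report") <- list(
    fast_removed = sum(fast),
    fraction_removed = if (nrow(data)) mean(fast) else 0)
  out
}

#' Standard preprocessing chain for choice analyses
#'
#' Block-accuracy filter followed by the invalid-trial filter; optionally
#' restricts to main blocks first (practice blocks do not enter the
#' published-style fits).
#'
#' @param data Trial data.frame.
#' @param threshold,rt_max_ms Filter settings.
#' @param main_only Drop practice blocks first (default `TRUE`; needs a
#'   `block_type` column).
#' @return Filtered data.frame with a combined `"exclusion_report"`.
#' @export
preprocess_choices <- function(data, threshold = 0.75, rt_max_ms = 5000,
                               main_only = TRUE) {
  if (main_only && "block_type" %in% names(data))
    data <- data[data$block_type == "main", , drop = FALSE]
  a <- exclude_low_accuracy_blocks(data, threshold)
  b <- exclude_invalid_trials(a, rt_max_ms)
  attr(b, "exclusion_report") <- list(
    blocks = attr(a, "exclusion_report"),
    trials = attr(b, "exclusion_report"))
  b
}
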