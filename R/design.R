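#' Build the event schedule for one run
#'
#' Lays out the task blocks of a run with lead-in, between-block, and lead-out
#' fixation periods. The condition order is counterbalanced deterministically:
#' the base order (preferred-condition blocks first) is reversed whenever
#' `subject_index + run_index` is odd, so order varies systematically across
#' runs and participants without any randomness.
#'
#' @param task a [task_spec()].
#' @param subject_index,run_index 1-based indices driving counterbalancing.
#' @param run_duration_s optional fixed run length (s); an error is raised if
#'   the blocks do not fit.
#' @return data frame of events (`condition`, `onset_s`, `duration_s`) with
#'   attribute `run_duration_s` giving the total run length including the
#'   trailing fixation.
#' @export
make_design <- function(task, subject_index, run_index, run_duration_s = NULL) {
  stopifnot(inherits(task, "nirs_task"))
  base <- unlist(lapply(task$condition_labels, function(cc) {
    rep(cc, task$blocks_per_run[[cc]])
  }))
  # preferred condition first in the base order
  base <- c(base[base == task$preferred_condition],
            base[base != task$preferred_condition])
  conds <- if ((subject_index + run_index) %% 2L == 1L) rev(base) else base
  n_blocks <- length(conds)
  onsets <- numeric(n_blocks)
  cursor <- task$fixation_s
  for (i in seq_len(n_blocks)) {
    cursor <- cursor + task$pre_block_s
    onsets[i] <- cursor
    cursor <- cursor + task$block_duration_s + task$fixation_s
  }
  total <- cursor
  if (!is.null(run_duration_s)) {
    if (run_duration_s < total) {
      stop_fcoi(sprintf("blocks (%.1f s) exceed run duration (%.1f s)",
                        total, run_duration_s),
                "fcoi_design_error")
    }
    total <- run_duration_s
  }
  events <- data.frame(condition = conds, onset_s = onsets,
                       duration_s = task$block_duration_s,
                       stringsAsFactors = FALSE)
  validate_events(events)
  attr(events, "run_duration_s") <- total
  events
}

# Event invariants: strictly increasing onsets, no overlap, positive durations.
validate_events <- function(events, run_duration_s = NULL) {
  if (nrow(events) == 0L) stop_fcoi("no events", "fcoi_validation_error")
  if (any(events$duration_s <= 0) || any(events$onset_s < 0)) {
    stop_fcoi("event onsets must be >= 0 and durations > 0",
              "fcoi_validation_error")
  }
  o <- events$onset_s
  if (is.unsorted(o, strictly = TRUE)) {
    stop_fcoi("event onsets must be strictly increasing",
              "fcoi_validation_error")
  }
  ends <- o + events$duration_s
  if (any(o[-1] < head(ends, -1))) {
    stop_fcoi("event blocks overlap", "fcoi_validation_error")
  }
  if (!is.null(run_duration_s) && any(ends > run_duration_s + 1e-9)) {
    stop_fcoi("event extends beyond the end of the recording",
              "fcoi_validation_error")
  }
  invisible(events)
}
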