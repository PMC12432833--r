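# Windowed block responses and the run/participant exclusion rules.

#' Baseline-correct one block
#'
#' Subtracts the per-channel mean over the `baseline_s` seconds preceding
#' block onset from the block segment. Blocks starting less than `baseline_s`
#' into the run are dropped (with a warning) rather than corrected against a
#' truncated baseline.
#'
#' @param conc `nirs_conc`; @param block one-row event (condition, onset_s,
#'   duration_s); @param baseline_s baseline duration (s).
#' @return list with matrices `hbo`, `hbr` (block samples x channels) and the
#'   onset-relative sample times `t_rel`, or `NULL` if the block was dropped.
#' @export
baseline_correct_block <- function(conc, block, baseline_s = 2) {
  fs <- conc$fs
  if (block$onset_s < baseline_s) {
    warning(sprintf("block at %.1f s dropped: onset precedes the %.1f s baseline",
                    block$onset_s, baseline_s))
    return(NULL)
  }
  n_t <- nrow(conc$hbo)
  onset_i <- floor(block$onset_s * fs) + 1L
  base_i <- seq(floor((block$onset_s - baseline_s) * fs) + 1L, onset_i - 1L)
  blk_i <- onset_i:min(n_t, ceiling((block$onset_s + block$duration_s) * fs))
  base_hbo <- colMeans(conc$hbo[base_i, , drop = FALSE])
  base_hbr <- colMeans(conc$hbr[base_i, , drop = FALSE])
  list(
    hbo = sweep(conc$hbo[blk_i, , drop = FALSE], 2, base_hbo),
    hbr = sweep(conc$hbr[blk_i, , drop = FALSE], 2, base_hbr),
    t_rel = (blk_i - onset_i) / fs
  )
}

#' Windowed mean block response
#'
#' Arithmetic mean over samples whose onset-relative time lies in the
#' half-open analysis window `[start_s, end_s)`.
#'
#' @param segment output of [baseline_correct_block()].
#' @param window `c(start_s, end_s)`.
#' @return list with per-channel vectors `hbo` and `hbr`.
#' @export
block_mean <- function(segment, window) {
  sel <- segment$t_rel >= window[1] & segment$t_rel < window[2]
  if (!any(sel)) stop_fcoi("empty analysis window", "fcoi_validation_error")
  list(hbo = colMeans(segment$hbo[sel, , drop = FALSE]),
       hbr = colMeans(segment$hbr[sel, , drop = FALSE]))
}

#' Build the block-response table for a set of preprocessed runs
#'
#' One row per kept channel x block holding the baseline-corrected windowed
#' mean HbO/HbR response; pruned channels produce no rows. Ordering is
#' deterministic (input run order, then block, then channel).
#'
#' @param conc_runs list of `nirs_conc` objects from [preprocess_run()]
#'   (each carrying its events, meta and mask).
#' @param tasks named list of [task_spec()] keyed by task id.
#' @param baseline_s pre-onset baseline duration (s).
#' @return data frame with columns `subject_id`, `task_id`, `run_index`,
#'   `channel_id`, `block_index`, `condition`, `mean_hbo`, `mean_hbr`.
#' @export
build_block_table <- function(conc_runs, tasks, baseline_s = 2) {
  rows <- vector("list", length(conc_runs))
  for (i in seq_along(conc_runs)) {
    conc <- conc_runs[[i]]
    if (isFALSE(attr(conc, "usable"))) next
    task <- tasks[[conc$meta$task_id]]
    if (is.null(task)) {
      stop_fcoi(sprintf("no task spec for task '%s'", conc$meta$task_id),
                "fcoi_config_error")
    }
    keep <- which(conc$kept)
    if (length(keep) == 0L) next
    blk_rows <- list()
    for (b in seq_len(nrow(conc$events))) {
      seg <- withCallingHandlers(
        baseline_correct_block(conc, conc$events[b, ], baseline_s),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (is.null(seg)) next
      m <- block_mean(seg, task$window)
      blk_rows[[length(blk_rows) + 1]] <- data.frame(
        subject_id = conc$meta$subject_id,
        task_id = conc$meta$task_id,
        run_index = conc$meta$run_index,
        channel_id = keep,
        block_index = b,
        condition = conc$events$condition[b],
        mean_hbo = m$hbo[keep],
        mean_hbr = m$hbr[keep],
        stringsAsFactors = FALSE
      )
    }
    if (length(blk_rows)) rows[[i]] <- do.call(rbind, blk_rows)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(subject_id = character(), task_id = character(),
                      run_index = integer(), channel_id = integer(),
                      block_index = integer(), condition = character(),
                      mean_hbo = numeric(), mean_hbr = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Apply the run and participant exclusion rules
#'
#' Evaluated separately for every search space (a run may be valid for one
#' space and excluded for another): a run is excluded when *strictly more
#' than* one-third of the space's channels were pruned in that run; a subject
#' is then excluded, per task and space, when fewer than `min_runs` valid
#' runs remain. Exactly `min_runs` valid runs is retained.
#'
#' @param table block-response table from [build_block_table()].
#' @param masks data frame with columns `subject_id`, `task_id`, `run_index`,
#'   `channel`, `kept` covering every run in `table`.
#' @param search_spaces named list of [search_space()] objects.
#' @param min_runs minimum valid runs per task (default 2).
#' @param max_bad_fraction exclusion threshold on the pruned fraction.
#' @return list with `table` (rows restricted to in-space channels of
#'   surviving runs, with an added `search_space` column) and `report` (an
#'   `exclusion_report`: excluded runs and subjects with reasons, surviving
#'   counts per task and space).
#' @export
apply_exclusions <- function(table, masks, search_spaces, min_runs = 2,
                             max_bad_fraction = 1 / 3) {
  out_tables <- list()
  excl_runs <- list()
  excl_subj <- list()
  surviving <- list()
  for (sp_name in names(search_spaces)) {
    sp <- search_spaces[[sp_name]]
    sp_size <- length(sp$member_channels)
    run_keys <- unique(masks[, c("subject_id", "task_id", "run_index")])
    run_keys$bad_frac <- NA_real_
    for (i in seq_len(nrow(run_keys))) {
      mk <- masks[masks$subject_id == run_keys$subject_id[i] &
                    masks$task_id == run_keys$task_id[i] &
                    masks$run_index == run_keys$run_index[i], ]
      pruned <- sum(!mk$kept[mk$channel %in% sp$member_channels])
      run_keys$bad_frac[i] <- pruned / sp_size
    }
    run_keys$excluded <- run_keys$bad_frac > max_bad_fraction
    bad_runs <- run_keys[run_keys$excluded, , drop = FALSE]
    if (nrow(bad_runs)) {
      bad_runs$search_space <- sp_name
      bad_runs$reason <- sprintf("pruned fraction %.3f > %.3f",
                                 bad_runs$bad_frac, max_bad_fraction)
      excl_runs[[sp_name]] <- bad_runs
    }
    valid <- run_keys[!run_keys$excluded, , drop = FALSE]
    # subjects with < min_runs valid runs for any task are dropped entirely
    counts <- stats::aggregate(run_index ~ subject_id + task_id, valid, length)
    short <- counts[counts$run_index < min_runs, , drop = FALSE]
    all_tasks <- unique(masks$task_id)
    missing <- expand.grid(subject_id = unique(masks$subject_id),
                           task_id = all_tasks, stringsAsFactors = FALSE)
    missing <- missing[!paste(missing$subject_id, missing$task_id) %in%
                         paste(counts$subject_id, counts$task_id), ,
                       drop = FALSE]
    bad_subjects <- unique(c(short$subject_id, missing$subject_id))
    if (length(bad_subjects)) {
      excl_subj[[sp_name]] <- data.frame(
        subject_id = bad_subjects, search_space = sp_name,
        reason = sprintf("fewer than %d valid runs for a task", min_runs))
    }
    valid <- valid[!valid$subject_id %in% bad_subjects, , drop = FALSE]
    keep_key <- paste(valid$subject_id, valid$task_id, valid$run_index)
    tab <- table[paste(table$subject_id, table$task_id, table$run_index) %in%
                   keep_key &
                   table$channel_id %in% sp$member_channels, , drop = FALSE]
    if (nrow(tab)) tab$search_space <- sp_name
    out_tables[[sp_name]] <- tab
    surv <- stats::aggregate(run_index ~ subject_id + task_id, valid, length)
    if (nrow(surv)) surv$search_space <- sp_name
    surviving[[sp_name]] <- surv
  }
  tab_all <- do.call(rbind, out_tables[vapply(out_tables, nrow,
                                              integer(1)) > 0])
  if (is.null(tab_all)) {
    tab_all <- cbind(table[0, , drop = FALSE],
                     search_space = character(0))
  }
  rownames(tab_all) <- NULL
  report <- structure(
    list(
      excluded_runs = if (length(excl_runs)) do.call(rbind, excl_runs) else
        data.frame(),
      excluded_subjects = if (length(excl_subj)) do.call(rbind, excl_subj)
      else data.frame(),
      surviving = do.call(rbind, surviving)
    ),
    class = "exclusion_report"
  )
  rownames(report$excluded_runs) <- NULL
  rownames(report$excluded_subjects) <- NULL
  list(table = tab_all, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d excluded runs, %d excluded subjects\n",
              nrow(x$excluded_runs), nrow(x$excluded_subjects)))
  invisible(x)
}

# Masks data frame for a list of preprocessed runs.
collect_masks <- function(conc_runs) {
  do.call(rbind, lapply(conc_runs, function(conc) {
    m <- attr(conc, "mask")
    data.frame(subject_id = conc$meta$subject_id,
               task_id = conc$meta$task_id,
               run_index = conc$meta$run_index,
               channel = m$channel, kept = m$kept, reason = m$reason,
               stringsAsFactors = FALSE)
  }))
}
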