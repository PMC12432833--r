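# Leave-one-run-out functional channel-of-interest selection and
# independent-data response estimation.

# per (run, channel, condition) mean HbO for one subject/task within a space
run_channel_means <- function(tab) {
  stats::aggregate(cbind(mean_hbo, mean_hbr) ~
                     run_index + channel_id + condition, tab, mean)
}

# training contrast per channel: unweighted mean over training runs of the
# per-run (positive - negative) condition-mean difference; channels must be
# present in every training run to be eligible.
training_contrast <- function(means, train_runs, contrast) {
  m <- means[means$run_index %in% train_runs, , drop = FALSE]
  res <- list()
  for (ch in sort(unique(m$channel_id))) {
    mc <- m[m$channel_id == ch, , drop = FALSE]
    per_run <- vapply(train_runs, function(r) {
      pos <- mc$mean_hbo[mc$run_index == r & mc$condition ==
                           contrast$positive_condition]
      neg <- mc$mean_hbo[mc$run_index == r & mc$condition ==
                           contrast$negative_condition]
      if (length(pos) != 1 || length(neg) != 1) return(NA_real_)
      pos - neg
    }, numeric(1))
    if (anyNA(per_run)) next # pruned or incomplete in some training run
    res[[as.character(ch)]] <- mean(per_run)
  }
  res
}

#' Specify an fCOI-defining contrast
#'
#' @param fcoi_type `"language"` or `"md"`.
#' @param defining_task task id whose data define the fCOI.
#' @param positive_condition,negative_condition condition labels of the
#'   defining task; the fCOI is the channel maximising
#'   `positive - negative` mean HbO.
#' @return object of class `contrast_spec`.
#' @export
contrast_spec <- function(fcoi_type, defining_task, positive_condition,
                          negative_condition) {
  structure(list(fcoi_type = fcoi_type, defining_task = defining_task,
                 positive_condition = positive_condition,
                 negative_condition = negative_condition),
            class = "contrast_spec")
}

# packaged contrasts given the available task specs
default_contrasts <- function(tasks) {
  out <- list()
  for (nm in c("language", "md")) {
    tk <- tasks[[nm]]
    if (is.null(tk)) next
    out[[nm]] <- contrast_spec(nm, tk$task_id, tk$preferred_condition,
                               setdiff(tk$condition_labels,
                                       tk$preferred_condition))
  }
  out
}

#' Leave-one-run-out fCOI selection for one subject
#'
#' For each valid run `r` of the defining task, the per-channel condition
#' means are averaged over all *other* valid runs, the in-space channel with
#' the maximum positive-minus-negative mean HbO contrast is selected (ties
#' broken by lowest channel id), and that channel's block-level responses are
#' recorded from run `r` only -- so held-out responses never come from data
#' used for selection.
#'
#' @param table space-restricted block table (rows for one search space, from
#'   [apply_exclusions()]).
#' @param subject subject id.
#' @param space [search_space()].
#' @param contrast [contrast_spec()].
#' @return object of class `fcoi_estimate` with elements `folds` (data frame:
#'   `held_out_run`, `selected_channel`, `train_contrast`) and `responses`
#'   (held-out block-level rows tagged `origin = "within_task"`), or `NULL`
#'   if the subject has fewer than 2 valid runs.
#' @export
loro_select <- function(table, subject, space, contrast) {
  tab <- table[table$subject_id == subject &
                 table$task_id == contrast$defining_task &
                 table$channel_id %in% space$member_channels, , drop = FALSE]
  runs <- sort(unique(tab$run_index))
  if (length(runs) < 2) return(NULL)
  means <- run_channel_means(tab)
  folds <- list()
  responses <- list()
  skipped <- list()
  for (r in runs) {
    tc <- training_contrast(means, setdiff(runs, r), contrast)
    if (length(tc) == 0) {
      skipped[[as.character(r)]] <- "no eligible in-space channel"
      next
    }
    vals <- unlist(tc)
    sel <- as.integer(names(tc)[which(vals == max(vals))])
    sel <- min(sel) # deterministic tie-break: lowest channel id
    folds[[length(folds) + 1]] <- data.frame(
      held_out_run = r, selected_channel = sel,
      train_contrast = max(vals))
    held <- tab[tab$run_index == r & tab$channel_id == sel, , drop = FALSE]
    if (nrow(held)) {
      held$origin <- "within_task"
      held$selected_channel <- sel
      responses[[length(responses) + 1]] <- held
    }
  }
  structure(
    list(subject_id = subject, search_space = space$name, contrast = contrast,
         folds = if (length(folds)) do.call(rbind, folds) else
           data.frame(held_out_run = integer(), selected_channel = integer(),
                      train_contrast = numeric()),
         responses = if (length(responses)) do.call(rbind, responses) else
           NULL,
         skipped_folds = skipped,
         n_valid_runs = length(runs),
         flagged = length(folds) == 0),
    class = "fcoi_estimate"
  )
}

#' @export
print.fcoi_estimate <- function(x, ...) {
  cat(sprintf("<fcoi_estimate> subject %s, %s %s fCOI: %d folds\n",
              x$subject_id, x$search_space, x$contrast$fcoi_type,
              nrow(x$folds)))
  invisible(x)
}

#' Cross-task fCOI response estimation for one subject
#'
#' Selects the channel on *all* valid runs of the defining task (no hold-out
#' is needed because the estimation data come from a different task), then
#' extracts that channel's block-level responses from every valid run of
#' `other_task`. Defining and estimating on the same task is refused -- that
#' would be double dipping.
#'
#' @inheritParams loro_select
#' @param other_task task id providing the independent estimation data.
#' @return `fcoi_estimate` whose `responses` carry `origin = "cross_task"`,
#'   or `NULL` if the subject lacks data in either task.
#' @export
cross_task_estimate <- function(table, subject, space, contrast, other_task) {
  if (identical(other_task, contrast$defining_task)) {
    stop_fcoi("cross-task estimation on the defining task is double dipping",
              "fcoi_api_error")
  }
  def <- table[table$subject_id == subject &
                 table$task_id == contrast$defining_task &
                 table$channel_id %in% space$member_channels, , drop = FALSE]
  oth <- table[table$subject_id == subject &
                 table$task_id == other_task &
                 table$channel_id %in% space$member_channels, , drop = FALSE]
  runs <- sort(unique(def$run_index))
  if (length(runs) < 1 || nrow(oth) == 0) return(NULL)
  tc <- training_contrast(run_channel_means(def), runs, contrast)
  if (length(tc) == 0) return(NULL)
  vals <- unlist(tc)
  sel <- min(as.integer(names(tc)[which(vals == max(vals))]))
  resp <- oth[oth$channel_id == sel, , drop = FALSE]
  omitted <- setdiff(unique(oth$run_index), unique(resp$run_index))
  if (nrow(resp)) {
    resp$origin <- "cross_task"
    resp$selected_channel <- sel
  } else resp <- NULL
  structure(
    list(subject_id = subject, search_space = space$name, contrast = contrast,
         folds = data.frame(held_out_run = NA_integer_,
                            selected_channel = sel,
                            train_contrast = max(vals)),
         responses = resp,
         omitted_runs = omitted, # channel pruned in these other-task runs
         n_valid_runs = length(runs), flagged = is.null(resp)),
    class = "fcoi_estimate"
  )
}

#' Selection histogram across subjects
#'
#' Counts, per channel, how often each channel was selected across all folds
#' of a set of estimates; counts sum to the number of successful folds.
#'
#' @param estimates list of `fcoi_estimate` objects.
#' @return data frame (`channel_id`, `count`) sorted by channel.
#' @export
selection_histogram <- function(estimates) {
  estimates <- Filter(Negate(is.null), estimates)
  if (length(estimates) == 0) {
    stop_fcoi("no estimates supplied", "fcoi_validation_error")
  }
  sel <- unlist(lapply(estimates, function(e) e$folds$selected_channel))
  sel <- sel[!is.na(sel)]
  tab <- table(sel)
  data.frame(channel_id = as.integer(names(tab)),
             count = as.integer(tab))
}
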