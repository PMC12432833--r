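# Mixed-effects group inference and family-wise error control.

#' Fit the condition model for one fCOI
#'
#' Linear mixed model `response ~ condition + (1|subject)` fitted by maximum
#' likelihood on block-level observations, with the condition factor coded
#' preferred = 1, other = 0 so that selectivity implies `beta > 0` (the sign
#' convention is explicit in the output rather than matched to any particular
#' software's default coding). Inference is a Wald t statistic with residual
#' degrees of freedom `n_obs - 2` (optionally Satterthwaite-free by design:
#' at these observation counts df corrections are immaterial). A singular fit
#' (zero random-intercept variance) falls back to its boundary solution and
#' is flagged, not treated as failure. No random slopes are fitted.
#'
#' @param responses data frame with columns `subject_id`, `condition`, and
#'   the response column `value_col`.
#' @param preferred_condition condition coded 1.
#' @param value_col response column (default `"mean_hbo"`).
#' @return object of class `model_fit`: `beta`, `se`, `t`, `df`, `p`,
#'   `random_intercept_var`, `n_obs`, `n_subjects`, `converged`, `singular`.
#' @export
fit_condition_model <- function(responses, preferred_condition,
                                value_col = "mean_hbo") {
  if (length(unique(responses$condition)) < 2) {
    stop_fcoi("both conditions must be present", "fcoi_validation_error")
  }
  n_subj <- length(unique(responses$subject_id))
  if (n_subj < 2) {
    stop_fcoi("need at least 2 subjects", "fcoi_validation_error")
  }
  d <- data.frame(y = responses[[value_col]],
                  x = as.numeric(responses$condition == preferred_condition),
                  subject = factor(responses$subject_id))
  n_obs <- nrow(d)
  converged <- TRUE
  singular <- FALSE
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      y ~ x + (1 | subject), data = d, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    singular <- lme4::isSingular(fit, tol = 1e-5)
    co <- summary(fit)$coefficients
    beta <- co["x", "Estimate"]
    se <- co["x", "Std. Error"]
    ri_var <- as.data.frame(lme4::VarCorr(fit))$vcov[1]
  } else {
    # boundary solution: zero intercept variance reduces to OLS
    converged <- FALSE
    ols <- lm.fit(cbind(1, d$x), d$y)
    beta <- ols$coefficients[2]
    rss <- sum(ols$residuals^2)
    se <- sqrt(rss / (n_obs - 2) /
                 sum((d$x - mean(d$x))^2))
    ri_var <- 0
  }
  tval <- beta / se
  df <- n_obs - 2
  p <- 2 * pt(-abs(tval), df)
  structure(
    list(beta = unname(beta), se = unname(se), t = unname(tval), df = df,
         p = unname(p), random_intercept_var = ri_var,
         n_obs = n_obs, n_subjects = n_subj,
         converged = converged, singular = singular,
         coding = sprintf("%s = 1 (preferred), other = 0",
                          preferred_condition)),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "<model_fit> beta = %.3g (SE %.3g), t(%d) = %.2f, p = %.4g [%s]\n",
    x$beta, x$se, x$df, x$t, x$p, x$coding))
  invisible(x)
}

#' Bonferroni per-comparison threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons in the family (>= 1).
#' @return `alpha / m`. With the paper-style family of the left and right
#'   IFG fCOIs (`m = 2`) and `alpha = 0.05` this is 0.025.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stop_fcoi("alpha must be in (0, 1)",
                                           "fcoi_config_error")
  if (!(is.numeric(m) && m >= 1)) stop_fcoi("family size must be >= 1",
                                            "fcoi_config_error")
  alpha / m
}

#' Family-wise significance decisions
#'
#' Marks each member fit significant iff `p < alpha / m` where `m` is the
#' family size.
#'
#' @param fits named list of `model_fit` objects forming one family.
#' @param alpha family-wise error rate.
#' @return object of class `family_decision` (data frame of members with the
#'   shared threshold and per-member significance).
#' @export
family_decision <- function(fits, alpha = 0.05) {
  thr <- bonferroni_threshold(alpha, length(fits))
  out <- data.frame(
    member = names(fits),
    p = vapply(fits, function(f) f$p, numeric(1)),
    threshold = thr)
  out$significant <- out$p < thr
  structure(out, class = c("family_decision", "data.frame"))
}

#' Summarise the language/MD double dissociation
#'
#' Takes the 8 cell fits (2 search spaces x 2 fCOI types x 2 contrasts) and
#' reports beta/SE/t/p and Bonferroni-corrected significance per cell, plus a
#' boolean dissociation flag: language fCOIs significant (positive beta) for
#' the language contrast and not significant for the demand contrast in both
#' spaces, and MD fCOIs the reverse. Missing cells yield a partial report
#' with an undefined (`NA`) flag. The family for correction is, per the
#' stated convention, the left/right pair within each task.
#'
#' @param fits data frame with one row per cell: `search_space`, `fcoi_type`,
#'   `data_task`, `beta`, `se`, `t`, `p` (as produced by [analyze_cohort()]).
#' @param alpha family-wise error rate (family size 2).
#' @return list of class `dissociation_report`: `cells` (the table with a
#'   `significant` column), `threshold`, and `double_dissociation` flag.
#' @export
dissociation_report <- function(fits, alpha = 0.05) {
  thr <- bonferroni_threshold(alpha, 2)
  fits$significant <- !is.na(fits$p) & fits$p < thr & fits$beta > 0
  cell <- function(space, type, task) {
    i <- fits$search_space == space & fits$fcoi_type == type &
      fits$data_task == task
    if (sum(i) != 1) return(NULL)
    fits[i, , drop = FALSE]
  }
  need <- list(
    lang_l_within = cell("LIFG", "language", "language"),
    lang_r_within = cell("RIFG", "language", "language"),
    lang_l_cross = cell("LIFG", "language", "md"),
    lang_r_cross = cell("RIFG", "language", "md"),
    md_l_within = cell("LIFG", "md", "md"),
    md_r_within = cell("RIFG", "md", "md"),
    md_l_cross = cell("LIFG", "md", "language"),
    md_r_cross = cell("RIFG", "md", "language")
  )
  flag <- if (any(vapply(need, is.null, logical(1)))) {
    NA
  } else {
    need$lang_l_within$significant && need$lang_r_within$significant &&
      !need$lang_l_cross$significant && !need$lang_r_cross$significant &&
      need$md_l_within$significant && need$md_r_within$significant &&
      !need$md_l_cross$significant && !need$md_r_cross$significant
  }
  structure(list(cells = fits, threshold = thr, double_dissociation = flag),
            class = "dissociation_report")
}

#' @export
print.dissociation_report <- function(x, ...) {
  cat(sprintf("<dissociation_report> threshold %.4g, double dissociation: %s\n",
              x$threshold, x$double_dissociation))
  print(x$cells[, c("search_space", "fcoi_type", "data_task", "beta", "t",
                    "p", "significant")])
  invisible(x)
}

#' Full fCOI analysis of a set of recordings
#'
#' Orchestrates the whole pipeline for one cohort: per-run preprocessing,
#' block-response extraction, run/participant exclusion per search space,
#' leave-one-run-out within-task fCOI estimation and cross-task estimation
#' for both fCOI types in both spaces, mixed-model fits of all 8 cells, and
#' the dissociation summary.
#'
#' @param runs list of `nirs_run` recordings (both tasks).
#' @param spaces named list of [search_space()] objects (LIFG, RIFG).
#' @param tasks named list of [task_spec()] (`language`, `md`).
#' @param config [preprocess_config()].
#' @param min_runs minimum valid runs per task.
#' @return list: `fits` (8-row data frame), `dissociation`
#'   (`dissociation_report`), `estimates` (per space x type lists of
#'   `fcoi_estimate`), `block_table`, `exclusions`, `histograms`.
#' @export
analyze_cohort <- function(runs, spaces, tasks,
                           config = preprocess_config(), min_runs = 2) {
  tasks_by_id <- setNames(tasks, vapply(tasks, `[[`, "", "task_id"))
  conc_runs <- lapply(runs, preprocess_run, config = config)
  masks <- collect_masks(conc_runs)
  table <- build_block_table(conc_runs, tasks_by_id,
                             baseline_s = config$baseline_window_s)
  fcoi_group_analysis(table, masks, spaces, tasks, min_runs = min_runs)
}

#' Simulate and analyse a scenario without retaining raw data
#'
#' Streaming counterpart of [simulate_cohort()] + [analyze_cohort()]: each
#' run is simulated, preprocessed, and reduced to its block-response rows
#' before the next is generated, so full-size cohorts fit in constant
#' memory.
#'
#' @param scn a [scenario()].
#' @param config [preprocess_config()].
#' @param task_ids which tasks to simulate (default both).
#' @param min_runs minimum valid runs per task.
#' @return as [analyze_cohort()], plus `truth` (the scenario ground truth).
#' @export
analyze_scenario <- function(scn, config = preprocess_config(),
                             task_ids = NULL, min_runs = 2) {
  truth <- scn$truth
  tasks <- scn$tasks
  if (!is.null(task_ids)) {
    tasks <- Filter(function(t) t$task_id %in% task_ids, tasks)
  }
  tasks_by_id <- setNames(tasks, vapply(tasks, `[[`, "", "task_id"))
  set.seed(derive_seed(truth$seed, stream = 9L))
  subj_dev <- rnorm(scn$n_subjects, 0, truth$subject_effect_sd_uM)
  tabs <- list()
  masks <- list()
  for (s in seq_len(scn$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (task in tasks) {
      for (r in seq_len(task$runs_expected)) {
        run <- simulate_run(truth, scn$montage, task, s, r, subject_id = sid,
                            subject_effect_uM = subj_dev[s])
        conc <- preprocess_run(run, config)
        tabs[[length(tabs) + 1]] <-
          build_block_table(list(conc), tasks_by_id,
                            baseline_s = config$baseline_window_s)
        masks[[length(masks) + 1]] <- collect_masks(list(conc))
      }
    }
  }
  out <- fcoi_group_analysis(do.call(rbind, tabs), do.call(rbind, masks),
                             scn$spaces, tasks, min_runs = min_runs)
  out$truth <- truth
  out
}

# Shared group-level stage: exclusions, fCOI estimation, mixed models,
# dissociation summary.
fcoi_group_analysis <- function(table, masks, spaces, tasks, min_runs = 2) {
  tasks_by_id <- setNames(tasks, vapply(tasks, `[[`, "", "task_id"))
  excl <- apply_exclusions(table, masks, spaces, min_runs = min_runs)
  contrasts <- default_contrasts(tasks_by_id)

  fit_rows <- list()
  estimates <- list()
  histograms <- list()
  for (sp_name in names(spaces)) {
    sp <- spaces[[sp_name]]
    sp_tab <- excl$table[excl$table$search_space == sp_name, , drop = FALSE]
    for (ct_name in names(contrasts)) {
      ct <- contrasts[[ct_name]]
      other <- setdiff(vapply(contrasts, `[[`, "", "defining_task"),
                       ct$defining_task)
      subjects <- unique(sp_tab$subject_id)
      within <- lapply(subjects, function(s) loro_select(sp_tab, s, sp, ct))
      cross <- if (length(other) == 1) {
        lapply(subjects, function(s)
          cross_task_estimate(sp_tab, s, sp, ct, other))
      } else list()
      key <- paste(sp_name, ct_name, sep = ".")
      estimates[[key]] <- list(within = within, cross = cross)
      histograms[[key]] <- tryCatch(selection_histogram(within),
                                    error = function(e) NULL)
      within_rows <- do.call(rbind, lapply(within, function(e)
        if (!is.null(e)) e$responses))
      cross_rows <- do.call(rbind, lapply(cross, function(e)
        if (!is.null(e)) e$responses))
      for (side in list(list(rows = within_rows, task = ct$defining_task),
                        list(rows = cross_rows, task = other))) {
        if (is.null(side$rows) || nrow(side$rows) == 0) next
        pref <- tasks_by_id[[side$task]]$preferred_condition
        fit <- tryCatch(fit_condition_model(side$rows, pref),
                        error = function(e) NULL)
        if (is.null(fit)) next
        fit_rows[[length(fit_rows) + 1]] <- data.frame(
          search_space = sp_name, fcoi_type = ct_name,
          data_task = side$task,
          analysis = if (identical(side$task, ct$defining_task)) "within"
          else "cross",
          beta = fit$beta, se = fit$se, t = fit$t, df = fit$df, p = fit$p,
          n_obs = fit$n_obs, n_subjects = fit$n_subjects,
          singular = fit$singular, stringsAsFactors = FALSE)
      }
    }
  }
  fits <- if (length(fit_rows)) do.call(rbind, fit_rows) else
    data.frame(search_space = character(), fcoi_type = character(),
               data_task = character(), beta = numeric(), se = numeric(),
               t = numeric(), p = numeric())
  list(fits = fits,
       dissociation = dissociation_report(fits),
       estimates = estimates,
       histograms = histograms,
       block_table = excl$table,
       exclusions = excl$report)
}
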