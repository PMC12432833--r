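#' Describe a block-design task
#'
#' Captures the block structure and analysis window of one localizer task. The
#' analysis window is expressed in seconds relative to block onset; windowed
#' block means use samples with onset-relative time in the half-open interval
#' `[start_s, end_s)` to keep block boundaries unambiguous on integer sample
#' grids.
#'
#' @param task_id `"language"` or `"md"`.
#' @param condition_labels two condition labels.
#' @param preferred_condition the positive pole of the task contrast (must be
#'   one of `condition_labels`).
#' @param block_duration_s block length in seconds.
#' @param fixation_s fixation duration between blocks (and lead-in/out).
#' @param window numeric `c(start_s, end_s)` analysis window; the default start
#'   of 5 s accounts for hemodynamic response lag.
#' @param runs_expected number of runs in the full design.
#' @param blocks_per_run named integer vector: blocks per condition per run.
#' @param pre_block_s dead time between fixation end and block onset (e.g. an
#'   instruction screen that is not part of the analysed block).
#' @return object of class `nirs_task`.
#' @export
task_spec <- function(task_id, condition_labels, preferred_condition,
                      block_duration_s, fixation_s, window, runs_expected,
                      blocks_per_run, pre_block_s = 0) {
  stopifnot(length(condition_labels) == 2L)
  if (!preferred_condition %in% condition_labels) {
    stop_fcoi("preferred_condition must be one of condition_labels",
              "fcoi_config_error")
  }
  window <- as.numeric(window)
  if (length(window) != 2L || window[1] < 0 || window[1] >= window[2] ||
      window[2] > block_duration_s) {
    stop_fcoi("analysis window must satisfy 0 <= start < end <= block length",
              "fcoi_config_error")
  }
  if (any(blocks_per_run < 0L) ||
      !setequal(names(blocks_per_run), condition_labels)) {
    stop_fcoi("blocks_per_run must be named by the condition labels",
              "fcoi_config_error")
  }
  structure(
    list(task_id = task_id,
         condition_labels = condition_labels,
         preferred_condition = preferred_condition,
         block_duration_s = as.numeric(block_duration_s),
         fixation_s = as.numeric(fixation_s),
         window = window,
         runs_expected = as.integer(runs_expected),
         blocks_per_run = blocks_per_run,
         pre_block_s = as.numeric(pre_block_s)),
    class = "nirs_task"
  )
}

#' Packaged task specifications
#'
#' Returns the two localizer tasks for a population:
#' * adult language localizer: 3 intact + 1 degraded 20-s blocks per run,
#'   10-s fixations, 8 runs, analysis window 5-20 s post-onset;
#' * adult spatial working-memory task: one easy + one hard 34-s block per
#'   run (4 trials of 8.5 s), 10-s fixations, 4 runs, window 5-33 s;
#' * toddler language localizer: 1 intact + 1 degraded 17-s block per run,
#'   6-s fixations, 4 runs, window 5-17 s;
#' * toddler go/no-go: one go-only (easy) + one go/no-go (hard) block per run;
#'   block onset marks the start of the 12-s trial sequence (the 3-s
#'   instruction screen precedes it), 10-s fixations, 4 runs, window 5-12 s.
#'
#' @param population `"adult"` or `"toddler"`.
#' @return named list with elements `language` and `md`.
#' @export
default_tasks <- function(population = c("adult", "toddler")) {
  population <- match.arg(population)
  if (population == "adult") {
    list(
      language = task_spec(
        "language", c("intact", "degraded"), "intact",
        block_duration_s = 20, fixation_s = 10, window = c(5, 20),
        runs_expected = 8, blocks_per_run = c(intact = 3L, degraded = 1L)
      ),
      md = task_spec(
        "md", c("hard", "easy"), "hard",
        block_duration_s = 34, fixation_s = 10, window = c(5, 33),
        runs_expected = 4, blocks_per_run = c(hard = 1L, easy = 1L)
      )
    )
  } else {
    list(
      language = task_spec(
        "language", c("intact", "degraded"), "intact",
        block_duration_s = 17, fixation_s = 6, window = c(5, 17),
        runs_expected = 4, blocks_per_run = c(intact = 1L, degraded = 1L)
      ),
      md = task_spec(
        "md", c("hard", "easy"), "hard",
        block_duration_s = 12, fixation_s = 10, window = c(5, 12),
        runs_expected = 4, blocks_per_run = c(hard = 1L, easy = 1L),
        pre_block_s = 3
      )
    )
  }
}

#' Preprocessing configuration
#'
#' Bundles every tunable of the preprocessing chain with its published default:
#' intensity range `[1e3, 1e7]` and SNR threshold 5 for channel pruning, a
#' 0.01-0.09 Hz zero-phase Butterworth band-pass (low-pass order 3, high-pass
#' order 5), TDDR internals (Tukey constant 4.685, 0.5 Hz split frequency),
#' partial pathlength factor 1.0 per wavelength, a 46 degree Gaussian kernel
#' for the PCA spatial filter, and a 2-s pre-onset baseline window.
#'
#' @param d_range intensity mean acceptance range.
#' @param snr_thresh minimum mean/SD ratio.
#' @param low_cut_hz,high_cut_hz band-pass corner frequencies.
#' @param lowpass_order,highpass_order Butterworth orders.
#' @param tddr_tukey_c,tddr_split_freq_hz,tddr_max_iter,tddr_tol TDDR controls.
#' @param pca_sigma_deg spatial-filter Gaussian width (degrees).
#' @param ppf partial pathlength factor, recycled per wavelength.
#' @param baseline_window_s pre-onset baseline duration (s).
#' @param run_bandpass,run_tddr,run_pca logical switches allowing individual
#'   steps to be disabled (used by forward/inverse validation).
#' @param manual_exclude integer channel ids to drop regardless of automatic
#'   pruning (channels lacking a clear cardiac signal).
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(d_range = c(1e3, 1e7), snr_thresh = 5,
                              low_cut_hz = 0.01, high_cut_hz = 0.09,
                              lowpass_order = 3, highpass_order = 5,
                              tddr_tukey_c = 4.685, tddr_split_freq_hz = 0.5,
                              tddr_max_iter = 50, tddr_tol = 1e-8,
                              pca_sigma_deg = 46, ppf = 1.0,
                              baseline_window_s = 2,
                              run_bandpass = TRUE, run_tddr = TRUE,
                              run_pca = TRUE, manual_exclude = integer()) {
  if (d_range[1] >= d_range[2]) {
    stop_fcoi("d_range low must be below high", "fcoi_config_error")
  }
  if (!(low_cut_hz > 0 && low_cut_hz < high_cut_hz)) {
    stop_fcoi("need 0 < low_cut_hz < high_cut_hz", "fcoi_config_error")
  }
  if (pca_sigma_deg <= 0) {
    stop_fcoi("pca_sigma_deg must be > 0", "fcoi_config_error")
  }
  structure(
    list(d_range = d_range, snr_thresh = snr_thresh,
         low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
         lowpass_order = lowpass_order, highpass_order = highpass_order,
         tddr_tukey_c = tddr_tukey_c, tddr_split_freq_hz = tddr_split_freq_hz,
         tddr_max_iter = tddr_max_iter, tddr_tol = tddr_tol,
         pca_sigma_deg = pca_sigma_deg, ppf = ppf,
         baseline_window_s = baseline_window_s,
         run_bandpass = run_bandpass, run_tddr = run_tddr, run_pca = run_pca,
         manual_exclude = as.integer(manual_exclude)),
    class = "preprocess_config"
  )
}
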