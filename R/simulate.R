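# Synthetic-cohort generator: block-design HbO/HbR responses with known
# channel-level ground truth, physiological noise, drifts, a shared global
# component, and scheduled motion artifacts, rendered to raw intensities via
# the forward Beer-Lambert model.

#' Ground truth for a simulated cohort
#'
#' Describes, per channel, the condition selectivity injected by the
#' simulator, plus every noise and artifact magnitude. Effects are windowed
#' plateau amplitudes in micromolar: the preferred condition of a task evokes
#' `base_amp_uM + effect`, the other condition `base_amp_uM`. Exactly one
#' "true" language channel and one "true" MD channel are designated per search
#' space in the default scenarios. HbR is generated as `hbr_ratio` times HbO.
#'
#' @param n_channels number of montage channels.
#' @param language_channels,md_channels integer ids of selective channels.
#' @param language_effect_uM,md_effect_uM effect amplitudes (micromolar) given
#'   to the selective channels (recycled).
#' @param base_amp_uM response amplitude common to both conditions.
#' @param white_sd_uM per-sample white noise SD.
#' @param drift_sd_uM SD of the slow random-walk drift over a run.
#' @param cardiac,respiration,mayer `c(freq_hz, amp_uM)` sinusoidal systemic
#'   oscillations.
#' @param global_amp_uM SD of the shared global component.
#' @param spike_rate_per_min,spike_amp_od,spike_width_s motion spikes
#'   (Gaussian bumps in optical density, shared across channels).
#' @param shift_rate_per_min,shift_amp_od step-like baseline shifts (OD).
#' @param hbr_ratio negative HbR:HbO ratio.
#' @param subject_effect_sd_uM between-subject SD of the injected effects.
#' @param baseline_intensity detector counts at rest (arbitrary units).
#' @param seed integer seed; together with subject/run indices it fully
#'   determines the cohort.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(n_channels,
                      language_channels = integer(),
                      md_channels = integer(),
                      language_effect_uM = 0.5,
                      md_effect_uM = 0.5,
                      base_amp_uM = 0.1,
                      white_sd_uM = 0.3,
                      drift_sd_uM = 0.2,
                      cardiac = c(1.2, 0.15),
                      respiration = c(0.25, 0.1),
                      mayer = c(0.1, 0.1),
                      global_amp_uM = 0.5,
                      spike_rate_per_min = 0.5,
                      spike_amp_od = 0.02,
                      spike_width_s = 0.5,
                      shift_rate_per_min = 0.2,
                      shift_amp_od = 0.01,
                      hbr_ratio = -1 / 3,
                      subject_effect_sd_uM = 0.1,
                      baseline_intensity = 1e5,
                      seed = 1L) {
  if (hbr_ratio >= 0) stop_fcoi("hbr_ratio must be negative",
                                "fcoi_config_error")
  amps <- c(language_effect_uM, md_effect_uM, base_amp_uM, white_sd_uM,
            drift_sd_uM, cardiac[2], respiration[2], mayer[2], global_amp_uM,
            spike_amp_od, shift_amp_od)
  if (any(amps < 0)) stop_fcoi("amplitudes must be >= 0", "fcoi_config_error")
  lang <- numeric(n_channels)
  lang[language_channels] <- rep_len(language_effect_uM,
                                     length(language_channels))
  md <- numeric(n_channels)
  md[md_channels] <- rep_len(md_effect_uM, length(md_channels))
  structure(
    list(n_channels = as.integer(n_channels),
         language_effect_uM = lang, md_effect_uM = md,
         language_channels = as.integer(language_channels),
         md_channels = as.integer(md_channels),
         base_amp_uM = base_amp_uM, white_sd_uM = white_sd_uM,
         drift_sd_uM = drift_sd_uM, cardiac = cardiac,
         respiration = respiration, mayer = mayer,
         global_amp_uM = global_amp_uM,
         spike_rate_per_min = spike_rate_per_min,
         spike_amp_od = spike_amp_od, spike_width_s = spike_width_s,
         shift_rate_per_min = shift_rate_per_min,
         shift_amp_od = shift_amp_od,
         hbr_ratio = hbr_ratio,
         subject_effect_sd_uM = subject_effect_sd_uM,
         baseline_intensity = baseline_intensity,
         seed = as.integer(seed)),
    class = "sim_truth"
  )
}

# Small deterministic sub-seed for (subject, task, run) streams; kept well
# below 2^31.
derive_seed <- function(seed, subject = 0L, run = 0L, stream = 0L) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2039 +
               subject * 1013 + run * 97 + stream * 7) %% 2147483647L
}

new_conc <- function(hbo, hbr, fs, kept = NULL, events = NULL, meta = list()) {
  if (!all(dim(hbo) == dim(hbr))) {
    stop_fcoi("hbo/hbr must have the same shape", "fcoi_validation_error")
  }
  if (is.null(kept)) kept <- rep(TRUE, ncol(hbo))
  structure(list(hbo = hbo, hbr = hbr, fs = fs, kept = kept,
                 events = events, meta = meta),
            class = "nirs_conc")
}

#' @export
print.nirs_conc <- function(x, ...) {
  cat(sprintf("<nirs_conc> %d samples x %d channels (%d kept), %.3g Hz\n",
              nrow(x$hbo), ncol(x$hbo), sum(x$kept), x$fs))
  invisible(x)
}

#' Noise-free simulated concentration signal
#'
#' Per channel, the HbO time course is the sum over blocks of the condition
#' amplitude times a boxcar convolved with the canonical HRF (kernel
#' normalised to unit sum, so a sustained response plateaus at the stated
#' amplitude). HbR is `hbr_ratio` times HbO. The effect used is
#' `language_effect_uM` for the language task and `md_effect_uM` for the MD
#' task; the preferred condition gets `base_amp_uM + effect`, the other
#' condition `base_amp_uM`.
#'
#' @param truth [sim_truth()].
#' @param events event data frame from [make_design()].
#' @param task [task_spec()].
#' @param n_time number of samples; @param fs sampling rate (Hz).
#' @param subject_effect_uM optional per-subject additive deviation of the
#'   selective channels' effect (micromolar).
#' @return a `nirs_conc` (concentrations in molar units).
#' @export
simulate_conc <- function(truth, events, task, n_time, fs,
                          subject_effect_uM = 0) {
  tmax <- (n_time - 1) / fs
  if (any(events$onset_s + events$duration_s > tmax + 1e-9)) {
    stop_fcoi("events fall outside the run span", "fcoi_validation_error")
  }
  kern <- hrf_kernel(fs)
  regs <- sapply(task$condition_labels, function(cc) {
    box <- numeric(n_time)
    ev <- events[events$condition == cc, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset_s[i] * fs) + 1
      i1 <- min(n_time, ceiling((ev$onset_s[i] + ev$duration_s[i]) * fs))
      box[i0:i1] <- 1
    }
    y <- stats::filter(c(rep(0, length(kern) - 1), box), kern,
                       method = "convolution", sides = 1)
    as.numeric(y)[-seq_len(length(kern) - 1)]
  })
  eff <- if (task$task_id == "md") truth$md_effect_uM else
    truth$language_effect_uM
  sel <- eff > 0
  eff[sel] <- pmax(0, eff[sel] + subject_effect_uM)
  amp <- sapply(task$condition_labels, function(cc) {
    extra <- if (cc == task$preferred_condition) eff else numeric(length(eff))
    (truth$base_amp_uM + extra) * 1e-6
  })                                         # n_ch x n_cond, molar
  hbo <- regs %*% t(amp)
  new_conc(hbo, truth$hbr_ratio * hbo, fs, events = events)
}

# Smooth spatial weights over the scalp: a Gaussian random field in angular
# distance with correlation length well above the PCA filter's 46-degree
# kernel, offset to be near-uniform.
global_weights <- function(channel_pos, sd_frac = 0.3, corr_deg = 120) {
  n <- nrow(channel_pos)
  u <- channel_pos - matrix(colMeans(channel_pos), n, 3, byrow = TRUE)
  u <- u / pmax(sqrt(rowSums(u^2)), 1e-9)
  ang <- acos(pmax(pmin(tcrossprod(u), 1), -1))
  K <- exp(-0.5 * (ang / (corr_deg * pi / 180))^2)
  z <- as.numeric(K %*% rnorm(n))
  z <- z / max(sd(z), 1e-12)
  1 + sd_frac * z
}

#' Add physiological noise, drifts, and a global component
#'
#' Adds, in concentration units: white noise, a slow random-walk drift,
#' cardiac/respiratory/Mayer-wave sinusoids (channel-specific phases), and a
#' shared low-frequency global component whose channel weights vary smoothly
#' over the scalp. Motion artifacts live in the optical-density domain, so
#' they are only *scheduled* here (seeded Poisson event times, recorded in the
#' artifact manifest) and injected by [conc_to_intensity()].
#'
#' HbR receives the structured noise scaled by `hbr_ratio` plus its own white
#' noise at half the HbO SD.
#'
#' @param conc `nirs_conc` signal part.
#' @param truth [sim_truth()].
#' @param channel_pos channel coordinate matrix (for the global field).
#' @param seed integer seed for this run's noise stream.
#' @return `nirs_conc` with attribute `"manifest"`: a data frame of scheduled
#'   motion events (`type`, `time_s`, `amp_od`).
#' @export
add_noise_and_artifacts <- function(conc, truth, channel_pos, seed = 1L) {
  set.seed(derive_seed(seed, stream = 3L))
  n_t <- nrow(conc$hbo); n_ch <- ncol(conc$hbo); fs <- conc$fs
  tt <- (seq_len(n_t) - 1) / fs
  uM <- 1e-6

  structured <- matrix(0, n_t, n_ch)
  # slow drift: random walk rescaled to the target SD over the run
  if (truth$drift_sd_uM > 0) {
    dr <- apply(matrix(rnorm(n_t * n_ch), n_t), 2, cumsum)
    dr <- scale(dr, center = TRUE, scale = apply(dr, 2, sd) /
                  (truth$drift_sd_uM * uM))
    structured <- structured + dr
  }
  # systemic sinusoids with per-channel phase and slight frequency jitter
  for (osc in list(truth$cardiac, truth$respiration, truth$mayer)) {
    if (osc[2] > 0) {
      f <- osc[1] * (1 + rnorm(1, 0, 0.02))
      ph <- runif(n_ch, 0, 2 * pi)
      structured <- structured +
        (osc[2] * uM) * sin(outer(2 * pi * f * tt, ph, `+`))
    }
  }
  # shared global component, band-limited below ~0.1 Hz
  if (truth$global_amp_uM > 0) {
    g <- rnorm(n_t)
    g <- filtfilt_bw(butter_design(3, 0.1, fs, "low"), g)
    g <- (g - mean(g)) / max(sd(g), 1e-12)
    w <- global_weights(channel_pos)
    structured <- structured + (truth$global_amp_uM * uM) * outer(g, w)
  }

  hbo <- conc$hbo + structured +
    matrix(rnorm(n_t * n_ch, 0, truth$white_sd_uM * uM), n_t)
  hbr <- conc$hbr + truth$hbr_ratio * structured +
    matrix(rnorm(n_t * n_ch, 0, 0.5 * truth$white_sd_uM * uM), n_t)

  dur_min <- n_t / fs / 60
  sched <- function(rate, type, amp) {
    k <- stats::rpois(1, rate * dur_min)
    if (k == 0) return(NULL)
    data.frame(type = type,
               time_s = sort(runif(k, 5, n_t / fs - 5)),
               amp_od = amp * runif(k, 0.5, 1.5) * sample(c(-1, 1), k, TRUE))
  }
  manifest <- rbind(
    sched(truth$spike_rate_per_min, "spike", truth$spike_amp_od),
    sched(truth$shift_rate_per_min, "shift", truth$shift_amp_od)
  )
  if (is.null(manifest)) {
    manifest <- data.frame(type = character(), time_s = numeric(),
                           amp_od = numeric())
  }
  out <- new_conc(hbo, hbr, fs, conc$kept, conc$events, conc$meta)
  attr(out, "manifest") <- manifest
  out
}

# OD-domain artifact waveform for one channel/wavelength series.
artifact_od <- function(n_t, fs, manifest, width_s) {
  a <- numeric(n_t)
  if (is.null(manifest) || nrow(manifest) == 0) return(a)
  tt <- (seq_len(n_t) - 1) / fs
  for (i in seq_len(nrow(manifest))) {
    if (manifest$type[i] == "spike") {
      a <- a + manifest$amp_od[i] *
        exp(-0.5 * ((tt - manifest$time_s[i]) / width_s)^2)
    } else {
      a <- a + manifest$amp_od[i] * (tt >= manifest$time_s[i])
    }
  }
  a
}

#' Render concentrations as raw intensities (forward Beer-Lambert)
#'
#' Computes `dOD(lambda, t) = (eps_hbo * dHbO + eps_hbr * dHbR) * d_cm *
#' ppf(lambda)` per channel, adds any scheduled motion artifacts in the OD
#' domain, and converts to detector intensities `I = baseline * exp(-dOD)`.
#' The output is strictly positive by construction and round-trips through
#' the preprocessing inversion exactly (2 wavelengths) or exactly for
#' consistent systems (3 wavelengths).
#'
#' @param conc `nirs_conc` (molar units).
#' @param montage `nirs_montage`.
#' @param extinction from [extinction_table()].
#' @param truth [sim_truth()] (supplies baseline intensity and spike width).
#' @param manifest optional artifact schedule (defaults to the one attached
#'   to `conc` by [add_noise_and_artifacts()]).
#' @param ppf partial pathlength factor per wavelength.
#' @param meta named list (`subject_id`, `task_id`, `run_index`).
#' @return a `nirs_run` recording.
#' @export
conc_to_intensity <- function(conc, montage, extinction, truth,
                              manifest = attr(conc, "manifest"),
                              ppf = 1.0, meta = list()) {
  if (any(truth$baseline_intensity <= 0)) {
    stop_fcoi("baseline intensity must be positive", "fcoi_config_error")
  }
  n_t <- nrow(conc$hbo); n_ch <- ncol(conc$hbo)
  n_wl <- length(montage$wavelengths_nm)
  ppf <- rep_len(ppf, n_wl)
  d_cm <- montage$separation_mm / 10
  art <- if (!is.null(manifest) && nrow(manifest) > 0) {
    artifact_od(n_t, conc$fs, manifest, truth$spike_width_s)
  } else numeric(n_t)
  intensity <- array(0, dim = c(n_t, n_ch, n_wl))
  for (w in seq_len(n_wl)) {
    od <- (conc$hbo * extinction$eps_hbo[w] +
             conc$hbr * extinction$eps_hbr[w]) *
      matrix(d_cm * ppf[w], n_t, n_ch, byrow = TRUE)
    od <- od + art # shared head-motion artifact
    intensity[, , w] <- truth$baseline_intensity * exp(-od)
  }
  new_run(meta$subject_id %||% "sim", meta$task_id %||% "language",
          meta$run_index %||% 1L, intensity, conc$events, montage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_run <- function(subject_id, task_id, run_index, intensity, events,
                    montage) {
  stopifnot(length(dim(intensity)) == 3L)
  run_duration <- (dim(intensity)[1] - 1) / montage$sampling_rate_hz
  validate_events(events, run_duration)
  structure(
    list(subject_id = subject_id, task_id = task_id,
         run_index = as.integer(run_index),
         intensity = intensity, events = events, montage = montage,
         fs = montage$sampling_rate_hz),
    class = "nirs_run"
  )
}

#' @export
print.nirs_run <- function(x, ...) {
  cat(sprintf(
    "<nirs_run> subject %s, task %s, run %d: %d samples x %d channels x %d wavelengths\n",
    x$subject_id, x$task_id, x$run_index, dim(x$intensity)[1],
    dim(x$intensity)[2], dim(x$intensity)[3]))
  invisible(x)
}

#' Simulate a single run end to end
#'
#' Convenience wrapper: design -> noise-free signal -> noise and artifacts ->
#' forward Beer-Lambert. Fully determined by `(truth$seed, subject, run)`.
#'
#' @inheritParams simulate_conc
#' @param montage `nirs_montage`; @param extinction extinction table.
#' @param subject_index,run_index indices; @param subject_id label.
#' @param subject_effect_uM per-subject effect deviation.
#' @param noise logical; `FALSE` produces the noise-free signal rendered to
#'   intensity (used by forward/inverse validation).
#' @return `nirs_run` with attribute `"manifest"`.
#' @export
simulate_run <- function(truth, montage, task, subject_index, run_index,
                         subject_id = sprintf("S%02d", subject_index),
                         extinction = extinction_table(montage$wavelengths_nm),
                         subject_effect_uM = 0, noise = TRUE) {
  events <- make_design(task, subject_index, run_index)
  dur <- attr(events, "run_duration_s")
  fs <- montage$sampling_rate_hz
  n_time <- ceiling(dur * fs) + 1
  conc <- simulate_conc(truth, events, task, n_time, fs, subject_effect_uM)
  manifest <- NULL
  if (noise) {
    conc <- add_noise_and_artifacts(
      conc, truth, montage$channel_pos,
      seed = derive_seed(truth$seed, subject_index, run_index,
                         stream = if (task$task_id == "md") 1L else 0L))
    manifest <- attr(conc, "manifest")
  }
  run <- conc_to_intensity(conc, montage, extinction, truth,
                           manifest = manifest,
                           meta = list(subject_id = subject_id,
                                       task_id = task$task_id,
                                       run_index = run_index))
  attr(run, "manifest") <- manifest
  run
}

#' Scenario description for a simulated cohort
#'
#' The packaged scenarios mirror the two experiments: `"adult"` is 20 subjects
#' with 8 language runs and 4 MD runs on the 79-channel montage; `"toddler"`
#' is 22 subjects with 4 runs of each task on the 81-channel montage. The
#' `compact` variant keeps the block designs and effect sizes but shrinks the
#' world for fast repeated cohort simulation: a 20-channel montage containing
#' two disjoint search spaces (7 + 6 channels) plus filler channels, 12
#' subjects, and 4 runs per task.
#'
#' In the default truth one channel per search space is language-selective and
#' a different one is MD-selective. `language_rifg` / `md_lifg` toggles encode
#' the developmental pattern: setting them to `FALSE` zeroes the RIFG language
#' effect and the LIFG MD effect (toddler-like scenario).
#'
#' @param population `"adult"` or `"toddler"`.
#' @param n_subjects cohort size.
#' @param compact logical, use the scaled-down world.
#' @param effect_uM injected effect amplitude (micromolar) for both contrasts.
#' @param language_rifg,md_lifg logicals; zero the respective effects.
#' @param seed master seed.
#' @param ... further overrides passed to [sim_truth()].
#' @return list of class `sim_scenario`.
#' @export
scenario <- function(population = c("adult", "toddler"),
                     n_subjects = NULL, compact = FALSE, effect_uM = 0.5,
                     language_rifg = TRUE, md_lifg = TRUE, seed = 1L, ...) {
  population <- match.arg(population)
  tasks <- default_tasks(population)
  if (compact) {
    # scaled-down world: search spaces keep their published sizes (7 + 6
    # adult, 5 + 5 toddler) plus three filler channels; patches keep the
    # real probe's ~3 cm channel spacing so the spatial filter sees a
    # comparable channel density
    lifg_dir <- c(-0.77, 0.55, 0.33)
    rifg_dir <- c(0.77, 0.55, 0.33)
    mid_dir <- c(0, 0.85, 0.53)
    if (population == "adult") {
      pos <- rbind(patch_positions(lifg_dir, 7),
                   patch_positions(rifg_dir, 6),
                   patch_positions(mid_dir, 3))
      mont <- montage(c(760, 850), pos, sampling_rate_hz = 11)
      spaces <- list(LIFG = search_space("LIFG", 1:7, mont),
                     RIFG = search_space("RIFG", 8:13, mont))
    } else {
      pos <- rbind(patch_positions(lifg_dir, 5),
                   patch_positions(rifg_dir, 5),
                   patch_positions(mid_dir, 3))
      mont <- montage(c(730, 808, 850), pos, sampling_rate_hz = 11)
      spaces <- list(LIFG = search_space("LIFG", 1:5, mont),
                     RIFG = search_space("RIFG", 6:10, mont))
    }
    if (is.null(n_subjects)) n_subjects <- 12L
    tasks$language$runs_expected <- 4L
    tasks$md$runs_expected <- 4L
  } else {
    mont <- if (population == "adult") adult_montage() else toddler_montage()
    spaces <- default_search_spaces(population, mont)
    if (is.null(n_subjects)) {
      n_subjects <- if (population == "adult") 20L else 22L
    }
  }
  pick <- function(space, k) space$member_channels[k]
  lang_ch <- c(pick(spaces$LIFG, 2), if (language_rifg) pick(spaces$RIFG, 2))
  md_ch <- c(if (md_lifg) pick(spaces$LIFG, 4), pick(spaces$RIFG, 4))
  truth <- sim_truth(mont$n_channels,
                     language_channels = lang_ch, md_channels = md_ch,
                     language_effect_uM = effect_uM, md_effect_uM = effect_uM,
                     seed = seed, ...)
  structure(
    list(population = population, n_subjects = as.integer(n_subjects),
         montage = mont, spaces = spaces, tasks = tasks, truth = truth,
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Simulate a full cohort
#'
#' Generates every run of every subject for both tasks of a scenario, plus a
#' ground-truth manifest (selective channels, effects, artifact schedules,
#' seed). Identical seeds yield identical cohorts.
#'
#' @param scn a [scenario()].
#' @return list with elements `runs` (list of `nirs_run`), `manifest`,
#'   and `scenario`.
#' @export
simulate_cohort <- function(scn) {
  truth <- scn$truth
  runs <- list()
  artifact_log <- list()
  set.seed(derive_seed(truth$seed, stream = 9L))
  subj_dev <- rnorm(scn$n_subjects, 0, truth$subject_effect_sd_uM)
  for (s in seq_len(scn$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (task in scn$tasks) {
      for (r in seq_len(task$runs_expected)) {
        run <- simulate_run(truth, scn$montage, task, s, r, subject_id = sid,
                            subject_effect_uM = subj_dev[s])
        key <- sprintf("%s_%s_r%d", sid, task$task_id, r)
        runs[[key]] <- run
        mf <- attr(run, "manifest")
        if (!is.null(mf) && nrow(mf) > 0) {
          mf$run <- key
          artifact_log[[key]] <- mf
        }
      }
    }
  }
  manifest <- list(
    population = scn$population,
    n_subjects = scn$n_subjects,
    seed = truth$seed,
    language_channels = truth$language_channels,
    md_channels = truth$md_channels,
    language_effect_uM = truth$language_effect_uM[truth$language_channels],
    md_effect_uM = truth$md_effect_uM[truth$md_channels],
    subject_effect_uM = subj_dev,
    artifacts = if (length(artifact_log)) do.call(rbind, artifact_log) else
      data.frame()
  )
  list(runs = runs, manifest = manifest, scenario = scn)
}
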