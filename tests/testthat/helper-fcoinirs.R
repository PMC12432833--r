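# Shared fixtures, built in code.

# tiny montage: n channels on a deterministic scalp layout, 2 wavelengths,
# 11 Hz, 30 mm separations
tiny_montage <- function(n = 6, wavelengths = c(760, 850)) {
  montage(wavelengths, fcoinirs:::fibonacci_scalp(n), sampling_rate_hz = 11)
}

# constant-intensity recording with a single event
tiny_run <- function(montage = tiny_montage(), n_time = 400,
                     baseline = 1e5, events = NULL,
                     subject = "S01", task = "language", run = 1L) {
  if (is.null(events)) {
    events <- data.frame(condition = "intact", onset_s = 1, duration_s = 2)
  }
  n_wl <- length(montage$wavelengths_nm)
  intensity <- array(baseline, c(n_time, montage$n_channels, n_wl))
  fcoinirs:::new_run(subject, task, run, intensity, events, montage)
}

# direct (independent) discrete convolution of a boxcar with a kernel,
# written with an explicit loop -- oracle for the simulator's regressors
oracle_boxcar_response <- function(onset_s, duration_s, amp, n_time, fs,
                                   kernel) {
  box <- numeric(n_time)
  i0 <- floor(onset_s * fs) + 1
  i1 <- min(n_time, ceiling((onset_s + duration_s) * fs))
  box[i0:i1] <- amp
  out <- numeric(n_time)
  for (t in seq_len(n_time)) {
    jmax <- min(t, length(kernel))
    out[t] <- sum(kernel[seq_len(jmax)] * box[t - seq_len(jmax) + 1])
  }
  out
}

# block-level response table generated directly (no pipeline): one subject
# block table for selection/statistics unit tests
synthetic_block_table <- function(n_subjects = 10, n_runs = 4, channels = 1:5,
                                  task_id = "language",
                                  conditions = c("intact", "degraded"),
                                  effect = 0, effect_channel = channels[1],
                                  noise_sd = 1, blocks_per_cond = 1,
                                  seed = 1) {
  set.seed(seed)
  rows <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subjects)),
                      run_index = seq_len(n_runs),
                      channel_id = channels,
                      block = seq_len(blocks_per_cond),
                      condition = conditions,
                      stringsAsFactors = FALSE)
  rows$task_id <- task_id
  rows$block_index <- rows$block +
    blocks_per_cond * (match(rows$condition, conditions) - 1)
  rows$mean_hbo <- rnorm(nrow(rows), 0, noise_sd) +
    ifelse(rows$condition == conditions[1] &
             rows$channel_id == effect_channel, effect, 0)
  rows$mean_hbr <- -rows$mean_hbo / 3
  rows[, c("subject_id", "task_id", "run_index", "channel_id", "block_index",
           "condition", "mean_hbo", "mean_hbr")]
}
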