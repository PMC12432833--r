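# Degraded-speech stimulus construction and minimal WAV I/O.
#
# The degraded control keeps the low-frequency speech content and the
# prosodic/rhythmic amplitude envelope of the intact clip while destroying
# intelligibility: low-pass filtered speech plus an envelope-modulated,
# time-shuffled noise track.

#' Construct an audio clip
#'
#' @param samples numeric waveform; normalised to `|x| <= 1` if needed.
#' @param rate_hz positive integer sampling rate.
#' @param check_localizer warn when the duration is outside the 17-20 s range
#'   expected of localizer stimuli.
#' @return object of class `audio_clip` (`samples`, `rate_hz`, `duration_s`).
#' @export
audio_clip <- function(samples, rate_hz, check_localizer = FALSE) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) {
    stop_fcoi("audio samples must be finite", "fcoi_validation_error")
  }
  peak <- max(abs(samples))
  if (peak > 1) samples <- samples / peak
  dur <- length(samples) / rate_hz
  if (check_localizer && (dur < 17 || dur > 20)) {
    warning(sprintf("clip duration %.1f s outside the 17-20 s localizer range",
                    dur))
  }
  structure(list(samples = samples, rate_hz = as.integer(rate_hz),
                 duration_s = dur),
            class = "audio_clip")
}

#' Read / write 16-bit PCM WAV
#'
#' Minimal mono RIFF/WAVE support (16-bit PCM, one channel), sufficient for
#' localizer stimulus files.
#'
#' @param path file path.
#' @return `wav_read` returns an [audio_clip()]; `wav_write` returns `path`
#'   invisibly.
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF" || wave != "WAVE") {
    stop_fcoi("not a RIFF/WAVE file", "fcoi_format_error")
  }
  rate <- NULL; bits <- NULL; n_chan <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", sz / 2, 2, endian = "little",
                     signed = FALSE)
      n_chan <- fmt[2]; rate <- fmt[3] + 65536 * fmt[4]; bits <- fmt[8]
    } else if (id == "data") {
      if (is.null(bits) || bits != 16 || n_chan != 1) {
        stop_fcoi("only 16-bit mono PCM WAV is supported",
                  "fcoi_format_error")
      }
      samples <- readBin(con, "integer", sz / 2, 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(samples)) stop_fcoi("no data chunk found", "fcoi_format_error")
  audio_clip(samples / 32767, rate)
}

#' @rdname wav_read
#' @param clip [audio_clip()] to write.
#' @export
wav_write <- function(clip, path) {
  x <- pmin(1, pmax(-1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")            # PCM, mono
  writeBin(as.integer(clip$rate_hz), con, 4, endian = "little")
  writeBin(as.integer(clip$rate_hz * 2), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")           # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

# FFT Hilbert transform: analytic-signal magnitude.
analytic_magnitude <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Amplitude envelope of a clip
#'
#' Magnitude of the analytic signal (FFT Hilbert transform), low-pass
#' smoothed. The envelope is non-negative and sampled at the audio rate.
#'
#' @param clip [audio_clip()].
#' @param smoothing_hz low-pass corner applied to the raw magnitude.
#' @return numeric envelope, same length as the clip.
#' @export
amplitude_envelope <- function(clip, smoothing_hz = 20) {
  if (length(clip$samples) == 0) {
    stop_fcoi("empty clip", "fcoi_validation_error")
  }
  env <- analytic_magnitude(clip$samples)
  if (smoothing_hz > 0 && smoothing_hz < clip$rate_hz / 2) {
    env <- filtfilt_bw(butter_design(3, smoothing_hz, clip$rate_hz, "low"),
                       env)
  }
  pmax(env, 0)
}

#' Create a degraded-speech control clip
#'
#' Implements the degradation recipe: the intact clip is low-pass filtered
#' (350 Hz pass-band; filter order chosen for >= 40 dB attenuation an octave
#' above), a noise track is built by randomising the time points of the
#' original audio (seeded uniform permutation of samples, or of short frames
#' via `frame_s`) and multiplying by the intact clip's amplitude envelope,
#' the noise is low-pass filtered (8 kHz pass-band) to soften the highest
#' frequencies, and the two are mixed with the noise RMS set to `noise_ratio`
#' times the filtered-speech RMS -- loud enough to render the result
#' unintelligible while the prosodic rhythm of the original survives in the
#' energy envelope.
#'
#' @param clip [audio_clip()]; rates of at least 22.05 kHz are recommended so
#'   the 8 kHz noise band is representable.
#' @param noise_ratio noise-to-speech RMS ratio.
#' @param seed integer seed for the permutation.
#' @param frame_s 0 for sample-level shuffling (default), otherwise the frame
#'   length in seconds shuffled as units.
#' @param speech_lp_order low-pass order of the 350 Hz speech path.
#' @param parts return the separate speech and noise paths alongside the mix
#'   (used by validation).
#' @return degraded [audio_clip()], same duration and rate as the input; with
#'   `parts = TRUE`, a list `(clip, speech, noise)`.
#' @export
degrade_speech <- function(clip, noise_ratio = 1.0, seed = 1L, frame_s = 0,
                           speech_lp_order = 7, parts = FALSE) {
  x <- clip$samples
  if (all(x == 0)) stop_fcoi("degenerate (all-zero) clip",
                             "fcoi_validation_error")
  fs <- clip$rate_hz
  if (fs < 22050) warning("sampling rates >= 22.05 kHz are recommended")
  speech <- filtfilt_bw(butter_design(speech_lp_order, 350, fs, "low"), x)
  set.seed(as.integer(seed))
  if (frame_s > 0) {
    flen <- max(1L, as.integer(round(frame_s * fs)))
    n_frames <- ceiling(length(x) / flen)
    idx <- unlist(lapply(sample(n_frames), function(f) {
      seq((f - 1L) * flen + 1L, min(f * flen, length(x)))
    }))
    idx <- idx[seq_along(x)]
  } else {
    idx <- sample(length(x))
  }
  noise <- x[idx] * amplitude_envelope(clip)
  if (fs / 2 > 8000) {
    noise <- filtfilt_bw(butter_design(4, 8000, fs, "low"), noise)
  }
  rms <- function(v) sqrt(mean(v^2))
  gain <- noise_ratio * rms(speech) / max(rms(noise), 1e-12)
  out <- speech + gain * noise
  peak <- max(abs(out))
  if (peak > 1) out <- out / peak
  result <- audio_clip(out, fs)
  if (parts) {
    return(list(clip = result, speech = speech, noise = gain * noise,
                shuffled = x[idx]))
  }
  result
}
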