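# Per-run preprocessing chain: raw intensity -> cleaned HbO/HbR.
# Runs are always processed in isolation so that one run's noise cannot skew
# another's normalisation.

#' Prune channels on intensity range and signal-to-noise ratio
#'
#' A channel is kept iff, at every wavelength, its mean raw intensity lies in
#' `d_range` and mean/SD >= `snr_thresh`. A constant channel (SD = 0) has
#' unbounded SNR and is kept if in range. Channels listed in
#' `config$manual_exclude` are dropped with reason `no_cardiac_manual`
#' (visual-inspection exclusions are an explicit user-supplied list; no
#' quantitative cardiac criterion is applied).
#'
#' @param rec `nirs_run`.
#' @param config [preprocess_config()].
#' @return data frame (`channel`, `kept`, `reason`) with reason one of
#'   `ok`, `out_of_range`, `low_snr`, `no_cardiac_manual`.
#' @export
prune_channels <- function(rec, config = preprocess_config()) {
  n_ch <- dim(rec$intensity)[2]
  n_wl <- dim(rec$intensity)[3]
  reason <- rep("ok", n_ch)
  for (ch in seq_len(n_ch)) {
    for (w in seq_len(n_wl)) {
      x <- rec$intensity[, ch, w]
      m <- mean(x)
      if (m < config$d_range[1] || m > config$d_range[2]) {
        reason[ch] <- "out_of_range"
        break
      }
      s <- sd(x)
      if (s > 0 && m / s < config$snr_thresh) {
        reason[ch] <- "low_snr"
        break
      }
    }
  }
  reason[seq_len(n_ch) %in% config$manual_exclude] <- "no_cardiac_manual"
  data.frame(channel = seq_len(n_ch), kept = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

# Replace non-positive samples on kept channels by the smallest positive
# observed value of that channel/wavelength; returns the recording plus a
# count of corrected samples.
guard_negative_intensity <- function(rec, mask) {
  n_fixed <- 0L
  for (ch in which(mask$kept)) {
    for (w in seq_len(dim(rec$intensity)[3])) {
      x <- rec$intensity[, ch, w]
      bad <- x <= 0
      if (any(bad)) {
        if (all(bad)) {
          stop_fcoi(sprintf("channel %d has no positive samples", ch),
                    "fcoi_numeric_error")
        }
        x[bad] <- min(x[!bad])
        rec$intensity[, ch, w] <- x
        n_fixed <- n_fixed + sum(bad)
      }
    }
  }
  attr(rec, "n_negative_fixed") <- n_fixed
  rec
}

new_od <- function(od, fs, kept) {
  structure(list(od = od, fs = fs, kept = kept), class = "nirs_od")
}

#' Convert raw intensities to optical density changes
#'
#' `dOD(t) = -ln(I(t) / mean_t I(t))` per channel and wavelength (natural
#' log, run-mean reference: the common fNIRS convention). Pruned channels are
#' set to `NA`, never silently zero.
#'
#' @param rec `nirs_run`; @param mask pruning mask from [prune_channels()].
#' @return `nirs_od` with array `od` of shape time x channel x wavelength.
#' @export
intensity_to_od <- function(rec, mask = NULL) {
  dims <- dim(rec$intensity)
  if (is.null(mask)) {
    mask <- data.frame(channel = seq_len(dims[2]), kept = TRUE, reason = "ok")
  }
  od <- array(NA_real_, dims)
  for (ch in which(mask$kept)) {
    for (w in seq_len(dims[3])) {
      x <- rec$intensity[, ch, w]
      if (any(x <= 0)) {
        t_bad <- which(x <= 0)[1]
        stop_fcoi(sprintf(
          "non-positive intensity on kept channel %d (wavelength %d) at sample %d",
          ch, w, t_bad), "fcoi_numeric_error")
      }
      od[, ch, w] <- -log(x / mean(x))
    }
  }
  new_od(od, rec$fs, mask$kept)
}

#' Remove per-channel linear trends
#'
#' Subtracts the least-squares line over the full run from every kept
#' channel/wavelength series; the residual is orthogonal to `[1, t]`.
#'
#' @param od `nirs_od`.
#' @return detrended `nirs_od`.
#' @export
detrend_linear <- function(od) {
  n_t <- dim(od$od)[1]
  if (n_t < 3) stop_fcoi("need at least 3 samples to detrend",
                         "fcoi_validation_error")
  X <- cbind(1, seq_len(n_t))
  Q <- qr.Q(qr(X))
  for (w in seq_len(dim(od$od)[3])) {
    M <- od$od[, od$kept, w, drop = FALSE]
    dim(M) <- c(n_t, sum(od$kept))
    od$od[, od$kept, w] <- M - Q %*% crossprod(Q, M)
  }
  od
}

# Core TDDR iteration on one series: robust reweighting of the temporal
# derivative of the low-frequency part, then reintegration.
tddr_series <- function(x, fs, config, split_design = NULL) {
  if (fs > 2 * config$tddr_split_freq_hz) {
    if (is.null(split_design)) {
      split_design <- butter_design(3, config$tddr_split_freq_hz, fs, "low")
    }
    low <- filtfilt_bw(split_design, x)
    high <- x - low
  } else {
    low <- x
    high <- numeric(length(x))
  }
  d <- diff(low)
  w <- rep(1, length(d))
  mu <- 0
  converged <- FALSE
  for (it in seq_len(config$tddr_max_iter)) {
    mu <- sum(w * d) / sum(w)
    r <- d - mu
    s <- 1.4826 * median(abs(r))
    if (s <= 0) { converged <- TRUE; break }
    dn <- r / (config$tddr_tukey_c * s)
    w_new <- pmax(1 - dn^2, 0)^2
    if (max(abs(w_new - w)) < config$tddr_tol) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  low_c <- cumsum(c(0, w * (d - mu)))
  out <- low_c + high
  out <- out + mean(low) - mean(low_c)
  attr(out, "converged") <- converged
  out
}

#' Motion correction by temporal derivative distribution repair
#'
#' Per channel and wavelength the signal is split at
#' `config$tddr_split_freq_hz`; the low-frequency part's first difference is
#' robustly re-estimated by iteratively reweighted least squares with Tukey
#' biweights (constant `tddr_tukey_c`, tolerance `tddr_tol` on the maximum
#' weight change, at most `tddr_max_iter` iterations), the corrected part is
#' rebuilt by cumulative summation of the weighted deviations, and the
#' high-frequency part is added back. Spikes and step shifts whose
#' derivatives are outliers of the derivative distribution are suppressed
#' without user thresholds; no convergence failure is fatal (the last iterate
#' is used, with a warning).
#'
#' @param od `nirs_od`; @param fs sampling rate (Hz);
#' @param config [preprocess_config()].
#' @return corrected `nirs_od`.
#' @export
correct_motion_tddr <- function(od, fs = od$fs,
                                config = preprocess_config()) {
  n_nonconv <- 0L
  split_design <- if (fs > 2 * config$tddr_split_freq_hz) {
    butter_design(3, config$tddr_split_freq_hz, fs, "low")
  }
  for (ch in which(od$kept)) {
    for (w in seq_len(dim(od$od)[3])) {
      y <- tddr_series(od$od[, ch, w], fs, config, split_design)
      if (!isTRUE(attr(y, "converged"))) n_nonconv <- n_nonconv + 1L
      od$od[, ch, w] <- y
    }
  }
  if (n_nonconv > 0) {
    warning(sprintf(
      "TDDR reweighting did not converge for %d series; last iterates used",
      n_nonconv))
  }
  od
}

#' Zero-phase Butterworth band-pass filter
#'
#' Cascaded low-pass (order `lowpass_order`, corner `high_cut_hz`) and
#' high-pass (order `highpass_order`, corner `low_cut_hz`) Butterworth
#' filters, each applied forward and backward so that no phase distortion is
#' introduced (the effective response is the squared magnitude). Defaults
#' pass 0.01-0.09 Hz, removing slow drifts and cardiac/respiratory
#' oscillations.
#'
#' @inheritParams correct_motion_tddr
#' @return filtered `nirs_od`.
#' @export
bandpass_filter <- function(od, fs = od$fs, config = preprocess_config()) {
  if (config$high_cut_hz >= fs / 2) {
    stop_fcoi("high_cut_hz must be below the Nyquist frequency",
              "fcoi_config_error")
  }
  lp <- butter_design(config$lowpass_order, config$high_cut_hz, fs, "low")
  hp <- butter_design(config$highpass_order, config$low_cut_hz, fs, "high")
  keep <- which(od$kept)
  n_t <- dim(od$od)[1]
  for (w in seq_len(dim(od$od)[3])) {
    M <- od$od[, keep, w, drop = FALSE]
    dim(M) <- c(n_t, length(keep))
    M <- filtfilt_bw(lp, M, dc_gain1 = TRUE)
    M <- filtfilt_bw(hp, M, dc_gain1 = FALSE)
    od$od[, keep, w] <- M
  }
  od
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per channel, `dOD(lambda) = (eps_hbo(lambda) dHbO +
#' eps_hbr(lambda) dHbR) * d_cm * ppf(lambda)` for `(dHbO, dHbR)`: the exact
#' 2x2 inverse for two wavelengths, the least-squares (normal-equations)
#' solution for three. With the default `ppf = 1` concentrations are
#' molar-equivalent up to the unknown differential pathlength scaling, which
#' cancels in every contrast-based analysis.
#'
#' @param od `nirs_od`; @param montage `nirs_montage`;
#' @param extinction from [extinction_table()];
#' @param config [preprocess_config()].
#' @return `nirs_conc` (pruned channels `NA`).
#' @export
od_to_concentration <- function(od, montage,
                                extinction =
                                  extinction_table(montage$wavelengths_nm),
                                config = preprocess_config()) {
  n_wl <- length(montage$wavelengths_nm)
  if (n_wl < 2) stop_fcoi("need at least 2 wavelengths", "fcoi_config_error")
  if (nrow(extinction) != n_wl) {
    stop_fcoi("extinction table does not match montage wavelengths",
              "fcoi_config_error")
  }
  ppf <- rep_len(config$ppf, n_wl)
  M <- as.matrix(extinction[, c("eps_hbo", "eps_hbr")]) * ppf
  if (kappa(M, exact = TRUE) > 1e10) {
    stop_fcoi("extinction system is ill-conditioned", "fcoi_config_error")
  }
  Minv <- if (n_wl == 2) solve(M) else solve(crossprod(M), t(M))
  n_t <- dim(od$od)[1]; n_ch <- dim(od$od)[2]
  hbo <- matrix(NA_real_, n_t, n_ch)
  hbr <- matrix(NA_real_, n_t, n_ch)
  d_cm <- montage$separation_mm / 10
  for (ch in which(od$kept)) {
    odc <- matrix(od$od[, ch, ], n_t, n_wl) / d_cm[ch]
    cc <- odc %*% t(Minv)
    hbo[, ch] <- cc[, 1]
    hbr[, ch] <- cc[, 2]
  }
  new_conc(hbo, hbr, od$fs, kept = od$kept)
}

#' PCA-based spatial filter for global systemic signals
#'
#' Removes diffuse, scalp-wide components (heart rate, respiration, blood
#' pressure waves) while preserving focal activity. Channel positions are
#' projected to a head-centred unit sphere; the concentration matrix is
#' decomposed by SVD and each spatial loading vector is smoothed with a
#' Gaussian kernel in pairwise angular distance (`sigma_deg`). The
#' reconstruction from smoothed loadings estimates the spatially smooth
#' (global) signal, which is subtracted; spatially sharp structure survives
#' because smoothing dilutes focal loadings. Applied separately per
#' chromophore. With fewer than 3 kept channels the filter is skipped with a
#' warning.
#'
#' @param conc `nirs_conc`; @param channel_pos channel coordinates (mm);
#' @param sigma_deg Gaussian kernel width in degrees of angular distance.
#' @return filtered `nirs_conc`.
#' @export
remove_global_pca <- function(conc, channel_pos, sigma_deg = 46) {
  keep <- which(conc$kept)
  if (length(keep) < 3) {
    warning("fewer than 3 kept channels: PCA spatial filter skipped")
    return(conc)
  }
  pos <- channel_pos[keep, , drop = FALSE]
  u <- pos - matrix(colMeans(pos), nrow(pos), 3, byrow = TRUE)
  u <- u / pmax(sqrt(rowSums(u^2)), 1e-9)
  ang <- acos(pmax(pmin(tcrossprod(u), 1), -1))
  K <- exp(-0.5 * (ang / (sigma_deg * pi / 180))^2)
  K <- K / rowSums(K)
  for (chrom in c("hbo", "hbr")) {
    X <- conc[[chrom]][, keep, drop = FALSE]
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd(Xc)
    V_s <- K %*% sv$v
    global <- sv$u %*% (sv$d * t(V_s))
    conc[[chrom]][, keep] <- Xc - global + matrix(mu, nrow(X), length(keep),
                                                  byrow = TRUE)
  }
  conc
}

#' Run the full preprocessing chain on one recording
#'
#' Applies, in order: channel pruning, negative-intensity guard, optical
#' density conversion, linear detrending, TDDR motion correction, band-pass
#' filtering, Beer-Lambert inversion, and the PCA spatial filter -- each run
#' processed in isolation. Individual steps can be disabled through the
#' config (used by forward/inverse validation); the provenance log attached
#' to the result records every executed step and its parameters.
#'
#' @param rec `nirs_run`; @param config [preprocess_config()].
#' @return `nirs_conc` carrying the run's events and identifiers, with
#'   attributes `mask` (pruning mask) and `provenance` (ordered step log).
#'   If every channel was pruned the run is flagged `usable = FALSE` rather
#'   than raising an error.
#' @export
preprocess_run <- function(rec, config = preprocess_config()) {
  prov <- list()
  log_step <- function(name, ...) {
    prov[[length(prov) + 1]] <<- c(list(step = name), list(...))
  }

  mask <- prune_channels(rec, config)
  log_step("prune_channels", d_range = config$d_range,
           snr_thresh = config$snr_thresh,
           n_pruned = sum(!mask$kept))
  if (!any(mask$kept)) {
    conc <- new_conc(matrix(NA_real_, dim(rec$intensity)[1],
                            dim(rec$intensity)[2]),
                     matrix(NA_real_, dim(rec$intensity)[1],
                            dim(rec$intensity)[2]),
                     rec$fs, kept = mask$kept, events = rec$events,
                     meta = run_meta(rec))
    attr(conc, "mask") <- mask
    attr(conc, "usable") <- FALSE
    attr(conc, "provenance") <- prov
    return(conc)
  }

  rec <- guard_negative_intensity(rec, mask)
  log_step("negative_guard", n_fixed = attr(rec, "n_negative_fixed"))

  od <- intensity_to_od(rec, mask)
  log_step("intensity_to_od", reference = "run mean", log = "natural")

  od <- detrend_linear(od)
  log_step("detrend_linear")

  if (config$run_tddr) {
    od <- correct_motion_tddr(od, rec$fs, config)
    log_step("correct_motion_tddr", tukey_c = config$tddr_tukey_c,
             split_freq_hz = config$tddr_split_freq_hz)
  }
  if (config$run_bandpass) {
    od <- bandpass_filter(od, rec$fs, config)
    log_step("bandpass_filter", band_hz = c(config$low_cut_hz,
                                            config$high_cut_hz),
             orders = c(config$lowpass_order, config$highpass_order))
  }

  extinction <- extinction_table(rec$montage$wavelengths_nm)
  conc <- od_to_concentration(od, rec$montage, extinction, config)
  log_step("od_to_concentration", ppf = config$ppf)

  if (config$run_pca) {
    conc <- remove_global_pca(conc, rec$montage$channel_pos,
                              config$pca_sigma_deg)
    log_step("remove_global_pca", sigma_deg = config$pca_sigma_deg)
  }

  conc$events <- rec$events
  conc$meta <- run_meta(rec)
  attr(conc, "mask") <- mask
  attr(conc, "usable") <- TRUE
  attr(conc, "provenance") <- prov
  conc
}

run_meta <- function(rec) {
  list(subject_id = rec$subject_id, task_id = rec$task_id,
       run_index = rec$run_index)
}
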