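test_that("channel pruning applies the intensity-range and SNR rules", {
  m <- tiny_montage(4)
  rec <- tiny_run(m, n_time = 200, baseline = 1e5)
  set.seed(1)
  # ch1: mean 5e2 at one wavelength -> out of range
  rec$intensity[, 1, 1] <- 5e2
  # ch2: constant 1e5 (SD 0) -> unbounded SNR, kept
  # ch3: mean 1e5, SD 2.5e4 -> SNR 4 < 5 -> low_snr
  n <- dim(rec$intensity)[1]
  wiggle <- rep(c(-1, 1), length.out = n)
  rec$intensity[, 3, 1] <- 1e5 + 2.5e4 * wiggle
  mask <- prune_channels(rec)
  expect_false(mask$kept[1]); expect_equal(mask$reason[1], "out_of_range")
  expect_true(mask$kept[2])
  expect_false(mask$kept[3]); expect_equal(mask$reason[3], "low_snr")
  expect_true(mask$kept[4])
  # manual exclusion list
  mask2 <- prune_channels(rec, preprocess_config(manual_exclude = 4))
  expect_equal(mask2$reason[4], "no_cardiac_manual")
  expect_false(mask2$kept[4])
  # all pruned: unusable run flag, not an exception
  rec$intensity[] <- 1
  conc <- preprocess_run(rec)
  expect_false(attr(conc, "usable"))
  expect_true(all(is.na(conc$hbo)))
})

test_that("optical density conversion is exact and scale-invariant", {
  m <- tiny_montage(2)
  rec <- tiny_run(m, n_time = 100, baseline = 1e5)
  od <- intensity_to_od(rec)
  expect_true(all(od$od == 0))
  # scaling a channel's intensity leaves OD unchanged
  rec2 <- rec
  set.seed(2)
  rec2$intensity[, 1, 1] <- exp(rnorm(100, log(1e5), 0.05))
  od_a <- intensity_to_od(rec2)
  rec3 <- rec2
  rec3$intensity[, 1, 1] <- 7.3 * rec2$intensity[, 1, 1]
  od_b <- intensity_to_od(rec3)
  expect_equal(od_a$od[, 1, 1], od_b$od[, 1, 1], tolerance = 1e-12)
  # two-level signal: OD difference equals the log ratio exactly
  rec4 <- rec
  lv <- rep(c(1, exp(-0.1)), each = 50) * 2e4
  rec4$intensity[, 2, 2] <- lv
  od4 <- intensity_to_od(rec4)
  expect_equal(od4$od[60, 2, 2] - od4$od[10, 2, 2], 0.1, tolerance = 1e-12)
  # non-positive sample on a kept channel is a numeric error naming it
  rec5 <- rec
  rec5$intensity[17, 1, 1] <- 0
  err <- tryCatch(intensity_to_od(rec5), error = function(e) e)
  expect_s3_class(err, "fcoi_numeric_error")
  expect_match(conditionMessage(err), "channel 1")
  expect_match(conditionMessage(err), "17")
})

test_that("linear detrending annihilates lines and matches normal equations", {
  m <- tiny_montage(2)
  n <- 300
  t_i <- seq_len(n)
  od <- fcoinirs:::new_od(array(0, c(n, 2, 2)), 11, rep(TRUE, 2))
  od$od[, 1, 1] <- 3 + 0.01 * t_i
  sinus <- sin(2 * pi * 0.05 * t_i / 11)
  od$od[, 2, 1] <- sinus + 1 - 0.002 * t_i
  dt <- detrend_linear(od)
  expect_lt(max(abs(dt$od[, 1, 1])), 1e-10)
  # independent least-squares oracle via the normal equations
  X <- cbind(1, t_i)
  beta <- solve(t(X) %*% X, t(X) %*% sinus)
  expect_equal(dt$od[, 2, 1], as.numeric(sinus - X %*% beta),
               tolerance = 1e-10)
  # residual orthogonal to [1, t]
  expect_lt(abs(sum(dt$od[, 2, 1])), 1e-8)
  expect_lt(abs(sum(dt$od[, 2, 1] * t_i)) / n, 1e-8)
})

test_that("TDDR repairs spikes and steps while preserving smooth signals", {
  # Stylised fNIRS OD world: a dominant Mayer-wave oscillation (which sets
  # the derivative scale TDDR estimates robustly) plus hemodynamic block
  # responses. Artifact metrics are taken through TDDR followed by the
  # band-pass, the cascade in which TDDR is deployed: TDDR repairs the
  # sub-split-frequency content and the band-pass removes the sharp residue.
  fs <- 11
  n <- 2420
  tt <- (seq_len(n) - 1) / fs
  cfg <- preprocess_config()
  td <- function(x) fcoinirs:::tddr_series(x, fs, cfg)
  bp <- function(x) {
    od <- fcoinirs:::new_od(array(x, c(n, 1, 1)), fs, TRUE)
    bandpass_filter(od, fs, cfg)$od[, 1, 1]
  }
  kern <- fcoinirs:::hrf_kernel(fs)
  mk_resp <- function(on) {
    box <- as.numeric(tt >= on & tt < on + 30)
    y <- stats::filter(c(rep(0, length(kern) - 1), box), kern,
                       method = "convolution", sides = 1)
    as.numeric(y)[-seq_len(length(kern) - 1)]
  }
  base <- 0.5 * sin(2 * pi * 0.1 * tt + 0.7) + mk_resp(30) + mk_resp(170)

  # artifact-free smooth signal passes nearly unchanged through TDDR alone
  expect_gt(cor(td(base), base), 0.99)

  sig_sd <- 1.4826 * mad(base, constant = 1)
  ref <- bp(td(base))
  bcm <- function(x, on) { # baseline-corrected block mean, as the pipeline
    mean(x[tt >= on + 5 & tt < on + 30]) - mean(x[tt >= on - 2 & tt < on])
  }

  # 10 robust-SD motion spike midway between the blocks: peak residual < 10 %
  spike <- 10 * sig_sd * exp(-0.5 * ((tt - 100) / 0.5)^2)
  out_sp <- bp(td(base + spike))
  resid_peak <- max(abs((out_sp - ref)[abs(tt - 100) < 6]))
  expect_lt(resid_peak, 0.1 * max(spike))
  # clean-segment block means shift < 5 %
  for (on in c(30, 170)) {
    expect_lt(abs(bcm(out_sp, on) - bcm(ref, on)), 0.05 * abs(bcm(ref, on)))
  }

  # 5 robust-SD step: difference of segment medians reduced > 80 %
  step <- 5 * sig_sd * (tt >= 100)
  out_st <- bp(td(base + step))
  no_tddr <- bp(base + step)
  ref_nt <- bp(base)
  seg_step <- function(x, rf) {
    median((x - rf)[tt > 110 & tt < 160]) -
      median((x - rf)[tt > 40 & tt < 90])
  }
  expect_lt(abs(seg_step(out_st, ref)), 0.2 * (5 * sig_sd))
  # and TDDR is doing the work: without it the band-pass leaves far more
  expect_lt(abs(seg_step(out_st, ref)), 0.5 * abs(seg_step(no_tddr, ref_nt)))
  for (on in c(30, 170)) {
    expect_lt(abs(bcm(out_st, on) - bcm(ref, on)), 0.05 * abs(bcm(ref, on)))
  }

  # non-convergence within max_iter proceeds with the last iterate + warning
  cfg_tight <- preprocess_config(tddr_max_iter = 2, tddr_tol = 0)
  expect_no_error(fcoinirs:::tddr_series(base, fs, cfg_tight))
})

test_that("band-pass gains match the analytic Butterworth response", {
  fs <- 11
  cfg <- preprocess_config()
  n <- fs * 1200 # 20 min so the 0.03 Hz line reaches steady state
  tt <- (seq_len(n) - 1) / fs
  make_od <- function(x) fcoinirs:::new_od(array(x, c(n, 1, 1)), fs,
                                           kept = TRUE)
  trim <- tt > 200 & tt < max(tt) - 200
  # 1.2 Hz cardiac-band sinusoid: essentially eliminated
  x_hi <- sin(2 * pi * 1.2 * tt)
  y_hi <- bandpass_filter(make_od(x_hi), fs, cfg)$od[, 1, 1]
  expect_lt(sqrt(mean(y_hi[trim]^2)) / sqrt(mean(x_hi[trim]^2)), 0.01)
  # analytic check: forward-backward application squares the magnitude
  g_ana <- butter_gain(1.2, 0.09, 3, "low")^2
  expect_lt(g_ana, 0.01)
  # 0.03 Hz passes within 10 % of the analytic squared-magnitude gain
  x_lo <- sin(2 * pi * 0.03 * tt)
  y_lo <- bandpass_filter(make_od(x_lo), fs, cfg)$od[, 1, 1]
  g_emp <- sqrt(mean(y_lo[trim]^2)) / sqrt(mean(x_lo[trim]^2))
  g_ana_lo <- butter_gain(0.03, 0.09, 3, "low")^2 *
    butter_gain(0.03, 0.01, 5, "high")^2
  expect_lt(abs(g_emp - g_ana_lo) / g_ana_lo, 0.10)
  expect_gt(g_emp, 0.9 * 0.9) # and within 10 % of unity overall
  # DC is annihilated
  y_dc <- bandpass_filter(make_od(rep(2.5, n)), fs, cfg)$od[, 1, 1]
  expect_lt(abs(mean(y_dc)), 1e-6 * 2.5)
})

test_that("Beer-Lambert inversion is exact for 2 wavelengths and least-squares for 3", {
  m2 <- tiny_montage(2, c(760, 850))
  n <- 50
  ext2 <- extinction_table(c(760, 850))
  od0 <- fcoinirs:::new_od(array(0, c(n, 2, 2)), 11, rep(TRUE, 2))
  c0 <- od_to_concentration(od0, m2, ext2)
  expect_true(all(c0$hbo == 0) && all(c0$hbr == 0))
  # forward-then-invert round trip, exact
  set.seed(6)
  hbo <- matrix(rnorm(n * 2, 0, 1e-6), n)
  hbr <- matrix(rnorm(n * 2, 0, 1e-6), n)
  M <- as.matrix(ext2[, c("eps_hbo", "eps_hbr")])
  od <- fcoinirs:::new_od(array(0, c(n, 2, 2)), 11, rep(TRUE, 2))
  for (ch in 1:2) {
    d_cm <- m2$separation_mm[ch] / 10
    od$od[, ch, ] <- cbind(hbo[, ch], hbr[, ch]) %*% t(M) * d_cm
  }
  back <- od_to_concentration(od, m2, ext2)
  expect_lt(max(abs(back$hbo - hbo)) / max(abs(hbo)), 1e-12)
  expect_lt(max(abs(back$hbr - hbr)) / max(abs(hbr)), 1e-12)

  # 3 wavelengths with OD noise: equals the normal-equations oracle
  m3 <- tiny_montage(2, c(730, 808, 850))
  ext3 <- extinction_table(c(730, 808, 850))
  M3 <- as.matrix(ext3[, c("eps_hbo", "eps_hbr")])
  od3 <- fcoinirs:::new_od(array(0, c(n, 2, 3)), 11, rep(TRUE, 2))
  for (ch in 1:2) {
    d_cm <- m3$separation_mm[ch] / 10
    od3$od[, ch, ] <- cbind(hbo[, ch], hbr[, ch]) %*% t(M3) * d_cm +
      matrix(rnorm(n * 3, 0, 1e-4), n)
  }
  back3 <- od_to_concentration(od3, m3, ext3)
  for (ch in 1:2) {
    d_cm <- m3$separation_mm[ch] / 10
    oracle <- t(solve(t(M3) %*% M3, t(M3) %*% t(od3$od[, ch, ] / d_cm)))
    expect_equal(back3$hbo[, ch], oracle[, 1], tolerance = 1e-10)
    expect_equal(back3$hbr[, ch], oracle[, 2], tolerance = 1e-10)
  }
})

test_that("PCA spatial filter removes global structure and keeps focal signal", {
  # channel density comparable to the real whole-head montages, so the
  # 46-degree kernel has neighbours to smooth over
  m <- tiny_montage(60)
  n <- 1200
  fs <- 11
  tt <- (seq_len(n) - 1) / fs
  # identical sinusoid on all channels: residual < 10 % RMS
  g <- 0.5 * sin(2 * pi * 0.05 * tt)
  conc <- fcoinirs:::new_conc(matrix(g, n, 60), matrix(-g / 3, n, 60), fs)
  out <- remove_global_pca(conc, m$channel_pos)
  expect_lt(sqrt(mean(out$hbo^2)) / sqrt(mean(conc$hbo^2)), 0.1)
  # focal response with mild uncorrelated noise: block mean retained >= 80 %
  set.seed(8)
  focal <- matrix(rnorm(n * 60, 0, 0.02), n)
  resp <- as.numeric(tt > 30 & tt < 60)
  focal[, 7] <- focal[, 7] + resp
  conc2 <- fcoinirs:::new_conc(focal, -focal / 3, fs)
  out2 <- remove_global_pca(conc2, m$channel_pos)
  bm <- function(x) mean(x[tt > 35 & tt < 55]) - mean(x[tt < 25])
  expect_gt(bm(out2$hbo[, 7]), 0.8 * bm(focal[, 7]))
  # zero input -> zero output; < 3 channels -> pass-through with warning
  z <- fcoinirs:::new_conc(matrix(0, 20, 60), matrix(0, 20, 60), fs)
  expect_true(all(remove_global_pca(z, m$channel_pos)$hbo == 0))
  small <- fcoinirs:::new_conc(matrix(1, 20, 2), matrix(1, 20, 2), fs)
  expect_warning(remove_global_pca(small, m$channel_pos[1:2, ]),
                 "fewer than 3")
})

test_that("the full chain runs in order with a provenance log", {
  scn <- scenario("adult", compact = TRUE, seed = 2)
  run <- simulate_run(scn$truth, scn$montage, scn$tasks$language, 1, 1)
  conc <- preprocess_run(run)
  prov <- attr(conc, "provenance")
  expect_equal(vapply(prov, `[[`, "", "step"),
               c("prune_channels", "negative_guard", "intensity_to_od",
                 "detrend_linear", "correct_motion_tddr", "bandpass_filter",
                 "od_to_concentration", "remove_global_pca"))
  # per-run purity: the same run preprocessed twice is identical
  conc2 <- preprocess_run(run)
  expect_identical(conc$hbo, conc2$hbo)
  # shape preserved, mask respected
  expect_equal(dim(conc$hbo), dim(run$intensity)[1:2])
  expect_true(all(is.finite(conc$hbo[, conc$kept])))
})

test_that("noise-free simulation is recovered through the chain (TDDR off)", {
  # TDDR's robust scale degenerates on noise-free input (the derivative MAD
  # collapses), so the recovery oracle runs the chain without it.
  scn <- scenario("adult", compact = TRUE, seed = 2)
  task <- scn$tasks$language
  run <- simulate_run(scn$truth, scn$montage, task, 1, 1, noise = FALSE)
  conc <- preprocess_run(run, preprocess_config(run_tddr = FALSE,
                                                run_bandpass = FALSE,
                                                run_pca = FALSE))
  tab <- build_block_table(list(conc), list(language = task))
  ch <- scn$truth$language_channels[1]
  agg <- stats::aggregate(mean_hbo ~ condition, tab[tab$channel_id == ch, ],
                          mean)
  got <- agg$mean_hbo[agg$condition == "intact"] -
    agg$mean_hbo[agg$condition == "degraded"]
  # analytic oracle: windowed boxcar*HRF contrast by direct convolution
  fs <- 11
  n_time <- dim(run$intensity)[1]
  kern <- fcoinirs:::hrf_kernel(fs)
  ev <- run$events
  y <- numeric(n_time)
  amp <- list(intact = 0.6e-6, degraded = 0.1e-6) # base 0.1 + effect 0.5
  for (i in seq_len(nrow(ev))) {
    y <- y + oracle_boxcar_response(ev$onset_s[i], ev$duration_s[i],
                                    amp[[ev$condition[i]]], n_time, fs, kern)
  }
  wm <- function(onset) {
    tt <- ((seq_len(n_time) - 1) / fs) - onset
    base <- mean(y[tt >= -2 & tt < 0])
    mean(y[tt >= 5 & tt < 20]) - base
  }
  per_cond <- tapply(seq_len(nrow(ev)), ev$condition,
                     function(i) mean(vapply(ev$onset_s[i], wm, numeric(1))))
  oracle <- per_cond[["intact"]] - per_cond[["degraded"]]
  expect_lt(abs(got - oracle) / abs(oracle), 0.15)
})

test_that("linear steps are homogeneous and never un-prune channels", {
  set.seed(9)
  n <- 300
  arr <- array(rnorm(n * 3 * 2), c(n, 3, 2))
  arr[, 2, ] <- NA_real_ # pruned channels are carried as missing
  od <- fcoinirs:::new_od(arr, 11, c(TRUE, FALSE, TRUE))
  a <- 3.7
  od_s <- od; od_s$od <- a * od_s$od
  d1 <- detrend_linear(od); d2 <- detrend_linear(od_s)
  expect_equal(a * d1$od[, 1, ], d2$od[, 1, ], tolerance = 1e-10)
  b1 <- bandpass_filter(od, 11); b2 <- bandpass_filter(od_s, 11)
  expect_equal(a * b1$od[, 1, ], b2$od[, 1, ], tolerance = 1e-8)
  # pruned channel stays NA through the chain
  expect_true(all(is.na(d1$od[, 2, ])))
  expect_true(all(is.na(b1$od[, 2, ])))
})
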