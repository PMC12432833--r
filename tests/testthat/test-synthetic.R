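test_that("zero-effect channels respond identically to both conditions", {
  task <- default_tasks("adult")$language
  truth <- sim_truth(4, language_channels = 2, language_effect_uM = 0.5)
  ev <- make_design(task, 1, 1)
  n_time <- ceiling(attr(ev, "run_duration_s") * 11) + 1
  conc <- simulate_conc(truth, ev, task, n_time, 11)
  tab <- build_block_table(
    list(structure(conc, class = class(conc)) |>
           (\(x) { x$meta <- list(subject_id = "S01", task_id = "language",
                                  run_index = 1L); x })()),
    list(language = task))
  agg <- stats::aggregate(mean_hbo ~ channel_id + condition, tab, mean)
  sel <- agg[agg$channel_id == 2, ]
  sel_contrast <- abs(diff(sel$mean_hbo))
  for (ch in c(1, 3, 4)) {
    v <- agg$mean_hbo[agg$channel_id == ch]
    # equal up to baseline carry-over from neighbouring blocks, and far
    # below the selective channel's contrast
    expect_equal(v[1], v[2], tolerance = 0.05)
    expect_lt(abs(v[1] - v[2]), 0.05 * sel_contrast)
  }
  # the selective channel prefers the intact condition
  v2 <- agg[agg$channel_id == 2, ]
  expect_gt(v2$mean_hbo[v2$condition == "intact"],
            v2$mean_hbo[v2$condition == "degraded"])
})

test_that("simulated contrast matches the direct convolution oracle and is linear", {
  task <- default_tasks("adult")$language
  fs <- 11
  truth0 <- sim_truth(2, language_channels = 1, language_effect_uM = 0.5)
  ev <- make_design(task, 1, 1)
  n_time <- ceiling(attr(ev, "run_duration_s") * fs) + 1
  kern <- fcoinirs:::hrf_kernel(fs)

  # independent oracle: loop-based convolution of each block's boxcar
  oracle <- function(amp_by_cond) {
    y <- numeric(n_time)
    for (i in seq_len(nrow(ev))) {
      y <- y + oracle_boxcar_response(ev$onset_s[i], ev$duration_s[i],
                                      amp_by_cond[[ev$condition[i]]],
                                      n_time, fs, kern)
    }
    y
  }
  win_mean <- function(y, onset) {
    tt <- ((seq_len(n_time) - 1) / fs) - onset
    mean(y[tt >= 5 & tt < 20])
  }
  contrasts <- sapply(c(0.25, 0.5, 1.0), function(eff) {
    truth <- sim_truth(2, language_channels = 1, language_effect_uM = eff)
    conc <- simulate_conc(truth, ev, task, n_time, fs)
    y_o <- oracle(list(intact = (0.1 + eff) * 1e-6, degraded = 0.1e-6))
    # channel 1 must equal the oracle series exactly (same model, independent code)
    expect_equal(conc$hbo[, 1], y_o, tolerance = 1e-9)
    oi <- which(ev$condition == "intact")[1]
    od <- which(ev$condition == "degraded")[1]
    win_mean(conc$hbo[, 1], ev$onset_s[oi]) -
      win_mean(conc$hbo[, 1], ev$onset_s[od])
  })
  expect_gt(contrasts[2], 0)
  # linearity in the injected effect
  expect_equal(contrasts[3] / contrasts[1], 4, tolerance = 0.02)
  expect_equal(contrasts[2] / contrasts[1], 2, tolerance = 0.02)
})

test_that("hbr is a fixed negative ratio of hbo", {
  task <- default_tasks("adult")$language
  truth <- sim_truth(2, language_channels = 1)
  ev <- make_design(task, 1, 1)
  n_time <- ceiling(attr(ev, "run_duration_s") * 11) + 1
  conc <- simulate_conc(truth, ev, task, n_time, 11)
  expect_equal(conc$hbr, -conc$hbo / 3, tolerance = 1e-12)
})

test_that("noise generator honours zero amplitudes and injects stated structure", {
  m <- tiny_montage(8)
  task <- default_tasks("adult")$language
  ev <- make_design(task, 1, 1)
  n_time <- ceiling(attr(ev, "run_duration_s") * 11) + 1
  silent <- sim_truth(8, white_sd_uM = 0, drift_sd_uM = 0,
                      cardiac = c(1.2, 0), respiration = c(0.25, 0),
                      mayer = c(0.1, 0), global_amp_uM = 0,
                      spike_rate_per_min = 0, shift_rate_per_min = 0)
  conc <- simulate_conc(silent, ev, task, n_time, 11)
  noisy <- add_noise_and_artifacts(conc, silent, m$channel_pos, seed = 1)
  expect_equal(noisy$hbo, conc$hbo)
  expect_equal(noisy$hbr, conc$hbr)
  expect_equal(nrow(attr(noisy, "manifest")), 0)

  # cardiac line: periodogram peak at 1.2 Hz dominates neighbouring bins
  cardiac <- sim_truth(8, white_sd_uM = 0.01, drift_sd_uM = 0,
                       cardiac = c(1.2, 0.3), respiration = c(0.25, 0),
                       mayer = c(0.1, 0), global_amp_uM = 0,
                       spike_rate_per_min = 0, shift_rate_per_min = 0)
  zero <- fcoinirs:::new_conc(matrix(0, n_time, 8), matrix(0, n_time, 8), 11)
  nz <- add_noise_and_artifacts(zero, cardiac, m$channel_pos, seed = 2)
  x <- nz$hbo[, 1]
  spec <- Mod(fft(x - mean(x)))^2
  freqs <- (seq_along(spec) - 1) * 11 / length(spec)
  peak_bin <- which.max(spec[freqs > 0.5 & freqs < 5.5])
  f_peak <- freqs[freqs > 0.5 & freqs < 5.5][peak_bin]
  expect_lt(abs(f_peak - 1.2), 0.1)
  band <- spec[abs(freqs - f_peak) < 0.02]
  away <- spec[freqs > 0.5 & freqs < 5.5 & abs(freqs - f_peak) > 0.3]
  expect_gt(max(band), 10 * max(away))

  # shared global component dominates the first principal component
  glob <- sim_truth(8, white_sd_uM = 0.1, drift_sd_uM = 0,
                    cardiac = c(1.2, 0), respiration = c(0.25, 0),
                    mayer = c(0.1, 0), global_amp_uM = 0.5,
                    spike_rate_per_min = 0, shift_rate_per_min = 0)
  ng <- add_noise_and_artifacts(zero, glob, m$channel_pos, seed = 3)
  pv <- svd(sweep(ng$hbo, 2, colMeans(ng$hbo)))$d^2
  expect_gt(pv[1] / sum(pv), 0.5)
})

test_that("forward model is exact and round-trips through the inversion", {
  for (wl in list(c(760, 850), c(730, 808, 850))) {
    m <- tiny_montage(4, wavelengths = wl)
    task <- default_tasks("adult")$language
    truth <- sim_truth(4, language_channels = 2, language_effect_uM = 0.5)
    ev <- make_design(task, 1, 1)
    n_time <- ceiling(attr(ev, "run_duration_s") * 11) + 1
    conc <- simulate_conc(truth, ev, task, n_time, 11)
    ext <- extinction_table(wl)
    run <- conc_to_intensity(conc, m, ext, truth)
    # zero concentrations, no artifacts: intensity constant at baseline
    zero <- fcoinirs:::new_conc(matrix(0, 30, 4), matrix(0, 30, 4), 11,
                                events = data.frame(condition = "intact",
                                                    onset_s = 0.5,
                                                    duration_s = 1))
    z <- conc_to_intensity(zero, m, ext, truth,
                           meta = list(run_index = 1L))
    expect_true(all(z$intensity == truth$baseline_intensity))
    # inversion (no filters) recovers the concentrations
    od <- intensity_to_od(run)
    rec <- od_to_concentration(od, m, ext)
    # OD referencing removes each channel's mean; compare centred series
    ctr <- function(x) sweep(x, 2, colMeans(x))
    scale_ref <- max(abs(conc$hbo))
    expect_lt(max(abs(ctr(rec$hbo) - ctr(conc$hbo))) / scale_ref, 1e-9)
    expect_lt(max(abs(ctr(rec$hbr) - ctr(conc$hbr))) / scale_ref, 1e-9)
  }
})

test_that("non-positive baseline intensity is rejected", {
  m <- tiny_montage(2)
  truth <- sim_truth(2, baseline_intensity = -5)
  zero <- fcoinirs:::new_conc(matrix(0, 10, 2), matrix(0, 10, 2), 11,
                              events = data.frame(condition = "intact",
                                                  onset_s = 0,
                                                  duration_s = 0.5))
  expect_error(conc_to_intensity(zero, m, extinction_table(c(760, 850)),
                                 truth),
               class = "fcoi_config_error")
})

test_that("scenarios encode the stated cohort shapes", {
  ad <- scenario("adult")
  expect_equal(ad$n_subjects, 20L)
  expect_equal(ad$tasks$language$runs_expected, 8L)
  expect_equal(ad$tasks$md$runs_expected, 4L)
  expect_equal(ad$montage$n_channels, 79L)
  td <- scenario("toddler")
  expect_equal(td$n_subjects, 22L)
  expect_equal(td$tasks$language$runs_expected, 4L)
  expect_equal(td$montage$n_channels, 81L)
  # one language-true and one md-true channel per space, distinct
  expect_length(ad$truth$language_channels, 2)
  expect_length(ad$truth$md_channels, 2)
  expect_length(intersect(ad$truth$language_channels, ad$truth$md_channels), 0)
})

test_that("cohorts are reproducible from the seed", {
  scn <- scenario("adult", compact = TRUE, n_subjects = 2, seed = 42)
  c1 <- simulate_cohort(scn)
  c2 <- simulate_cohort(scn)
  expect_equal(length(c1$runs), 2 * (4 + 4))
  expect_identical(
    jsonlite::toJSON(c1$manifest, digits = NA),
    jsonlite::toJSON(c2$manifest, digits = NA))
  expect_identical(c1$runs[[1]]$intensity, c2$runs[[1]]$intensity)
  expect_identical(c1$runs[[9]]$intensity, c2$runs[[9]]$intensity)
  # a different seed changes the noise realisation
  c3 <- simulate_cohort(scenario("adult", compact = TRUE, n_subjects = 2,
                                 seed = 43))
  expect_false(identical(c1$runs[[1]]$intensity, c3$runs[[1]]$intensity))
})
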