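make_series <- function(arr, tr = 3.5, vox = 1.5, bounds = NULL)
  volume_series(arr, voxel_size_mm = vox, tr_s = tr, session_bounds = bounds)

# plain-R reference convolution used by the HRF test
causal_conv_ref <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n))
    for (j in seq_along(k))
      if (t - j + 1 >= 1) out[t] <- out[t] + x[t - j + 1] * k[j]
  out
}

test_that("Gaussian smoothing: identity cases, kernel shape, mass", {
  d <- c(15L, 15L, 15L, 2L)
  const <- make_series(array(7, d))
  sm <- smooth_gaussian(const, 3)
  # interior voxels of a constant volume are unchanged
  expect_equal(sm$data[5:11, 5:11, 5:11, ], const$data[5:11, 5:11, 5:11, ],
               tolerance = 1e-6)
  expect_identical(smooth_gaussian(const, 0)$data, const$data)

  # unit impulse: neighbour/centre ratio = exp(-4 ln2 d^2 / FWHM^2),
  # d = 1.5 mm, FWHM = 3 mm -> 0.5
  imp <- array(0, d); imp[8, 8, 8, 1] <- 1
  smi <- smooth_gaussian(make_series(imp), 3)
  expect_equal(smi$data[9, 8, 8, 1] / smi$data[8, 8, 8, 1], 0.5,
               tolerance = 1e-9)
  # kernel is normalised: total mass preserved for interior support
  expect_equal(sum(smi$data[, , , 1]), 1, tolerance = 1e-3)
})

test_that("linear detrend removes ramps per session, keeps means", {
  n_t <- 24L
  base <- array(0, c(2L, 2L, 2L, n_t))
  tt <- seq_len(n_t)
  ramp <- base
  ramp[1, 1, 1, ] <- 5 + 0.3 * tt
  v <- detrend_linear(make_series(ramp))
  expect_equal(v$data[1, 1, 1, ], rep(mean(5 + 0.3 * tt), n_t),
               tolerance = 1e-10)

  const <- base; const[1, 1, 1, ] <- 4.2
  expect_equal(detrend_linear(make_series(const))$data, const,
               tolerance = 1e-12)

  # linearity: adding a zero-mean ramp (pure slope) leaves the detrended
  # signal unchanged (the session mean is retained by design)
  sig <- base; sig[2, 1, 1, ] <- sin(tt)
  both <- sig; both[2, 1, 1, ] <- sig[2, 1, 1, ] + 0.2 * (tt - mean(tt))
  expect_equal(detrend_linear(make_series(both))$data[2, 1, 1, ],
               detrend_linear(make_series(sig))$data[2, 1, 1, ],
               tolerance = 1e-6)

  # per-session: a ramp restarting each session is removed entirely
  two <- base
  two[1, 2, 1, ] <- c(0.5 * (1:12), 0.5 * (1:12))
  bounds <- cbind(c(1, 13), c(12, 24))
  dv <- detrend_linear(make_series(two, bounds = bounds))
  expect_equal(dv$data[1, 2, 1, ], rep(mean(0.5 * (1:12)), 24),
               tolerance = 1e-10)
  expect_error(detrend_linear(make_series(base,
                                          bounds = cbind(c(1, 3), c(2, 24)))),
               "fewer than 3")
})

test_that("HRF convolution matches its kernel and shifts a boxcar peak", {
  tr <- 3.5
  n_t <- 40L
  kernel <- canonical_hrf(seq(0, 32, by = tr))
  kernel <- kernel / sum(kernel)

  imp <- array(0, c(1L, 1L, 1L, n_t)); imp[1, 1, 1, 3] <- 1
  out <- hrf_convolve(make_series(imp, tr = tr))$data[1, 1, 1, ]
  expected <- rep(0, n_t)
  expected[3:(2 + length(kernel))] <- kernel
  expect_equal(out, expected, tolerance = 1e-9)

  const <- array(2, c(1L, 1L, 1L, n_t))
  outc <- hrf_convolve(make_series(const, tr = tr))$data[1, 1, 1, ]
  # constant input -> constant x kernel sum (once the kernel has filled in)
  expect_equal(outc[length(kernel):n_t],
               rep(2 * sum(kernel), n_t - length(kernel) + 1),
               tolerance = 1e-9)

  # convolving an already once-convolved 12 s boxcar delays the peak by
  # >= 2 further volumes (the "doubled delay" the onset shift compensates)
  box <- rep(0, n_t); box[5:8] <- 1   # 4 volumes ~ 12 s of recall
  once <- causal_conv_ref(box, kernel)
  arr <- array(once, c(1L, 1L, 1L, n_t))
  twice <- hrf_convolve(make_series(arr, tr = tr))$data[1, 1, 1, ]
  expect_gte(which.max(twice) - which.max(once), 2)
})

test_that("onset shift rounds the delay to the nearest volume", {
  expect_identical(compute_onset_shift(12, 3.5), 3L)
  expect_identical(compute_onset_shift(12, 3.0), 4L)
  expect_identical(compute_onset_shift(0, 3.5), 0L)
  expect_identical(compute_onset_shift(1.75, 3.5), 1L)  # tie: away from zero
  expect_error(compute_onset_shift(-1, 3.5), "validation")
})

test_that("trial filter applies the >= 4 / >= 4 rule exactly", {
  tab <- data.frame(onset = (0:4) * 26.5, duration = 12,
                    memory = letters[1:5], condition = "recent", session = 1L,
                    vividness = c(5L, 4L, 3L, 4L, 5L),
                    consistency = c(4L, 3L, 5L, 4L, 5L))
  class(tab) <- c("trial_table", "data.frame")
  kept <- filter_trials(tab)
  expect_identical(kept$memory, c("a", "d", "e"))   # (5,4),(4,4),(5,5)
  all5 <- tab; all5$vividness <- 5L; all5$consistency <- 5L
  expect_equal(nrow(filter_trials(all5)), 5L)
  bad <- tab; bad$vividness[2] <- NA
  expect_error(filter_trials(bad), "complete")
  bad2 <- tab; bad2$consistency[1] <- 6L
  expect_error(filter_trials(bad2), "1..5")
})

test_that("trial extraction windows, averaging, and errors", {
  tr <- 3.5
  n_t <- 30L
  cfg <- preproc_config()
  expect_equal(ceiling(cfg$recall_s / cfg$tr_s), 4)  # 4 volumes per trial

  arr <- array(0, c(3L, 3L, 3L, n_t))
  # identical volumes in the window -> pattern equals any single volume
  vals <- rnorm(27)
  for (t in 1:n_t) arr[, , , t] <- vals * t
  win_start <- floor(10 / tr) + 3       # trial onset 10 s, shift 3
  arr[, , , (win_start + 1):(win_start + 4)] <- vals
  tab <- data.frame(onset = 10, duration = 12, memory = "m1",
                    condition = "recent", session = 1L,
                    vividness = 5L, consistency = 5L)
  class(tab) <- c("trial_table", "data.frame")
  mask <- array(TRUE, c(3L, 3L, 3L))
  ps <- extract_trial_patterns(volume_series(arr, tr_s = tr), tab, mask, cfg)
  expect_equal(ps$X[1, ], vals, ignore_attr = TRUE)
  expect_equal(ps$n_volumes_per_trial, 4L)

  # volumes-as-samples alternative keeps each volume
  cfg2 <- preproc_config(volumes_as_samples = TRUE)
  ps2 <- extract_trial_patterns(volume_series(arr, tr_s = tr), tab, mask, cfg2)
  expect_equal(nrow(ps2$X), 4L)

  late <- tab; late$onset <- (n_t - 1) * tr
  expect_error(extract_trial_patterns(volume_series(arr, tr_s = tr), late,
                                      mask, cfg),
               "trial\\(s\\): 1")
})

test_that("pipeline is deterministic and recovers planted patterns", {
  geom <- small_geometry(seed = 21)
  des <- design_spec()
  sch <- make_trial_schedule(des, seed = 22)
  truth <- plant_patterns(geom, des, amplitudes = 1, noise_sd = 0,
                          drift_slope = 0, seed = 23)
  bold <- synthesize_bold(geom, truth, sch, des)

  p1 <- preprocess_subject(bold, sch, geom$roi_masks)
  p2 <- preprocess_subject(bold, sch, geom$roi_masks)
  expect_identical(p1$HC$X, p2$HC$X)    # bit-identical re-run

  # noiseless, unsmoothed extraction: per-trial cosine similarity with the
  # planted weight map > 0.99
  cfg <- preproc_config(smooth_fwhm_mm = 0)
  ext <- extract_trial_patterns(hrf_convolve(detrend_linear(bold)), sch,
                                geom$roi_masks$HC, cfg)
  W <- matrix(0, sum(geom$roi_masks$HC), length(truth$memories))
  for (mi in seq_along(truth$memories)) {
    mem <- truth$memories[mi]
    W[truth$rois$HC$supports[[mem]], mi] <- truth$rois$HC$weights[[mem]]
  }
  cosims <- vapply(seq_len(nrow(ext$X)), function(i) {
    v <- ext$X[i, ]; w <- W[, match(ext$memory[i], truth$memories)]
    sum(v * w) / sqrt(sum(v^2) * sum(w^2))
  }, numeric(1))
  expect_gt(min(cosims), 0.99)
})
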