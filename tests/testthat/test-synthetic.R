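test_that("phantom ROI builder hits size targets with disjoint masks", {
  geom <- build_phantom_rois(c(40L, 28L, 28L), c(HC = 928, vmPFC = 1169),
                             seed = 11)
  n_hc <- sum(geom$roi_masks$HC)
  n_vm <- sum(geom$roi_masks$vmPFC)
  expect_lt(abs(n_hc - 928) / 928, 0.05)
  expect_lt(abs(n_vm - 1169) / 1169, 0.05)
  expect_equal(sum(geom$roi_masks$HC & geom$roi_masks$vmPFC), 0)

  # hippocampus elongated along the long axis
  ext <- apply(which(geom$roi_masks$HC, arr.ind = TRUE), 2,
               function(x) diff(range(x)))
  expect_gt(ext[geom$long_axis], 1.5 * max(ext[-geom$long_axis]))

  geom2 <- build_phantom_rois(c(40L, 28L, 28L), c(HC = 928, vmPFC = 1169),
                              seed = 11)
  expect_identical(geom$roi_masks, geom2$roi_masks)  # determinism
})

test_that("impossible ROI requests raise capacity errors", {
  expect_error(build_phantom_rois(c(10L, 10L, 10L), c(A = 1e9), seed = 1),
               "capacity")
  expect_error(build_phantom_rois(c(8L, 8L, 8L),
                                  c(A = 200, B = 200, C = 200), seed = 1),
               "capacity|fit")
})

test_that("trial schedule has the stated counts and no immediate repeats", {
  des <- design_spec()
  sch <- make_trial_schedule(des, seed = 5)
  expect_equal(nrow(sch), 126L)
  expect_equal(as.vector(table(sch$session)), c(63L, 63L))
  expect_true(all(table(sch$memory) == 14L))
  same <- head(sch$memory, -1) == tail(sch$memory, -1) &
    head(sch$session, -1) == tail(sch$session, -1)
  expect_equal(sum(same), 0L)
  # onsets follow the timing grid within a session
  for (s in 1:2) {
    on <- sch$onset[sch$session == s]
    expect_equal(diff(on), rep(26.5, 62))   # 3+12+1.5+6+4 s per trial
  }
  expect_identical(sch, make_trial_schedule(des, seed = 5))
  expect_false(identical(sch$memory,
                         make_trial_schedule(des, seed = 6)$memory))
})

test_that("scheduling fails cleanly when no valid order exists", {
  des <- design_spec(n_memories_per_condition = 1L, conditions = "only",
                     repetitions = 4L, n_sessions = 2L)
  expect_error(make_trial_schedule(des, seed = 1, max_retries = 10),
               "scheduling error")
})

test_that("rating filter retention matches retention_prob", {
  des <- design_spec(repetitions = 112L)   # 9 x 112 = 1008 trials
  sch <- make_trial_schedule(des, seed = 3)
  retained <- mean(sch$vividness >= 4 & sch$consistency >= 4)
  se <- sqrt(0.79 * 0.21 / nrow(sch))
  expect_lt(abs(retained - 0.79), 3 * se)
})

test_that("planted supports honour overlap constraints", {
  geom <- small_geometry(seed = 2)
  des <- design_spec()
  n_roi <- sum(geom$roi_masks$HC)

  t0 <- plant_patterns(geom, des, support_frac = 0.2, support_overlap = 0,
                       seed = 4)
  sup <- t0$rois$HC$supports
  for (a in names(sup)) for (b in names(sup)) {
    if (t0$conditions[[a]] != t0$conditions[[b]])
      expect_length(intersect(sup[[a]], sup[[b]]), 0)
  }

  t1 <- plant_patterns(geom, des, support_frac = 0.2, support_overlap = 1,
                       seed = 4)
  sup1 <- t1$rois$HC$supports
  base <- sup1[[1]]
  for (s in sup1) expect_identical(s, base)   # identical supports

  th <- plant_patterns(geom, des, support_frac = 0.2, support_overlap = 0.5,
                       seed = 4)
  m <- length(th$rois$HC$supports[[1]])
  sa <- th$rois$HC$supports[["recent_1"]]
  sb <- th$rois$HC$supports[["remote_1"]]
  expect_lte(abs(length(intersect(sa, sb)) - round(0.5 * m)), 1)

  expect_error(plant_patterns(geom, des, support_overlap = 1.2), "\\[0, 1\\]")
  expect_error(plant_patterns(geom, des, support_frac = 0.5,
                              support_overlap = 0), "infeasible")
  # supports always inside the ROI
  expect_true(all(unlist(sup) >= 1 & unlist(sup) <= n_roi))
})

test_that("zero-amplitude conditions produce zero signal in the series", {
  geom <- small_geometry(seed = 6)
  des <- design_spec()
  amp <- matrix(c(0, 1, 1), 1, 3,
                dimnames = list("HC", des$conditions))
  truth <- plant_patterns(geom, des, amplitudes = amp, noise_sd = 0,
                          drift_slope = 0, seed = 7)
  sch <- make_trial_schedule(des, seed = 8)
  bold <- synthesize_bold(geom, truth, sch, des)
  # voxels supporting only recent-condition memories stay flat
  rec_only <- setdiff(unlist(truth$rois$HC$supports[1:3]),
                      unlist(truth$rois$HC$supports[4:9]))
  expect_gt(length(rec_only), 0)
  roi_idx <- which(geom$roi_masks$HC)
  flat <- apply(matrix(bold$data, prod(dim(bold)[1:3]),
                       dim(bold)[4])[roi_idx[rec_only], , drop = FALSE],
                1, function(x) max(abs(x)))
  expect_lt(max(flat), 1e-12)
})

test_that("BOLD synthesis is seed-deterministic and validates inputs", {
  geom <- small_geometry(seed = 9)
  des <- design_spec()
  truth <- plant_patterns(geom, des, seed = 10)
  sch <- make_trial_schedule(des, seed = 11)
  b1 <- synthesize_bold(geom, truth, sch, des)
  b2 <- synthesize_bold(geom, truth, sch, des)
  expect_identical(b1$data, b2$data)
  bad <- sch
  attr(bad, "session_volumes") <- NULL
  expect_error(synthesize_bold(geom, truth, bad, des), "validation")
})

test_that("ground truth JSON round-trips losslessly", {
  geom <- small_geometry(seed = 12)
  truth <- plant_patterns(geom, design_spec(), amplitudes = 0.7,
                          support_frac = 0.2, support_overlap = 0.25,
                          noise_sd = 1.5, drift_slope = 0.03, seed = 13)
  f <- tempfile(fileext = ".json")
  write_ground_truth(truth, f)
  back <- read_ground_truth(f)
  expect_equal(back, truth)
  unlink(f)
})

test_that("timepoint re-realisation retains the requested support fraction", {
  geom <- small_geometry(seed = 14)
  des <- design_spec()
  truth <- plant_patterns(geom, des, support_frac = 0.2, seed = 15)
  for (ov in c(0, 0.5, 1)) {
    t2 <- ground_truth_at_timepoint(truth, ov, seed = 16)
    for (mem in truth$memories) {
      s1 <- truth$rois$HC$supports[[mem]]
      s2 <- t2$rois$HC$supports[[mem]]
      expect_length(s2, length(s1))
      expect_equal(length(intersect(s1, s2)), round(ov * length(s1)),
                   tolerance = 0, ignore_attr = TRUE)
    }
  }
})

test_that("decoding accuracy is monotone in the amplitude/noise ratio", {
  ratios <- c(0, 0.5, 1, 2, 4)
  acc <- vapply(ratios, function(r) {
    mean(vapply(1:2, function(s)
      decode_one_subject(s, amplitude = r, targets = c(HC = 60),
                         grid = c(16L, 11L, 11L), k = 5L)$accuracy,
      numeric(1)))
  }, numeric(1))
  # non-decreasing up to small Monte Carlo jitter at the flat ends
  expect_true(all(diff(acc) > -0.05))
  expect_gt(acc[5], acc[1] + 0.3)
})
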