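test_that("stratified folds partition trials with balanced class counts", {
  y <- rep(c("m1", "m2", "m3"), each = 10)
  f <- make_folds(y, k = 10, seed = 1)
  expect_equal(attr(f, "k"), 10L)
  expect_equal(sort(unique(f)), 1:10)
  # each fold tests 3 trials, one per class
  for (k in 1:10) {
    expect_equal(sum(f == k), 3L)
    expect_equal(sort(y[f == k]), c("m1", "m2", "m3"))
  }
  expect_identical(f, make_folds(y, k = 10, seed = 1))
  expect_false(identical(f, make_folds(y, k = 10, seed = 2)))

  # per-class test counts differ by <= 1 across folds
  y2 <- rep(c("a", "b", "c"), c(11, 9, 12))
  f2 <- make_folds(y2, k = 5, seed = 3)
  for (cl in unique(y2)) {
    counts <- table(factor(f2[y2 == cl], levels = 1:5))
    expect_lte(diff(range(counts)), 1)
  }

  expect_message(make_folds(rep(c("a", "b"), c(4, 8)), k = 10, seed = 1),
                 "reduced")
  expect_error(make_folds(c("a", "a", "b"), k = 2, seed = 1), "fewer than 2")
})

test_that("one-vs-rest codebook has the stated codewords and distances", {
  cb <- ecoc_codebook(3)
  expect_equal(unclass(cb), diag(3L), ignore_attr = TRUE)
  dists <- outer(1:3, 1:3, Vectorize(function(i, j) sum(cb[i, ] != cb[j, ])))
  expect_equal(min(dists[upper.tri(dists)]), 2)      # min Hamming distance
  # every dichotomy splits classes into two non-empty groups
  expect_true(all(colSums(cb) >= 1 & colSums(cb) <= 2))

  cb2 <- ecoc_codebook(2)
  expect_equal(dim(cb2), c(2L, 1L))
  expect_equal(as.vector(cb2), c(1L, 0L))
  expect_error(ecoc_codebook(1), "validation")
})

test_that("Hamming decoding picks nearest codeword, lowest index on ties", {
  cb <- ecoc_codebook(3)
  expect_equal(hamming_decode(c(1, 0, 0), cb), 1L)
  expect_equal(hamming_decode(c(0, 1, 0), cb), 2L)
  expect_equal(hamming_decode(c(1, 1, 0), cb), 1L)   # tie 1 vs 2 -> lowest
  expect_equal(hamming_decode(c(0, 1, 1), cb), 2L)   # tie 2 vs 3 -> lowest
  expect_equal(hamming_decode(rbind(c(0, 0, 1), c(1, 1, 1)), cb), c(3L, 1L))
})

test_that("ECOC-Hamming matches the exhaustive oracle on small problems", {
  skip_if_not_installed("quadprog")
  set.seed(110)
  for (rep in 1:6) {
    n <- 12L
    X <- cbind(rnorm(n), rnorm(n))
    y <- sample(rep(c("m1", "m2", "m3"), each = 4))
    # well-separated class means keep margins away from solver tolerance
    X <- X + 3 * cbind(match(y, c("m1", "m2", "m3")) %% 2,
                       match(y, c("m1", "m2", "m3")) %/% 2)
    te <- sample(n, 3)
    pred <- ecoc_classify(X[-te, ], y[-te], X[te, , drop = FALSE])
    pred_oracle <- ecoc_oracle(X[-te, ], y[-te], X[te, , drop = FALSE])
    expect_identical(pred, pred_oracle)
  }
})

test_that("feature selection recovers planted signal and ignores noise", {
  # strong signal confined (support_overlap = 0) to a contiguous slab of
  # the ROI: the winning sphere sits in that slab on every fold
  out <- decode_one_subject(51, amplitude = 2, targets = c(HC = 60),
                            grid = c(16L, 11L, 11L), support_frac = 0.25,
                            support_overlap = 0, noise_sd = 0.5, k = 5L)
  pool <- out$truth$rois$HC$pools[["recent"]]
  for (fs in out$result$feature_sets) {
    expect_false(fs$fallback)
    expect_length(fs$selected_spheres, 1L)
    # radius-3 spheres (45 voxels) overhang the ~20-voxel slab, so demand a
    # plurality, not a majority, of selected voxels inside the pool
    expect_gt(length(intersect(fs$voxels, pool)) / length(fs$voxels), 0.35)
    expect_true(all(fs$voxels >= 1 &
                      fs$voxels <= length(out$spheres$members)))
  }
  expect_gt(out$accuracy, 0.85)

  # pure-noise data: held-out accuracy sits near chance
  nulls <- lapply(52:54, function(s)
    decode_one_subject(s, amplitude = 0, targets = c(HC = 60),
                       grid = c(16L, 11L, 11L), k = 5L))
  null_acc <- mean(vapply(nulls, function(o) o$accuracy, numeric(1)))
  expect_lt(abs(null_acc - 1 / 3), 0.15)
})

test_that("empty selections fall back to the best sphere, flagged", {
  # all-zero features: every dichotomy outputs 0, Hamming ties resolve to
  # class 1, so every sphere scores exactly chance -- never strictly above
  X <- matrix(0, 18, 10)
  y <- rep(c("a", "b", "c"), 6)
  mask <- array(FALSE, c(10L, 3L, 3L)); mask[1:10, 1, 1] <- TRUE
  sp <- enumerate_spheres(mask, 1)
  fs <- suppressMessages(select_features(X, y, sp, seed = 5))
  expect_true(fs$fallback)
  expect_length(fs$selected_spheres, 1L)
  expect_gt(length(fs$voxels), 0)
})

test_that("feature selection never touches held-out trials", {
  out <- decode_one_subject(54, amplitude = 0.5, targets = c(HC = 50),
                            grid = c(15L, 10L, 10L), k = 5L)
  ps <- out$patterns
  y <- ps$memory
  fold <- make_folds(y, 5L, seed = substream_seed(54, "d"))
  f <- 1L
  tr <- fold != f
  fs_full <- select_features(ps$X[tr, , drop = FALSE], y[tr], out$spheres,
                             seed = substream_seed(54, "x"))
  # deleting any test trial leaves the training split, hence the selected
  # FeatureSet, untouched
  for (drop in sample(which(!tr), 2)) {
    keep <- setdiff(seq_along(y), drop)
    tr2 <- tr[keep]
    fs2 <- select_features(ps$X[keep, , drop = FALSE][tr2, , drop = FALSE],
                           y[keep][tr2], out$spheres,
                           seed = substream_seed(54, "x"))
    expect_identical(fs2$voxels, fs_full$voxels)
    expect_identical(fs2$scores, fs_full$scores)
  }
})

test_that("cross-validation accounting is internally consistent", {
  out <- decode_one_subject(55, amplitude = 1, targets = c(HC = 50),
                            grid = c(15L, 10L, 10L), k = 5L)
  res <- out$result
  expect_true(all(res$fold_accuracy >= 0 & res$fold_accuracy <= 1))
  expect_equal(res$mean_accuracy, mean(res$fold_accuracy))
  expect_equal(res$chance, 1 / 3)
  expect_equal(sum(res$confusion), res$n_trials)
  # reproducible with the same seed
  res2 <- suppressMessages(cross_validate(out$patterns, out$spheres, k = 5L,
                                          seed = substream_seed(55, "d")))
  expect_identical(res2$fold_accuracy, res$fold_accuracy)
})

test_that("set-level generalisation detects shared condition components", {
  set.seed(120)
  n_vox <- 40L
  mask <- array(FALSE, c(10L, 4L, 3L)); mask[1:10, 1:4, 1] <- TRUE
  make_set <- function(cond_comp, label) {
    # 3 memories x 12 trials; each trial = memory pattern + condition
    # component + noise
    X <- do.call(rbind, lapply(1:3, function(m) {
      memp <- rnorm(n_vox)
      t(replicate(12, memp + cond_comp + rnorm(n_vox, sd = 0.5)))
    }))
    structure(list(X = X, memory = rep(paste0(label, "_", 1:3), each = 12),
                   condition = label, session = 1L,
                   trial = seq_len(36), voxel_index = which(mask)),
              class = "trial_pattern_set")
  }
  shared_a <- rnorm(n_vox, sd = 1.2)
  shared_b <- rnorm(n_vox, sd = 1.2)
  g <- set_generalization(make_set(shared_a, "rec"),
                          make_set(shared_b, "rem"), seed = 1)
  expect_gt(g$accuracy, 0.9)
  expect_equal(g$chance, 0.5)
  expect_length(g$per_pair, 9L)

  # no shared component: generalisation collapses to chance. A held-out
  # memory's trials tend to fall on one side together, so single-run
  # accuracy is lumpy; average over fresh constructions.
  g0 <- mean(vapply(1:8, function(i)
    set_generalization(make_set(shared_a * 0, "rec"),
                       make_set(shared_b * 0, "rem"), seed = i)$accuracy,
    numeric(1)))
  expect_lt(abs(g0 - 0.5), 0.15)

  one_mem <- make_set(shared_a, "rec")
  one_mem$memory <- rep("rec_1", 36)
  expect_error(set_generalization(one_mem, make_set(shared_b, "rem")),
               "validation")
})
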