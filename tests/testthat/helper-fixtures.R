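# Shared fixtures: small phantom worlds and independent oracles.
# Everything is generated in code; sizes are desk-scale (small ROIs) while
# the trial structure (9 memories x 14 reps, 2 sessions, TR 3.5 s) stays at
# the study's stated values.

small_geometry <- function(seed = 1L, targets = c(HC = 100)) {
  build_phantom_rois(c(22L, 14L, 14L), targets, seed = seed)
}

# one simulated subject at a given signal amplitude; returns the decoded
# accuracy for the "recent" 3-memory problem plus intermediate objects
decode_one_subject <- function(seed, amplitude, targets = c(HC = 80),
                               grid = c(18L, 12L, 12L),
                               support_frac = 0.4, support_overlap = NULL,
                               noise_sd = 1, k = 10L,
                               condition = "recent") {
  geom <- build_phantom_rois(grid, targets, seed = substream_seed(seed, "g"))
  des <- design_spec()
  sch <- make_trial_schedule(des, seed = substream_seed(seed, "s"))
  truth <- plant_patterns(geom, des, amplitudes = amplitude,
                          support_frac = support_frac,
                          support_overlap = support_overlap,
                          noise_sd = noise_sd,
                          seed = substream_seed(seed, "t"))
  bold <- synthesize_bold(geom, truth, sch, des)
  pat <- preprocess_subject(bold, sch, geom$roi_masks)
  roi <- names(targets)[1]
  sp <- enumerate_spheres(geom$roi_masks[[roi]], 3)
  ps <- subset_patterns(pat[[roi]], pat[[roi]]$condition == condition)
  res <- suppressMessages(cross_validate(ps, sp, k = k,
                                         seed = substream_seed(seed, "d")))
  list(accuracy = res$mean_accuracy, result = res, spheres = sp,
       patterns = ps, geometry = geom, truth = truth, schedule = sch)
}

# --- independent oracles ------------------------------------------------

# exact linear C-SVM via the dual QP (augmented-bias formulation: no
# equality constraint, box constraints only), solved with quadprog
svm_qp_oracle <- function(X, y, C = 1, ridge = 1e-8) {
  n <- nrow(X)
  Xa <- cbind(X, 1)                       # augmented bias feature
  Q <- (tcrossprod(Xa)) * (y %o% y)
  D <- Q + diag(ridge, n)
  A <- cbind(diag(n), -diag(n))
  b0 <- c(rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0)
  alpha <- sol$solution
  w_aug <- colSums(alpha * y * Xa)
  list(w = w_aug[seq_len(ncol(X))], b = w_aug[ncol(X) + 1])
}

# exhaustive ECOC-Hamming reimplementation in plain R: z-score with train
# stats, fit each one-vs-rest dichotomy with the QP oracle, threshold,
# enumerate codeword Hamming distances, lowest class index on ties
ecoc_oracle <- function(train_X, train_y, test_X, C = 1) {
  classes <- sort(unique(as.character(train_y)))
  K <- length(classes)
  mu <- colMeans(train_X)
  sd_ <- apply(train_X, 2, sd)
  sd_[sd_ <= 0] <- 1
  Ztr <- scale(train_X, center = mu, scale = sd_)
  Zte <- scale(test_X, center = mu, scale = sd_)
  code <- if (K == 2) matrix(c(1, 0), 2, 1) else diag(K)
  bits <- matrix(0L, nrow(test_X), ncol(code))
  for (l in seq_len(ncol(code))) {
    yy <- ifelse(code[match(as.character(train_y), classes), l] == 1, 1, -1)
    fit <- svm_qp_oracle(Ztr, yy, C)
    bits[, l] <- as.integer(Zte %*% fit$w + fit$b > 0)
  }
  pred <- apply(bits, 1, function(b) {
    dists <- apply(code, 1, function(cw) sum(cw != b))
    which.min(dists)                       # first minimum = lowest index
  })
  classes[pred]
}

# closed-form one-way repeated-measures F via stats::aov (independent path)
rm_anova_aov_oracle <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   cond = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  fit <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
  tab <- fit[["Error: subj:cond"]][[1]]
  list(F = tab["cond", "F value"], p = tab["cond", "Pr(>F)"])
}
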