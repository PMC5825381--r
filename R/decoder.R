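#' Stratified cross-validation fold plan
#'
#' Partitions trials into `k` folds stratified by class label, so per-class
#' test counts differ by at most one across folds and every class appears in
#' every training set. If the smallest class has fewer than `k` trials, `k`
#' is reduced to that count (with a message), mirroring the behaviour needed
#' after rating-based trial exclusion.
#'
#' @param labels class label per trial (character or factor).
#' @param k requested fold count (default 10).
#' @param seed integer seed.
#' @return integer fold id (1..k) per trial, with attribute `k`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("class(es) with fewer than 2 trials: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  k_eff <- min(as.integer(k), min(counts))
  if (k_eff < k)
    message("fold count reduced from ", k, " to ", k_eff,
            " (smallest class has ", min(counts), " trials)")
  rs <- get_rng_state()
  on.exit(restore_rng_state(rs))
  set.seed(substream_seed(seed, "folds"))
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    # rotate the fold cycle per class so small classes don't all load fold 1
    start <- sample.int(k_eff, 1L)
    fold[idx] <- ((seq_along(idx) + start - 2L) %% k_eff) + 1L
  }
  attr(fold, "k") <- k_eff
  fold
}

#' One-vs-rest ECOC codebook
#'
#' Binary codeword per class over dichotomies. For `n_classes = 3` this is
#' the three one-vs-rest dichotomies with codewords (1,0,0), (0,1,0),
#' (0,0,1) — minimum pairwise Hamming distance 2. For two classes a single
#' dichotomy with codewords (1) and (0).
#'
#' @param n_classes number of classes (>= 2).
#' @return integer matrix (classes x dichotomies) of 0/1 codewords, class
#'   `ecoc_codebook`.
#' @export
ecoc_codebook <- function(n_classes) {
  if (n_classes < 2) stop("n_classes must be >= 2 (validation error)")
  cb <- if (n_classes == 2L) matrix(c(1L, 0L), 2L, 1L) else diag(n_classes)
  storage.mode(cb) <- "integer"
  class(cb) <- c("ecoc_codebook", class(cb))
  cb
}

#' Decode ECOC binary outputs by Hamming distance
#'
#' Assigns each row of binary dichotomy outputs to the class whose codeword
#' is nearest in Hamming distance; ties go to the lowest class index
#' (deterministic reproducibility).
#'
#' @param bits 0/1 vector (one sample) or matrix (samples x dichotomies).
#' @param codebook an [ecoc_codebook()].
#' @return integer class index (1-based) per sample.
#' @export
hamming_decode <- function(bits, codebook) {
  if (is.null(dim(bits))) bits <- matrix(bits, 1L)
  apply(bits, 1L, function(b) {
    d <- rowSums(sweep(unclass(codebook), 2L, b, "!="))
    which.min(d)   # which.min takes the first (lowest index) on ties
  })
}

#' Train a linear soft-margin SVM
#'
#' Binary linear C-SVM (hinge loss, fixed regularisation `C`), solved by
#' dual coordinate descent. Used as the base classifier of every ECOC
#' dichotomy. Features are used as given; the ECOC wrapper z-scores them
#' with training-split statistics.
#'
#' @param X numeric matrix, samples x features.
#' @param y labels with exactly two levels; the first sorted level maps
#'   to +1.
#' @param C soft-margin cost (default 1).
#' @return list with `w` (feature weights), `b` (bias), `levels`.
#' @export
linear_svm <- function(X, y, C = 1) {
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L)
    stop("linear_svm needs exactly 2 classes, got ", length(lev))
  yy <- ifelse(as.character(y) == lev[1L], 1, -1)
  w <- .svm_train_cpp(as.matrix(X), yy, C)
  structure(list(w = w[seq_len(ncol(X))], b = w[ncol(X) + 1L],
                 levels = lev, C = C),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  s <- as.matrix(newdata) %*% object$w + object$b
  ifelse(s > 0, object$levels[1L], object$levels[2L])
}

#' ECOC multi-class classification
#'
#' Fits one linear SVM per codebook dichotomy on the training patterns
#' (restricted to the selected voxels, z-scored with training statistics)
#' and decodes each test pattern's binary output vector by minimum Hamming
#' distance, ties to the lowest class index.
#'
#' @param train_X,train_y training patterns and labels.
#' @param test_X test patterns.
#' @param features optional `feature_set` (or integer vector) of column
#'   indices; `NULL` uses all columns.
#' @param codebook an [ecoc_codebook()]; defaults to one-vs-rest over the
#'   training classes.
#' @param C SVM cost (default 1).
#' @return character vector of predicted labels.
#' @export
ecoc_classify <- function(train_X, train_y, test_X, features = NULL,
                          codebook = NULL, C = 1) {
  classes <- sort(unique(as.character(train_y)))
  if (length(classes) < 2L)
    stop("degenerate training set: fewer than 2 classes (validation error)")
  if (is.null(codebook)) codebook <- ecoc_codebook(length(classes))
  cols <- feature_columns(features, ncol(train_X))
  y0 <- match(as.character(train_y), classes) - 1L
  pred <- .ecoc_fit_predict_cpp(as.matrix(train_X)[, cols, drop = FALSE],
                                as.integer(y0),
                                as.matrix(test_X)[, cols, drop = FALSE],
                                unclass(codebook), C)
  classes[pred + 1L]
}

feature_columns <- function(features, n_col) {
  if (is.null(features)) return(seq_len(n_col))
  v <- if (inherits(features, "feature_set")) features$voxels else
    as.integer(features)
  if (length(v) == 0L)
    stop("empty feature set passed to the classifier")
  v
}

#' Searchlight feature selection on training data
#'
#' Scores every ROI-restricted searchlight sphere by inner cross-validated
#' ECOC-SVM accuracy computed on the training trials only (fully independent
#' of the test fold), then selects the single best-scoring sphere — the
#' voxel set carrying the greatest decoding information in the training
#' data. Ties go to the lowest sphere index. All per-sphere scores are
#' retained. If not even the best sphere beats chance the selection is
#' flagged (`fallback = TRUE`) but the best sphere is still returned, so the
#' classifier always has features.
#'
#' When a chronological trial `order` is supplied, the inner folds are
#' contiguous temporal blocks rather than stratified random splits. Blocking
#' matters: HRF-convolved noise is anti-correlated at the trial spacing
#' (the undershoot), and since the schedule forbids immediate repeats,
#' temporal neighbours are always different memories — random inner folds
#' let that structure inflate every sphere's score above chance, making the
#' above-chance threshold non-selective.
#'
#' @param train_X training patterns (trials x ROI voxels).
#' @param train_y training labels.
#' @param spheres a [enumerate_spheres()] `sphere_set` over the same ROI
#'   voxel ordering as the columns of `train_X`.
#' @param chance chance accuracy (default `1 / n_classes`).
#' @param C SVM cost (default 1).
#' @param inner_k inner fold count for sphere scoring (default 5).
#' @param seed integer seed for the inner folds (stratified mode only).
#' @param order optional chronological order (e.g. trial indices) of the
#'   training trials; when given, inner folds are contiguous temporal
#'   blocks (recommended; used by [cross_validate()]).
#' @param max_epochs solver epoch cap for sphere scoring (default 100; a
#'   lower cap than the final classifier's because thousands of small SVMs
#'   are fit per fold and scores only rank spheres).
#' @return an object of class `feature_set`: `voxels` (column indices),
#'   `scores` (per sphere), `selected_spheres`, `fallback` flag.
#' @export
select_features <- function(train_X, train_y, spheres, chance = NULL,
                            C = 1, inner_k = 5L, seed = 1L, order = NULL,
                            max_epochs = 100L) {
  classes <- sort(unique(as.character(train_y)))
  if (any(table(train_y) < 2L))
    stop("need >= 2 training trials per class")
  if (is.null(chance)) chance <- 1 / length(classes)
  codebook <- ecoc_codebook(length(classes))
  inner <- if (is.null(order)) {
    suppressMessages(make_folds(train_y, inner_k, seed))
  } else {
    if (length(order) != length(train_y))
      stop("`order` must have one entry per training trial")
    as.integer(cut(rank(order, ties.method = "first"), inner_k,
                   labels = FALSE))
  }
  y0 <- match(as.character(train_y), classes) - 1L
  scores <- .score_spheres_cpp(as.matrix(train_X), as.integer(y0),
                               as.integer(inner), spheres$members,
                               unclass(codebook), C,
                               max_epochs = as.integer(max_epochs))
  sel <- which.max(scores)          # first maximum = lowest sphere index
  fallback <- scores[sel] <= chance # nothing informative in training data
  voxels <- sort(spheres$members[[sel]])
  structure(list(voxels = voxels, scores = as.numeric(scores),
                 selected_spheres = sel, fallback = fallback,
                 chance = chance),
            class = "feature_set")
}

#' Cross-validated searchlight ECOC-SVM decoding
#'
#' The MVPA core: stratified `k`-fold cross-validation where, within each
#' fold, searchlight feature selection runs on the training trials only and
#' the ECOC linear SVM (cost `C`) is tested on the held-out trials. Reports
#' per-fold and mean accuracy against chance = 1 / n_classes.
#'
#' @param patterns a `trial_pattern_set` (typically one condition's trials).
#' @param spheres `sphere_set` for the ROI.
#' @param k fold count (default 10).
#' @param C SVM cost (default 1).
#' @param seed integer seed.
#' @param inner_k inner fold count for sphere scoring (default 5).
#' @param labels optional label vector overriding `patterns$memory`.
#' @return an object of class `decoding_result`: `fold_accuracy`,
#'   `mean_accuracy`, `chance`, `feature_sets` (per fold), `confusion`,
#'   `classes`, `k`, `n_trials`.
#' @export
cross_validate <- function(patterns, spheres, k = 10L, C = 1, seed = 1L,
                           inner_k = 5L, labels = NULL) {
  y <- if (is.null(labels)) patterns$memory else labels
  X <- patterns$X
  classes <- sort(unique(as.character(y)))
  chance <- 1 / length(classes)
  fold <- make_folds(y, k, seed)
  k_eff <- attr(fold, "k")
  fold_acc <- numeric(k_eff)
  feature_sets <- vector("list", k_eff)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes, predicted = classes))
  ord <- if (!is.null(patterns$trial)) patterns$trial else seq_along(y)
  for (f in seq_len(k_eff)) {
    tr <- fold != f
    fs <- select_features(X[tr, , drop = FALSE], y[tr], spheres,
                          chance = chance, C = C, inner_k = inner_k,
                          seed = substream_seed(seed, "inner", f),
                          order = ord[tr])
    pred <- ecoc_classify(X[tr, , drop = FALSE], y[tr],
                          X[!tr, , drop = FALSE], features = fs, C = C)
    truth <- as.character(y[!tr])
    fold_acc[f] <- mean(pred == truth)
    for (i in seq_along(truth))
      confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
    feature_sets[[f]] <- fs
  }
  structure(list(fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 chance = chance,
                 feature_sets = feature_sets,
                 confusion = confusion,
                 classes = classes,
                 k = k_eff,
                 n_trials = length(y),
                 n_voxels = ncol(X),
                 seed = as.integer(seed)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "decoding_result: %d classes, %d trials, %d folds\n  mean accuracy %.3f (chance %.3f)\n  fold accuracies: %s\n",
    length(x$classes), x$n_trials, x$k, x$mean_accuracy, x$chance,
    paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  invisible(x)
}

#' Serialise a decoding result to JSON
#'
#' @param result a `decoding_result`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_decoding_result <- function(result, path) {
  x <- list(classes = result$classes, k = result$k,
            n_trials = result$n_trials, chance = result$chance,
            fold_accuracy = result$fold_accuracy,
            mean_accuracy = result$mean_accuracy,
            confusion = result$confusion,
            per_fold_voxel_count = vapply(result$feature_sets,
                                          function(f) length(f$voxels), 1L),
            seed = result$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Set-level generalisation decoding between two conditions
#'
#' Tests whether the *condition* (memory set) is decodable in a way that
#' generalises across the individual memories within each set: a binary
#' condition classifier is trained on the trials of all but one held-out
#' memory per condition and tested on the held-out memories' trials, for
#' every held-out pair; accuracies are averaged. Chance is 1/2. Above-chance
#' accuracy requires a shared condition-level pattern component, not
#' memory-specific patterns.
#'
#' @param patterns_a,patterns_b `trial_pattern_set`s for the two conditions
#'   (same ROI voxel ordering).
#' @param spheres optional `sphere_set`; when supplied, searchlight feature
#'   selection (chance 1/2) runs on each training split.
#' @param C SVM cost (default 1).
#' @param seed integer seed.
#' @return list with `accuracy` (mean over held-out pairs), `per_pair`
#'   accuracies, `chance`.
#' @export
set_generalization <- function(patterns_a, patterns_b, spheres = NULL,
                               C = 1, seed = 1L) {
  mems_a <- unique(patterns_a$memory)
  mems_b <- unique(patterns_b$memory)
  if (length(mems_a) < 2L || length(mems_b) < 2L)
    stop("need >= 2 memories per condition (validation error)")
  X <- rbind(patterns_a$X, patterns_b$X)
  cond <- c(rep("A", nrow(patterns_a$X)), rep("B", nrow(patterns_b$X)))
  mem <- c(patterns_a$memory, patterns_b$memory)
  combos <- expand.grid(a = mems_a, b = mems_b, stringsAsFactors = FALSE)
  acc <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    te <- mem == combos$a[i] | mem == combos$b[i]
    fs <- NULL
    if (!is.null(spheres))
      fs <- select_features(X[!te, , drop = FALSE], cond[!te], spheres,
                            chance = 0.5, C = C,
                            seed = substream_seed(seed, "setgen", i))
    pred <- ecoc_classify(X[!te, , drop = FALSE], cond[!te],
                          X[te, , drop = FALSE], features = fs, C = C)
    acc[i] <- mean(pred == cond[te])
  }
  list(accuracy = mean(acc), per_pair = acc, chance = 0.5)
}
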