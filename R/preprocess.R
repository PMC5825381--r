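#' Preprocessing configuration
#'
#' Parameters of the fixed preprocessing pipeline:
#' smooth -> detrend -> HRF-convolve -> shift onsets -> extract -> filter.
#'
#' @param smooth_fwhm_mm Gaussian smoothing FWHM in mm (default 3; minimal
#'   smoothing at 1.5 mm voxels).
#' @param tr_s repetition time in seconds (default 3.5).
#' @param hrf_delay_s effective BOLD delay compensated by the onset shift
#'   (default 12 s: the natural ~6 s delay doubled by HRF convolution).
#' @param recall_s recall-period duration in seconds (default 12, giving
#'   ceil(12 / 3.5) = 4 volumes per trial).
#' @param min_vividness,min_consistency rating thresholds in 1..5
#'   (default 4; trials below either threshold are excluded).
#' @param volumes_as_samples if `TRUE`, each trial contributes its
#'   individual volumes as separate samples; default `FALSE` averages the
#'   trial window into one pattern (avoids temporal-autocorrelation leakage
#'   across cross-validation folds).
#' @return an object of class `preproc_config`.
#' @export
preproc_config <- function(smooth_fwhm_mm = 3, tr_s = 3.5, hrf_delay_s = 12,
                           recall_s = 12, min_vividness = 4L,
                           min_consistency = 4L,
                           volumes_as_samples = FALSE) {
  if (smooth_fwhm_mm < 0 || tr_s <= 0 || hrf_delay_s < 0 || recall_s <= 0)
    stop("durations must be positive (fwhm and delay may be 0)")
  if (min_vividness < 1 || min_vividness > 5 ||
      min_consistency < 1 || min_consistency > 5)
    stop("rating thresholds must be in 1..5")
  structure(list(smooth_fwhm_mm = smooth_fwhm_mm, tr_s = tr_s,
                 hrf_delay_s = hrf_delay_s, recall_s = recall_s,
                 min_vividness = as.integer(min_vividness),
                 min_consistency = as.integer(min_consistency),
                 volumes_as_samples = isTRUE(volumes_as_samples)),
            class = "preproc_config")
}

# 1D Gaussian convolution matrix (zero padding at edges), n x n
gaussian_band_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  offs <- (-half):half
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (j in seq_along(offs)) {
    o <- offs[j]
    rows <- seq_len(n) + o
    ok <- rows >= 1L & rows <= n
    K[cbind(rows[ok], seq_len(n)[ok])] <- K[cbind(rows[ok], seq_len(n)[ok])] + w[j]
  }
  K
}

#' Spatially smooth a volume series
#'
#' Convolves each volume with an isotropic Gaussian kernel of the given
#' full-width-at-half-maximum, converted from mm to voxels via the series'
#' voxel size (sigma = FWHM / (2 sqrt(2 ln 2))). Zero padding outside the
#' grid. `fwhm_mm = 0` is the identity.
#'
#' @param vol a `volume_series`.
#' @param fwhm_mm kernel FWHM in mm (>= 0).
#' @return the smoothed `volume_series`.
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 3) {
  stopifnot(inherits(vol, "volume_series"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_size_mm
  d <- dim(vol$data)
  x <- vol$data
  # separable convolution: bring each spatial axis first, multiply by its
  # banded kernel matrix, restore
  for (ax in 1:3) {
    K <- gaussian_band_matrix(d[ax], sigma)
    perm <- c(ax, setdiff(1:4, ax))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- K %*% matrix(xp, d[ax])
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  vol$data <- x
  vol
}

#' Remove per-session linear drift
#'
#' For each voxel and session, subtracts the best-fit (least-squares) linear
#' trend in time while retaining the session mean. Removes slow scanner
#' drift without recentring the signal.
#'
#' @param vol a `volume_series`.
#' @param session_bounds optional 2-column matrix (`start`, `end`)
#'   overriding the series' own session partition.
#' @return the detrended `volume_series`.
#' @export
detrend_linear <- function(vol, session_bounds = NULL) {
  stopifnot(inherits(vol, "volume_series"))
  bounds <- if (is.null(session_bounds)) vol$session_bounds
            else as.matrix(session_bounds)
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  for (s in seq_len(nrow(bounds))) {
    idx <- bounds[s, 1]:bounds[s, 2]
    if (length(idx) < 3L)
      stop("session ", s, " has fewer than 3 volumes (validation error)")
    tt <- seq_along(idx) - mean(seq_along(idx))   # centred time
    denom <- sum(tt^2)
    slope <- (m[, idx, drop = FALSE] %*% tt) / denom
    m[, idx] <- m[, idx, drop = FALSE] - slope %*% t(tt)
  }
  vol$data <- array(m, d)
  vol
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: a gamma density with response delay 6 s minus
#' an undershoot gamma with delay 16 s scaled by 1/6 (shape/rate 6/1 and
#' 16/1, the usual defaults). Zero for negative times.
#'
#' @param t time in seconds (vector).
#' @return HRF values at `t` (unnormalised).
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

#' Convolve a volume series with the canonical HRF
#'
#' Causally convolves each voxel time course with the canonical double-gamma
#' HRF sampled at the TR (kernel normalised to unit sum, so a constant
#' series is unchanged). Convolution restarts at each session boundary.
#' Output length equals input length (the tail is truncated). Applied to
#' already-haemodynamic data this doubles the effective BOLD delay, which is
#' what the downstream onset shift compensates.
#'
#' @param vol a `volume_series` with TR metadata.
#' @return the convolved `volume_series`.
#' @export
hrf_convolve <- function(vol) {
  stopifnot(inherits(vol, "volume_series"))
  kernel <- canonical_hrf(seq(0, 32, by = vol$tr_s))
  kernel <- kernel / sum(kernel)
  d <- dim(vol$data)
  m <- t(matrix(vol$data, prod(d[1:3]), d[4]))   # time x voxels
  for (s in seq_len(nrow(vol$session_bounds))) {
    idx <- vol$session_bounds[s, 1]:vol$session_bounds[s, 2]
    m[idx, ] <- causal_convolve(m[idx, , drop = FALSE], kernel)
  }
  vol$data <- array(t(m), d)
  vol
}

#' Onset shift in volumes compensating the HRF delay
#'
#' Number of whole volumes the trial onsets are shifted forward to
#' compensate the effective BOLD delay: `round(delay_s / tr_s)` with ties
#' rounded away from zero. For the study parameters (12 s delay, TR 3.5 s)
#' this is 3 volumes.
#'
#' @param delay_s effective delay in seconds (>= 0).
#' @param tr_s repetition time in seconds (> 0).
#' @return integer volume count.
#' @export
compute_onset_shift <- function(delay_s, tr_s) {
  if (tr_s <= 0) stop("tr_s must be > 0")
  if (delay_s < 0) stop("delay_s must be >= 0 (validation error)")
  as.integer(floor(delay_s / tr_s + 0.5))
}

#' Filter trials by vividness and consistency ratings
#'
#' Retains exactly the trials with `vividness >= min_vividness` and
#' `consistency >= min_consistency` (defaults 4 and 4: only the most vivid
#' and most consistently recalled trials enter the MVPA), preserving order.
#'
#' @param trials a `trial_table`.
#' @param min_vividness,min_consistency thresholds in 1..5.
#' @return the filtered `trial_table`.
#' @export
filter_trials <- function(trials, min_vividness = 4L, min_consistency = 4L) {
  if (is.null(trials$vividness) || is.null(trials$consistency) ||
      anyNA(trials$vividness) || anyNA(trials$consistency))
    stop("trials must carry complete vividness/consistency ratings")
  if (any(trials$vividness < 1 | trials$vividness > 5) ||
      any(trials$consistency < 1 | trials$consistency > 5))
    stop("ratings must lie in 1..5")
  keep <- trials$vividness >= min_vividness &
    trials$consistency >= min_consistency
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("session_volumes", "tr_s"))
    attr(out, a) <- attr(trials, a)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Extract per-trial ROI pattern vectors
#'
#' For each trial, gathers the `ceil(recall_s / tr_s)` volumes starting at
#' the shifted onset volume (`floor(onset / tr_s) + compute_onset_shift()`,
#' 0-based, half-open window) over the ROI voxels. By default the window is
#' averaged into one pattern vector per trial; with
#' `volumes_as_samples = TRUE` each volume becomes its own sample.
#'
#' @param vol a preprocessed `volume_series`.
#' @param trials a `trial_table` (typically already rating-filtered).
#' @param roi_mask 3D logical array on the series grid.
#' @param config a [preproc_config()].
#' @return an object of class `trial_pattern_set`: list with matrix `X`
#'   (samples x ROI voxels), `memory`, `condition`, `session`, `trial`
#'   (row metadata) and `voxel_index` (linear grid indices of the columns).
#' @export
extract_trial_patterns <- function(vol, trials, roi_mask,
                                   config = preproc_config()) {
  stopifnot(inherits(vol, "volume_series"))
  d <- dim(vol$data)
  if (!identical(dim(roi_mask), d[1:3]))
    stop("roi_mask does not match the series grid")
  roi_idx <- which(roi_mask != 0)
  if (length(roi_idx) == 0L) stop("roi_mask is empty")
  n_t <- d[4]
  shift <- compute_onset_shift(config$hrf_delay_s, config$tr_s)
  n_win <- as.integer(ceiling(config$recall_s / config$tr_s))
  start0 <- floor(trials$onset / config$tr_s) + shift       # 0-based
  bad <- which(start0 + n_win > n_t | start0 < 0)
  if (length(bad) > 0L)
    stop("trial window(s) exceed the series for trial(s): ",
         paste(bad, collapse = ", "))
  m <- matrix(vol$data, prod(d[1:3]), n_t)[roi_idx, , drop = FALSE]
  n_trials <- nrow(trials)
  if (config$volumes_as_samples) {
    X <- matrix(NA_real_, n_trials * n_win, length(roi_idx))
    for (i in seq_len(n_trials)) {
      cols <- (start0[i] + 1L):(start0[i] + n_win)
      X[((i - 1L) * n_win + 1L):(i * n_win), ] <- t(m[, cols, drop = FALSE])
    }
    rep_i <- rep(seq_len(n_trials), each = n_win)
  } else {
    X <- matrix(NA_real_, n_trials, length(roi_idx))
    for (i in seq_len(n_trials)) {
      cols <- (start0[i] + 1L):(start0[i] + n_win)
      X[i, ] <- rowMeans(m[, cols, drop = FALSE])
    }
    rep_i <- seq_len(n_trials)
  }
  structure(list(X = X,
                 memory = trials$memory[rep_i],
                 condition = trials$condition[rep_i],
                 session = trials$session[rep_i],
                 trial = rep_i,
                 voxel_index = roi_idx,
                 n_volumes_per_trial = n_win),
            class = "trial_pattern_set")
}

#' @export
print.trial_pattern_set <- function(x, ...) {
  cat(sprintf("trial_pattern_set: %d samples x %d voxels (%d memories)\n",
              nrow(x$X), ncol(x$X), length(unique(x$memory))))
  invisible(x)
}

#' Subset a trial pattern set
#'
#' @param patterns a `trial_pattern_set`.
#' @param rows logical or integer sample index.
#' @return the subset `trial_pattern_set`.
#' @export
subset_patterns <- function(patterns, rows) {
  patterns$X <- patterns$X[rows, , drop = FALSE]
  for (f in c("memory", "condition", "session", "trial"))
    patterns[[f]] <- patterns[[f]][rows]
  patterns
}

#' Run the full preprocessing pipeline for one subject
#'
#' Fixed order: smooth -> per-session linear detrend -> HRF convolution ->
#' onset shift -> trial-window extraction -> rating filter. Returns one
#' pattern set per ROI, containing only retained trials.
#'
#' @param vol the raw (realigned) `volume_series`.
#' @param trials the full `trial_table`.
#' @param roi_masks named list of 3D logical masks.
#' @param config a [preproc_config()].
#' @return named list of `trial_pattern_set`, one per ROI.
#' @export
preprocess_subject <- function(vol, trials, roi_masks,
                               config = preproc_config()) {
  vol <- smooth_gaussian(vol, config$smooth_fwhm_mm)
  vol <- detrend_linear(vol)
  vol <- hrf_convolve(vol)
  out <- lapply(roi_masks, function(mask) {
    ps <- extract_trial_patterns(vol, trials, mask, config)
    keep <- trials$vividness >= config$min_vividness &
      trials$consistency >= config$min_consistency
    subset_patterns(ps, keep[ps$trial])
  })
  names(out) <- names(roi_masks)
  out
}
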