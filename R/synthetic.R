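#' Experimental design specification
#'
#' Describes the slow event-related recall design: 9 memories (3 per
#' condition) each recalled 14 times, split over two scanning sessions, with
#' a 3 s word cue, 12 s eyes-closed recall, 1.5 s tone, two self-paced
#' ratings (up to 3 s each) and a 4 s rest. TR is 3.5 s. The rating filter
#' retains on average `retention_prob` of trials (vividness and consistency
#' both >= 4).
#'
#' @param n_memories_per_condition memories per condition (default 3).
#' @param conditions condition labels (default recent, remote, control).
#' @param repetitions recall trials per memory (default 14).
#' @param n_sessions scanning sessions (default 2).
#' @param cue_s,recall_s,tone_s,rating_s,rest_s trial-phase durations in
#'   seconds (defaults 3, 12, 1.5, 6, 4).
#' @param tr_s repetition time in seconds (default 3.5).
#' @param retention_prob probability a trial passes the rating filter
#'   (default 0.79, i.e. ~11.07 of 14 trials).
#' @param lead_in_s,tail_s baseline padding at session start/end in seconds.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_memories_per_condition = 3L,
                        conditions = c("recent", "remote", "control"),
                        repetitions = 14L,
                        n_sessions = 2L,
                        cue_s = 3, recall_s = 12, tone_s = 1.5,
                        rating_s = 6, rest_s = 4,
                        tr_s = 3.5,
                        retention_prob = 0.79,
                        lead_in_s = 14, tail_s = 21) {
  durs <- c(cue_s, recall_s, tone_s, rating_s, rest_s, tr_s)
  if (any(durs <= 0)) stop("all durations and tr_s must be > 0")
  if (retention_prob <= 0 || retention_prob > 1)
    stop("retention_prob must be in (0, 1]")
  n_mem <- n_memories_per_condition * length(conditions)
  if ((n_mem * repetitions) %% n_sessions != 0L)
    stop("repetitions x total memories must be divisible by n_sessions")
  d <- list(n_memories_per_condition = as.integer(n_memories_per_condition),
            conditions = conditions,
            repetitions = as.integer(repetitions),
            n_sessions = as.integer(n_sessions),
            cue_s = cue_s, recall_s = recall_s, tone_s = tone_s,
            rating_s = rating_s, rest_s = rest_s, tr_s = tr_s,
            retention_prob = retention_prob,
            lead_in_s = lead_in_s, tail_s = tail_s)
  class(d) <- "design_spec"
  d
}

design_memories <- function(design) {
  unlist(lapply(design$conditions, function(cc)
    paste0(cc, "_", seq_len(design$n_memories_per_condition))))
}

design_trial_duration <- function(design) {
  design$cue_s + design$recall_s + design$tone_s + design$rating_s + design$rest_s
}

#' Phantom acquisition geometry
#'
#' A voxel grid with named, pairwise-disjoint binary ROI masks. `long_axis`
#' names the grid axis running along the hippocampal anterior-posterior
#' direction (used by [split_long_axis()] and by the phantom builder to
#' elongate the hippocampus mask).
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param roi_masks named list of 3D logical arrays with dim `grid_shape`.
#' @param voxel_size_mm isotropic voxel size (default 1.5).
#' @param long_axis axis index (1-3) of the hippocampal long axis.
#' @return an object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(grid_shape, roi_masks, voxel_size_mm = 1.5,
                             long_axis = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be > 0")
  if (!is.list(roi_masks) || is.null(names(roi_masks)) ||
      any(names(roi_masks) == ""))
    stop("roi_masks must be a named list of 3D logical arrays")
  occupied <- array(FALSE, grid_shape)
  for (nm in names(roi_masks)) {
    m <- roi_masks[[nm]]
    if (!is.array(m) || !identical(dim(m), grid_shape))
      stop("mask '", nm, "' does not match grid_shape")
    m <- m != 0
    if (!any(m)) stop("mask '", nm, "' is empty")
    if (any(occupied & m)) stop("mask '", nm, "' overlaps another ROI")
    occupied <- occupied | m
    roi_masks[[nm]] <- m
  }
  structure(list(grid_shape = grid_shape, roi_masks = roi_masks,
                 voxel_size_mm = voxel_size_mm,
                 long_axis = as.integer(long_axis)),
            class = "phantom_geometry")
}

# lattice-point count inside an ellipsoid with semi-axes `semi`
ellipsoid_voxels <- function(semi) {
  ranges <- lapply(semi, function(a) seq(-floor(a), floor(a)))
  g <- expand.grid(x = ranges[[1]], y = ranges[[2]], z = ranges[[3]])
  keep <- (g$x / semi[1])^2 + (g$y / semi[2])^2 + (g$z / semi[3])^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

#' Build disjoint phantom ROI masks
#'
#' Places one ellipsoidal mask per requested ROI at seeded random positions
#' on the grid. ROIs named `HC` (or starting with `HC`) are elongated 3:1
#' along `long_axis`, mimicking the hippocampus; all others are spherical.
#' Ellipsoid radii are tuned so each voxel count lands within 5% of its
#' target (the study's mean ROI sizes at 1.5 mm EPI resolution were
#' HC 928, vmPFC 1169 voxels).
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param roi_size_targets named integer vector of target voxel counts.
#' @param seed integer seed.
#' @param voxel_size_mm voxel size (default 1.5).
#' @param long_axis hippocampal long-axis index (default 1).
#' @return a `phantom_geometry`.
#' @export
build_phantom_rois <- function(grid_shape,
                               roi_size_targets = c(HC = 928, vmPFC = 1169),
                               seed = 1L, voxel_size_mm = 1.5,
                               long_axis = 1L) {
  if (any(roi_size_targets <= 0)) stop("roi_size_targets must be positive")
  grid_shape <- as.integer(grid_shape)
  rs <- get_rng_state()
  on.exit(restore_rng_state(rs))
  set.seed(substream_seed(seed, "phantom"))

  offsets <- list()
  for (nm in names(roi_size_targets)) {
    shape <- if (grepl("^HC", nm)) {
      s <- c(1, 1, 1); s[long_axis] <- 3; s
    } else c(1, 1, 1)
    target <- roi_size_targets[[nm]]
    # bracket then bisect the scale r so the lattice count hits the target
    lo <- 0.5; hi <- 1
    while (nrow(ellipsoid_voxels(hi * shape)) < target) {
      hi <- hi * 1.5
      if (hi * max(shape) > 2 * max(grid_shape) + 10)
        stop("grid too small: ROI '", nm, "' cannot fit (capacity error)")
    }
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (nrow(ellipsoid_voxels(mid * shape)) < target) lo <- mid else hi <- mid
    }
    vox <- ellipsoid_voxels(hi * shape)
    # trim the outermost surplus voxels to land exactly on the target
    r2 <- (vox[, 1] / shape[1])^2 + (vox[, 2] / shape[2])^2 +
      (vox[, 3] / shape[3])^2
    vox <- vox[order(r2)[seq_len(round(target))], , drop = FALSE]
    offsets[[nm]] <- vox
  }

  occupied <- array(FALSE, grid_shape)
  masks <- list()
  for (nm in names(offsets)) {
    vox <- offsets[[nm]]
    span_lo <- apply(vox, 2, min); span_hi <- apply(vox, 2, max)
    lo_c <- 1L - span_lo; hi_c <- grid_shape - span_hi
    if (any(hi_c < lo_c))
      stop("grid too small: ROI '", nm, "' does not fit (capacity error)")
    placed <- FALSE
    for (attempt in 1:200) {
      centre <- vapply(1:3, function(a)
        if (hi_c[a] > lo_c[a]) sample(lo_c[a]:hi_c[a], 1L) else lo_c[a],
        integer(1))
      coords <- sweep(vox, 2, centre, "+")
      idx <- coords[, 1] + (coords[, 2] - 1L) * grid_shape[1] +
        (coords[, 3] - 1L) * grid_shape[1] * grid_shape[2]
      if (!any(occupied[idx])) {
        m <- array(FALSE, grid_shape); m[idx] <- TRUE
        masks[[nm]] <- m
        occupied[idx] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("grid too small to place all ROIs disjointly (capacity error)")
  }
  phantom_geometry(grid_shape, masks, voxel_size_mm, long_axis)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
  invisible(NULL)
}

#' Generate a pseudo-random trial schedule
#'
#' Every memory appears exactly `repetitions` times, split equally across
#' sessions; within a session no memory is repeated on consecutive trials.
#' Onsets (seconds from series start, recall-period onset = trial start +
#' cue duration) follow the cue/recall/tone/rating/rest grid, with
#' `lead_in_s` baseline at each session start. Vividness and consistency
#' ratings are drawn independently on 1..5 with P(rating >= 4) =
#' sqrt(`retention_prob`), so a trial passes the joint >= 4 filter with
#' probability `retention_prob`.
#'
#' @param design a [design_spec()].
#' @param seed integer seed.
#' @param max_retries attempts at a no-immediate-repeat order before failing.
#' @return a `data.frame` (class `trial_table`) with columns `onset`,
#'   `duration`, `memory`, `condition`, `session`, `vividness`,
#'   `consistency`, plus attributes `session_volumes` and `tr_s`.
#' @export
make_trial_schedule <- function(design, seed = 1L, max_retries = 500L) {
  stopifnot(inherits(design, "design_spec"))
  rs <- get_rng_state()
  on.exit(restore_rng_state(rs))
  set.seed(substream_seed(seed, "schedule"))

  mems <- design_memories(design)
  conds <- rep(design$conditions, each = design$n_memories_per_condition)
  names(conds) <- mems
  n_sess <- design$n_sessions
  per_sess_counts <- balanced_session_counts(length(mems), design$repetitions,
                                             n_sess)

  order_one_session <- function(counts) {
    for (attempt in seq_len(max_retries)) {
      remaining <- counts
      seq_out <- character(sum(counts))
      prev <- ""
      ok <- TRUE
      for (i in seq_along(seq_out)) {
        allowed <- names(remaining)[remaining > 0 & names(remaining) != prev]
        if (length(allowed) == 0L) { ok <- FALSE; break }
        pick <- if (length(allowed) == 1L) allowed else
          sample(allowed, 1L, prob = remaining[allowed])
        seq_out[i] <- pick
        remaining[pick] <- remaining[pick] - 1L
        prev <- pick
      }
      if (ok) return(seq_out)
    }
    stop("no valid no-immediate-repeat order found (scheduling error)")
  }

  trial_dur <- design_trial_duration(design)
  n_per_sess <- (length(mems) * design$repetitions) %/% n_sess
  sess_dur_s <- design$lead_in_s + n_per_sess * trial_dur + design$tail_s
  sess_vols <- rep(as.integer(ceiling(sess_dur_s / design$tr_s)), n_sess)

  rows <- list()
  for (s in seq_len(n_sess)) {
    counts <- per_sess_counts[, s]
    names(counts) <- mems
    ord <- order_one_session(counts)
    sess_start_s <- sum(sess_vols[seq_len(s - 1L)]) * design$tr_s
    onsets <- sess_start_s + design$lead_in_s +
      (seq_along(ord) - 1L) * trial_dur + design$cue_s
    p_hi <- sqrt(design$retention_prob)
    draw_rating <- function(n) {
      sample(1:5, n, replace = TRUE,
             prob = c(rep((1 - p_hi) / 3, 3), p_hi / 2, p_hi / 2))
    }
    rows[[s]] <- data.frame(
      onset = onsets, duration = design$recall_s, memory = ord,
      condition = unname(conds[ord]), session = s,
      vividness = draw_rating(length(ord)),
      consistency = draw_rating(length(ord)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "session_volumes") <- sess_vols
  attr(out, "tr_s") <- design$tr_s
  class(out) <- c("trial_table", "data.frame")
  out
}

# split `reps` repetitions of each of `n_mem` memories over `n_sess` equal
# sessions; returns n_mem x n_sess count matrix
balanced_session_counts <- function(n_mem, reps, n_sess) {
  base <- reps %/% n_sess
  rem <- reps %% n_sess
  counts <- matrix(base, n_mem, n_sess)
  if (rem > 0L) {
    # distribute each memory's remainder so session totals stay equal
    quota <- rep((n_mem * reps) %/% n_sess - n_mem * base, n_sess)
    for (m in seq_len(n_mem)) {
      sess <- order(-quota)[seq_len(rem)]
      counts[m, sess] <- counts[m, sess] + 1L
      quota[sess] <- quota[sess] - 1L
    }
  }
  counts
}

#' Plant ground-truth memory patterns
#'
#' Gives each memory, in each ROI, a sparse voxel weight map: a support of
#' `round(support_frac * n_roi_voxels)` voxels with standard-normal weights,
#' scaled at synthesis time by the (ROI, condition) amplitude. When
#' `support_overlap` is a number in \[0, 1\], supports are structured so any
#' two memories from *different* conditions share exactly
#' `round(support_overlap * support_size)` voxels (a randomly placed common
#' core), with the remainder drawn from disjoint per-condition pools laid
#' out as contiguous slabs along the ROI's long axis (mirroring the
#' long-axis separation of memory representations seen in hippocampal
#' information maps); `NULL` leaves supports unconstrained (independent
#' uniform draws).
#'
#' @param geometry a `phantom_geometry`.
#' @param design a `design_spec`.
#' @param amplitudes signal scale per (ROI, condition): a single number, or
#'   a matrix with ROI rows and condition columns (dimnames required).
#' @param support_frac fraction of ROI voxels in each memory's support
#'   (default 0.4).
#' @param support_overlap cross-condition shared-support fraction in
#'   \[0, 1\], or `NULL` for unconstrained supports.
#' @param noise_sd Gaussian noise SD in signal units (default 1).
#' @param drift_slope linear scanner drift, signal units per volume,
#'   restarting each session (default 0.05).
#' @param seed integer seed.
#' @return an object of class `ground_truth`.
#' @export
plant_patterns <- function(geometry, design, amplitudes = 1,
                           support_frac = 0.4, support_overlap = NULL,
                           noise_sd = 1, drift_slope = 0.05, seed = 1L) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(design, "design_spec"))
  if (!is.null(support_overlap) &&
      (support_overlap < 0 || support_overlap > 1))
    stop("support_overlap must be in [0, 1]")
  mems <- design_memories(design)
  conds <- rep(design$conditions, each = design$n_memories_per_condition)
  amplitudes <- expand_amplitudes(amplitudes, names(geometry$roi_masks),
                                  design$conditions)
  rs <- get_rng_state()
  on.exit(restore_rng_state(rs))
  set.seed(substream_seed(seed, "patterns"))

  rois <- list()
  for (nm in names(geometry$roi_masks)) {
    n_vox <- sum(geometry$roi_masks[[nm]])
    m <- max(1L, round(support_frac * n_vox))
    pools <- NULL
    if (is.null(support_overlap)) {
      supports <- lapply(mems, function(x) sort(sample.int(n_vox, m)))
    } else {
      n_shared <- round(support_overlap * m)
      n_priv <- m - n_shared
      n_cond <- length(design$conditions)
      if (n_shared + n_cond * n_priv > n_vox)
        stop("support_overlap/support_frac infeasible in ROI '", nm,
             "': need ", n_shared + n_cond * n_priv, " voxels, have ", n_vox)
      shared <- if (n_shared > 0L) sort(sample.int(n_vox, n_shared))
                else integer(0)
      # condition pools: contiguous slabs along the long axis
      coords <- arrayInd(which(geometry$roi_masks[[nm]]),
                         geometry$grid_shape)
      axis_order <- order(coords[, geometry$long_axis],
                          coords[, (geometry$long_axis %% 3) + 1L],
                          coords[, ((geometry$long_axis + 1L) %% 3) + 1L])
      rest <- setdiff(axis_order, shared)
      pool_size <- length(rest) %/% n_cond
      pools <- lapply(seq_len(n_cond), function(ci)
        rest[((ci - 1L) * pool_size + 1L):(ci * pool_size)])
      names(pools) <- design$conditions
      supports <- lapply(seq_along(mems), function(mi) {
        pool <- pools[[conds[mi]]]
        sort(c(shared, if (n_priv > 0L) sample(pool, n_priv)))
      })
    }
    weights <- lapply(supports, function(s) stats::rnorm(length(s)))
    names(supports) <- names(weights) <- mems
    rois[[nm]] <- list(supports = supports, weights = weights,
                       n_vox = n_vox, pools = pools)
  }
  structure(list(rois = rois, amplitudes = amplitudes,
                 memories = mems, conditions = stats::setNames(conds, mems),
                 support_frac = support_frac,
                 support_overlap = support_overlap,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

expand_amplitudes <- function(amplitudes, roi_names, conditions) {
  if (is.matrix(amplitudes)) {
    if (is.null(dimnames(amplitudes)))
      stop("amplitude matrix needs ROI row names and condition column names")
    out <- matrix(NA_real_, length(roi_names), length(conditions),
                  dimnames = list(roi_names, conditions))
    out[] <- amplitudes[roi_names, conditions]
  } else if (length(amplitudes) == 1L) {
    out <- matrix(as.numeric(amplitudes), length(roi_names),
                  length(conditions),
                  dimnames = list(roi_names, conditions))
  } else stop("amplitudes must be a scalar or a named ROI x condition matrix")
  if (any(out < 0)) stop("amplitudes must be >= 0")
  out
}

#' Re-realise ground truth at a later timepoint
#'
#' Models representational drift between two studies of the same subject:
#' each memory keeps `round(timepoint_overlap * support_size)` of its support
#' voxels and re-draws the remainder (from its condition pool when supports
#' are structured, otherwise from voxels outside the old support). Kept
#' voxels keep their weights; new voxels get fresh standard-normal weights.
#' `timepoint_overlap = 1` returns the truth unchanged.
#'
#' @param truth a `ground_truth`.
#' @param timepoint_overlap fraction in \[0, 1\] of support retained.
#' @param seed integer seed for the re-draw.
#' @return a new `ground_truth`.
#' @export
ground_truth_at_timepoint <- function(truth, timepoint_overlap, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (timepoint_overlap < 0 || timepoint_overlap > 1)
    stop("timepoint_overlap must be in [0, 1]")
  if (timepoint_overlap == 1) {
    truth$seed <- as.integer(seed)
    return(truth)
  }
  rs <- get_rng_state()
  on.exit(restore_rng_state(rs))
  set.seed(substream_seed(seed, "timepoint"))
  for (nm in names(truth$rois)) {
    roi <- truth$rois[[nm]]
    for (mem in names(roi$supports)) {
      old <- roi$supports[[mem]]
      w_old <- roi$weights[[mem]]
      m <- length(old)
      n_keep <- round(timepoint_overlap * m)
      keep_idx <- if (n_keep > 0L) sort(sample.int(m, n_keep)) else integer(0)
      pool <- if (!is.null(roi$pools))
        roi$pools[[truth$conditions[[mem]]]] else seq_len(roi$n_vox)
      candidates <- setdiff(pool, old)
      if (length(candidates) < m - n_keep)
        stop("timepoint_overlap infeasible in ROI '", nm,
             "': pool too small to re-draw ", m - n_keep, " voxels")
      new_vox <- if (m - n_keep > 0L) sample(candidates, m - n_keep)
                 else integer(0)
      supp <- c(old[keep_idx], new_vox)
      w <- c(w_old[keep_idx], stats::rnorm(length(new_vox)))
      ord <- order(supp)
      truth$rois[[nm]]$supports[[mem]] <- supp[ord]
      truth$rois[[nm]]$weights[[mem]] <- w[ord]
    }
  }
  truth$seed <- as.integer(seed)
  truth
}

#' Synthesize a BOLD volume series from planted patterns
#'
#' Forward model: per memory, a recall-period boxcar regressor (sampled as
#' the fraction of each TR bin covered by recall) is convolved with the
#' canonical double-gamma HRF; each ROI voxel's time course is the sum over
#' memories of regressor x planted weight x (ROI, condition) amplitude.
#' Linear drift (restarting each session) and i.i.d. Gaussian noise are
#' added everywhere. With `noise_sd = 0` and `drift_slope = 0` each voxel
#' equals its convolved planted signal exactly.
#'
#' @param geometry a `phantom_geometry`.
#' @param truth a `ground_truth` (supplies weights, amplitudes, noise, drift
#'   and the noise seed).
#' @param schedule a `trial_table` from [make_trial_schedule()].
#' @param design the `design_spec` used for the schedule.
#' @return a `volume_series` with session bounds matching the schedule.
#' @export
synthesize_bold <- function(geometry, truth, schedule, design) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(truth, "ground_truth"),
            inherits(schedule, "trial_table"))
  sess_vols <- attr(schedule, "session_volumes")
  tr <- attr(schedule, "tr_s")
  if (is.null(sess_vols) || is.null(tr))
    stop("schedule lacks session_volumes/tr_s attributes (validation error)")
  n_t <- sum(sess_vols)
  last_end <- max(schedule$onset + schedule$duration)
  if (last_end > n_t * tr)
    stop("schedule does not fit within the generated run length")

  grid <- geometry$grid_shape
  n_grid <- prod(grid)
  kernel <- canonical_hrf(seq(0, 32, by = tr))
  kernel <- kernel / sum(kernel)

  sess_starts <- cumsum(c(0L, sess_vols[-length(sess_vols)]))
  bounds <- cbind(start = sess_starts + 1L,
                  end = sess_starts + sess_vols)

  # per-memory convolved regressors, per session, then concatenated
  mems <- truth$memories
  reg <- matrix(0, n_t, length(mems))
  colnames(reg) <- mems
  for (s in seq_along(sess_vols)) {
    Tn <- sess_vols[s]
    t0 <- sess_starts[s] * tr
    in_sess <- schedule$session == s
    neural <- matrix(0, Tn, length(mems))
    for (i in which(in_sess)) {
      a <- schedule$onset[i] - t0
      b <- a + schedule$duration[i]
      v <- seq_len(Tn)
      lo <- (v - 1) * tr; hi <- v * tr
      frac <- pmax(0, pmin(hi, b) - pmax(lo, a)) / tr
      mi <- match(schedule$memory[i], mems)
      neural[, mi] <- neural[, mi] + frac
    }
    conv <- causal_convolve(neural, kernel)
    reg[(sess_starts[s] + 1L):(sess_starts[s] + Tn), ] <- conv
  }

  rs <- get_rng_state()
  on.exit(restore_rng_state(rs))
  set.seed(substream_seed(truth$seed, "bold"))

  data <- matrix(0, n_grid, n_t)
  for (nm in names(geometry$roi_masks)) {
    roi_idx <- which(geometry$roi_masks[[nm]])
    roi <- truth$rois[[nm]]
    W <- matrix(0, length(roi_idx), length(mems))
    for (mi in seq_along(mems)) {
      mem <- mems[mi]
      amp <- truth$amplitudes[nm, truth$conditions[[mem]]]
      if (amp > 0 && length(roi$supports[[mem]]) > 0L)
        W[roi$supports[[mem]], mi] <- roi$weights[[mem]] * amp
    }
    data[roi_idx, ] <- data[roi_idx, ] + W %*% t(reg)
  }
  if (truth$drift_slope != 0) {
    drift <- unlist(lapply(sess_vols, function(Tn)
      truth$drift_slope * (seq_len(Tn) - 1L)))
    data <- sweep(data, 2, drift, "+")
  }
  if (truth$noise_sd > 0)
    data <- data + stats::rnorm(length(data), sd = truth$noise_sd)

  volume_series(array(data, c(grid, n_t)),
                voxel_size_mm = geometry$voxel_size_mm, tr_s = tr,
                session_bounds = bounds)
}

# causal discrete convolution of each column of `x` with `kernel`,
# truncated to nrow(x); FFT-based
causal_convolve <- function(x, kernel) {
  n <- nrow(x)
  L <- stats::nextn(n + length(kernel) - 1L, 2)
  xp <- rbind(x, matrix(0, L - n, ncol(x)))
  kf <- stats::fft(c(kernel, rep(0, L - length(kernel))))
  out <- Re(stats::mvfft(stats::mvfft(xp) * kf, inverse = TRUE)) / L
  out[seq_len(n), , drop = FALSE]
}

#' Write / read ground truth as JSON
#'
#' Serialisation is lossless: `read_ground_truth(write_ground_truth(x, f))`
#' reproduces `x`.
#'
#' @param truth a `ground_truth`.
#' @param path output JSON path.
#' @return `path` invisibly; `read_ground_truth` returns a `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- unclass(truth)
  x$conditions <- as.list(truth$conditions)   # keep names in JSON
  x$amplitudes <- list(rois = rownames(truth$amplitudes),
                       conditions = colnames(truth$amplitudes),
                       values = unname(truth$amplitudes))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  amp <- matrix(x$amplitudes$values,
                nrow = length(x$amplitudes$rois),
                dimnames = list(x$amplitudes$rois, x$amplitudes$conditions))
  rois <- lapply(x$rois, function(r) {
    list(supports = lapply(r$supports, as.integer),
         weights = lapply(r$weights, as.numeric),
         n_vox = as.integer(r$n_vox),
         pools = if (is.null(r$pools)) NULL else lapply(r$pools, as.integer))
  })
  structure(list(rois = rois,
                 amplitudes = amp,
                 memories = as.character(x$memories),
                 conditions = stats::setNames(as.character(unlist(x$conditions)),
                                              names(x$conditions)),
                 support_frac = x$support_frac,
                 support_overlap = x$support_overlap,
                 noise_sd = x$noise_sd, drift_slope = x$drift_slope,
                 seed = as.integer(x$seed)),
            class = "ground_truth")
}

#' Write / read a trial events table
#'
#' Tab-separated events dialect with header
#' `onset duration memory condition session vividness consistency`.
#'
#' @param trials a `trial_table`.
#' @param path output TSV path.
#' @return `path` invisibly; `read_events` returns a `trial_table` (without
#'   session-volume attributes, which belong to the simulator).
#' @export
write_events <- function(trials, path) {
  cols <- c("onset", "duration", "memory", "condition", "session",
            "vividness", "consistency")
  utils::write.table(as.data.frame(trials)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}
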