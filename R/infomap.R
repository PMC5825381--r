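#' Build an information map from a decoding result
#'
#' The information map of a decoded condition marks the voxel sets that
#' produced above-chance classification: the union, over cross-validation
#' folds, of each fold's selected searchlight voxel set, counting only the
#' folds whose held-out accuracy exceeded chance. Folds that decoded at or
#' below chance contribute nothing; if no fold did better than chance the
#' map is empty and flagged. Returned as a binary mask over the ROI voxel
#' ordering, optionally expanded to the 3D grid.
#'
#' @param result a `decoding_result` with per-fold accuracies and feature
#'   sets.
#' @param chance accuracy a fold must exceed to contribute; defaults to the
#'   result's own chance level (1 / n classes).
#' @param grid_shape optional 3-vector; with `voxel_index` expands the map
#'   to a 3D logical array.
#' @param voxel_index linear grid indices of the ROI voxel ordering (e.g.
#'   `patterns$voxel_index`).
#' @return logical vector over ROI voxels (attribute `empty` flags an
#'   all-below-chance map), or a 3D logical array when `grid_shape` is given.
#' @export
build_information_map <- function(result, chance = NULL, grid_shape = NULL,
                                  voxel_index = NULL) {
  stopifnot(inherits(result, "decoding_result"))
  if (is.null(chance)) chance <- result$chance
  n_vox <- if (!is.null(voxel_index)) length(voxel_index) else
    if (!is.null(result$n_voxels)) result$n_voxels else
      max(1L, max(vapply(result$feature_sets,
                         function(f) if (length(f$voxels)) max(f$voxels) else 0L,
                         1L)))
  map <- logical(n_vox)
  any_above <- FALSE
  for (f in seq_along(result$feature_sets)) {
    if (result$fold_accuracy[f] <= chance) next
    any_above <- TRUE
    map[result$feature_sets[[f]]$voxels] <- TRUE
  }
  attr(map, "empty") <- !any_above
  if (!is.null(grid_shape)) {
    if (is.null(voxel_index))
      stop("voxel_index required to expand to a grid")
    out <- array(FALSE, grid_shape)
    if (any_above) out[voxel_index[which(map)]] <- TRUE
    attr(out, "empty") <- !any_above
    return(out)
  }
  map
}

#' Dice coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`: 0 for disjoint masks, 1 for identical
#' ones. Masks must live on the same grid (or voxel ordering); both empty is
#' undefined and raises an error.
#'
#' @param mask_a,mask_b logical arrays/vectors of equal length.
#' @return the Dice overlap in \[0, 1\].
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  if (length(a) != length(b))
    stop("masks must be on the same grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) stop("Dice undefined: both masks empty")
  2 * sum(a & b) / (na + nb)
}

#' Permutation test of information-map overlap
#'
#' Per subject, compares the observed Dice overlap of two information maps
#' with a null distribution obtained by re-drawing both maps as uniformly
#' random voxel subsets of the ROI with the observed cardinalities
#' (`n_perm` draws, default 1000). The group statistic is a one-sample
#' two-tailed t-test across subjects of (observed - subject's null mean)
#' against 0, with the direction (below/above the null) reported. A
#' per-subject permutation p (rank of the observed value among draws) is
#' also returned.
#'
#' @param maps_a,maps_b lists (one element per subject) of logical masks.
#' @param roi_masks list (per subject) of logical ROI masks on the same
#'   grid/ordering; maps must be subsets of their ROI.
#' @param n_perm permutations per subject (default 1000).
#' @param seed integer seed.
#' @return an object of class `dice_test`: per-subject `observed`,
#'   `null_mean`, `null_sd`, `perm_p`, and group `t`, `df`, `p`,
#'   `direction`.
#' @export
permutation_overlap_test <- function(maps_a, maps_b, roi_masks,
                                     n_perm = 1000L, seed = 1L) {
  n_sub <- length(maps_a)
  stopifnot(length(maps_b) == n_sub, length(roi_masks) == n_sub)
  rs <- get_rng_state()
  on.exit(restore_rng_state(rs))
  observed <- null_mean <- null_sd <- perm_p <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    roi <- as.logical(roi_masks[[s]])
    a <- as.logical(maps_a[[s]]); b <- as.logical(maps_b[[s]])
    if (any(a & !roi) || any(b & !roi))
      stop("subject ", s, ": map extends outside its ROI (validation error)")
    n_roi <- sum(roi)
    na <- sum(a); nb <- sum(b)
    observed[s] <- dice_coefficient(a, b)
    set.seed(substream_seed(seed, "dice", s))
    draws <- vapply(seq_len(n_perm), function(i) {
      ra <- sample.int(n_roi, na)
      rb <- sample.int(n_roi, nb)
      2 * sum(ra %in% rb) / (na + nb)
    }, numeric(1))
    null_mean[s] <- mean(draws)
    null_sd[s] <- stats::sd(draws)
    perm_p[s] <- (1 + sum(draws <= observed[s])) / (n_perm + 1)
  }
  delta <- observed - null_mean
  if (n_sub >= 2 && stats::sd(delta) > 0) {
    tt <- t_one_sample(delta, 0, one_tailed = FALSE)
  } else {
    tt <- list(t = NA_real_, df = n_sub - 1, p = NA_real_)
  }
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, perm_p = perm_p,
                 t = tt$t, df = tt$df, p = tt$p,
                 direction = if (mean(delta) < 0) "below" else "above",
                 n_perm = as.integer(n_perm)),
            class = "dice_test")
}

#' @export
print.dice_test <- function(x, ...) {
  cat(sprintf(
    "dice_test: %d subject(s), %d permutations\n  mean observed %.3f vs null %.3f (%s null)\n  group t(%d) = %.3f, two-tailed p = %.4f\n",
    length(x$observed), x$n_perm, mean(x$observed), mean(x$null_mean),
    x$direction, x$df, x$t, x$p))
  invisible(x)
}
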