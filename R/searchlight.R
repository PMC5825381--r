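#' Split a mask along the hippocampal long axis
#'
#' Partitions the slices (along `axis`) that contain mask voxels into an
#' anterior block covering the first `round(anterior_fraction * n_occupied)`
#' occupied slices and a posterior block covering the rest. Rounding is
#' half-up. With the study's convention the anterior 35% of the hippocampus
#' is labelled anterior.
#'
#' @param mask 3D logical array.
#' @param anterior_fraction fraction in (0, 1) of occupied slices labelled
#'   anterior (default 0.35).
#' @param axis grid axis (1-3) of the long axis.
#' @return list with 3D logical `anterior` and `posterior` masks; their
#'   union is the input and their intersection empty.
#' @export
split_long_axis <- function(mask, anterior_fraction = 0.35, axis = 1L) {
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty")
  if (anterior_fraction <= 0 || anterior_fraction >= 1)
    stop("anterior_fraction must be in (0, 1)")
  slice_counts <- apply(mask, axis, sum)
  occupied <- which(slice_counts > 0)
  if (length(occupied) < 2L)
    stop("mask spans a single slice; cannot split (validation error)")
  n_ant <- as.integer(floor(anterior_fraction * length(occupied) + 0.5))
  n_ant <- max(1L, min(length(occupied) - 1L, n_ant))
  ant_slices <- occupied[seq_len(n_ant)]
  anterior <- mask
  idx <- slice.index(mask, axis)
  anterior[!(idx %in% ant_slices)] <- FALSE
  posterior <- mask & !anterior
  list(anterior = anterior, posterior = posterior)
}

#' Enumerate ROI-restricted searchlight spheres
#'
#' For every ROI voxel, the set of ROI voxels within Euclidean distance
#' `radius_voxels` (in voxel units; radius 3 voxels = 4.5 mm at 1.5 mm
#' isotropic). Spheres never leave the ROI, so their shape and size shrink
#' near the ROI border; a full interior sphere of radius 3 has 123 voxels.
#'
#' @param mask 3D logical ROI mask.
#' @param radius_voxels sphere radius in voxels (>= 0, default 3).
#' @return an object of class `sphere_set`: list with `members` (per centre,
#'   integer indices into the ROI voxel ordering), `voxel_index` (linear
#'   grid indices of ROI voxels, the ordering used), `radius`.
#' @export
enumerate_spheres <- function(mask, radius_voxels = 3) {
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty (validation error)")
  if (radius_voxels < 0) stop("radius must be >= 0")
  d <- dim(mask)
  roi_idx <- which(mask)
  n <- length(roi_idx)
  rank <- array(0L, d)
  rank[roi_idx] <- seq_len(n)
  coords <- arrayInd(roi_idx, d)

  r <- floor(radius_voxels)
  offs <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  offs <- offs[rowSums(offs^2) <= radius_voxels^2, , drop = FALSE]

  members <- vector("list", n)
  for (i in seq_len(n)) members[[i]] <- integer(0)
  acc <- matrix(0L, n, nrow(offs))
  for (j in seq_len(nrow(offs))) {
    shifted <- coords + matrix(offs[j, ], n, 3, byrow = TRUE)
    ok <- shifted[, 1] >= 1L & shifted[, 1] <= d[1] &
      shifted[, 2] >= 1L & shifted[, 2] <= d[2] &
      shifted[, 3] >= 1L & shifted[, 3] <= d[3]
    rk <- integer(n)
    lin <- shifted[ok, 1] + (shifted[ok, 2] - 1L) * d[1] +
      (shifted[ok, 3] - 1L) * d[1] * d[2]
    rk[ok] <- rank[lin]
    acc[, j] <- rk
  }
  members <- lapply(seq_len(n), function(i) {
    v <- acc[i, ]
    sort(v[v > 0L])
  })
  structure(list(members = members, voxel_index = roi_idx,
                 radius = radius_voxels),
            class = "sphere_set")
}

#' @export
print.sphere_set <- function(x, ...) {
  sizes <- lengths(x$members)
  cat(sprintf("sphere_set: %d centres, radius %g voxels, sphere size %d-%d (median %g)\n",
              length(x$members), x$radius, min(sizes), max(sizes),
              stats::median(sizes)))
  invisible(x)
}
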