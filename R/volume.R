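#' 4D BOLD volume series
#'
#' Container for a 4D scalar field on a regular voxel grid with acquisition
#' metadata. The spatial grid is the first three array dimensions, time
#' (volumes) the fourth. Session boundaries, when present, partition the time
#' axis into independently acquired runs (drift and HRF convolution are
#' handled per session downstream).
#'
#' @param data numeric 4D array (x, y, z, t).
#' @param voxel_size_mm isotropic voxel edge length in mm (default 1.5).
#' @param tr_s repetition time in seconds, the sampling interval of the
#'   time axis (default 3.5).
#' @param session_bounds optional integer matrix with columns `start`, `end`
#'   (1-based, inclusive volume indices) partitioning the time axis; a single
#'   session covering everything if omitted.
#' @return an object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size_mm = 1.5, tr_s = 3.5,
                          session_bounds = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be positive")
  if (!is.numeric(tr_s) || tr_s <= 0)
    stop("`tr_s` must be positive")
  n_t <- dim(data)[4L]
  if (is.null(session_bounds)) {
    session_bounds <- cbind(start = 1L, end = n_t)
  }
  session_bounds <- as.matrix(session_bounds)
  storage.mode(session_bounds) <- "integer"
  colnames(session_bounds) <- c("start", "end")
  if (session_bounds[1L, "start"] != 1L ||
      session_bounds[nrow(session_bounds), "end"] != n_t ||
      any(session_bounds[, "end"] < session_bounds[, "start"]) ||
      (nrow(session_bounds) > 1L &&
       any(session_bounds[-1L, "start"] !=
           session_bounds[-nrow(session_bounds), "end"] + 1L)))
    stop("`session_bounds` must partition 1..", n_t, " contiguously")
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
         session_bounds = session_bounds),
    class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "volume_series: %d x %d x %d grid, %d volumes, %.2f mm voxels, TR %.2f s, %d session(s)\n",
    d[1], d[2], d[3], d[4], x$voxel_size_mm, x$tr_s, nrow(x$session_bounds)))
  invisible(x)
}

#' @export
dim.volume_series <- function(x) dim(x$data)

n_volumes <- function(vol) dim(vol$data)[4L]

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one integer master seed. Distinct
#' stages and repetitions derive their own seeds through this function, so a
#' report regenerates bit-identically from the master seed alone. The
#' derivation is a polynomial hash of the stream tags modulo 2^31 - 1,
#' keeping every derived seed a valid 32-bit R integer.
#'
#' @param master integer master seed.
#' @param ... integer or character tags identifying the substream
#'   (e.g. `"subject"`, 3, `"noise"`).
#' @return a positive integer seed.
#' @export
substream_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (tag in list(...)) {
    codes <- if (is.character(tag)) utf8ToInt(tag) else as.numeric(tag)
    for (cc in codes) h <- (h * 69069 + cc + 1) %% m
  }
  as.integer(h %% (m - 1L) + 1)
}
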