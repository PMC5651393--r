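#' 4D volumetric time series
#'
#' Container for a single subject's 4D intensity data: a numeric array with
#' dimensions `(x, y, z, t)`, the voxel size in millimetres, and the
#' repetition time (TR) in seconds. All voxel-level preprocessing steps
#' transform objects of this class.
#'
#' @param data numeric 4D array `(x, y, z, t)` of finite intensities.
#' @param voxel_mm numeric length-3 voxel size in mm.
#' @param tr_s repetition time in seconds.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_mm = c(3, 3, 3), tr_s = 2) {
  abort_if(length(dim(data)) != 4L, "volume_series data must be a 4D array (x, y, z, t)")
  abort_if(!all(is.finite(data)), "volume_series intensities must all be finite")
  abort_if(dim(data)[4] < 1L, "volume_series needs at least one frame")
  abort_if(length(voxel_mm) != 3L || any(voxel_mm <= 0), "voxel_mm must be 3 positive sizes")
  abort_if(tr_s <= 0, "tr_s must be positive")
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm), tr_s = as.numeric(tr_s)),
            class = "volume_series")
}

#' Number of frames in a volume series
#' @param series a `volume_series`.
#' @return Integer frame count.
#' @export
n_frames <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  dim(series$data)[4]
}

# frames x voxels matrix view (voxels in column-major grid order)
vol_as_matrix <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, nrow = prod(d[1:3]), ncol = d[4]))
}

# rebuild a volume_series from a frames x voxels matrix and a template
vol_from_matrix <- function(mat, template) {
  d <- dim(template$data)
  d[4] <- nrow(mat)
  volume_series(array(t(mat), dim = d), voxel_mm = template$voxel_mm, tr_s = template$tr_s)
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_series: %d x %d x %d voxels, %d frames, voxel %s mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4], paste(signif(x$voxel_mm, 3), collapse = "x"), x$tr_s))
  invisible(x)
}
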