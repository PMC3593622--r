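#' Construct a volume series (time-by-voxel BOLD matrix with geometry)
#'
#' The substrate of all decompositions: a `t x v` matrix of BOLD intensities
#' whose rows are acquired volumes and whose columns are in-mask voxels, plus
#' the 3D mask and voxel geometry needed to reshape spatial maps back into
#' image space. Voxel columns follow the mask's native linear-index order
#' (`which(mask)`), recorded in `voxel_index` so that any map vector can be
#' written back to the grid bit-reproducibly.
#'
#' @param data numeric matrix, time points by in-mask voxels. All entries
#'   must be finite.
#' @param mask logical 3D array marking included voxels. `sum(mask)` must
#'   equal `ncol(data)`.
#' @param voxel_size numeric length-3, mm per axis.
#' @param tr repetition time in seconds (> 0).
#' @param subject_id label carried through results.
#' @param reference optional `RNifti` image whose header (affine etc.) is
#'   reused when writing derived images.
#' @return an object of class `volume_series`.
#' @export
volume_series <- function(data, mask, voxel_size = c(3, 3, 5), tr = 1,
                          subject_id = "subject", reference = NULL) {
  data <- as.matrix(data)
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a 3D array")
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (ncol(data) != sum(mask)) {
    abort(sprintf("data has %d columns but mask has %d TRUE voxels",
                  ncol(data), sum(mask)))
  }
  if (!all(is.finite(data))) abort("`data` contains non-finite values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) abort("`tr` must be > 0")
  structure(
    list(
      data = data,
      mask = mask,
      grid_dims = dim(mask),
      voxel_size = as.numeric(voxel_size),
      tr = as.numeric(tr),
      subject_id = subject_id,
      voxel_index = which(mask),
      reference = reference
    ),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf(
    "<volume_series> %s: %d volumes x %d voxels, grid %s, TR %.3g s\n",
    x$subject_id, nrow(x$data), ncol(x$data),
    paste(x$grid_dims, collapse = "x"), x$tr
  ))
  invisible(x)
}

#' @export
dim.volume_series <- function(x) dim(x$data)

n_volumes <- function(series) nrow(series$data)
n_voxels <- function(series) ncol(series$data)

#' Reshape the time-by-voxel matrix into a 4D array
#'
#' Inverse of the masking/flattening applied on read: out-of-mask voxels are
#' zero. `series_from_array()` composed with this is the identity on in-mask
#' voxels.
#'
#' @param series a [volume_series()].
#' @return a 4D numeric array `grid_dims x time`.
#' @export
series_to_array <- function(series) {
  d <- series$grid_dims
  t <- n_volumes(series)
  arr <- array(0, dim = c(prod(d), t))
  arr[series$voxel_index, ] <- t(series$data)
  array(arr, dim = c(d, t))
}

#' Place a spatial map vector into the 3D grid
#'
#' @param map numeric vector over in-mask voxels (length `v`).
#' @param series the [volume_series()] defining mask and geometry.
#' @return 3D numeric array with `map` at in-mask voxels, zero elsewhere.
#' @export
map_to_array <- function(map, series) {
  if (length(map) != n_voxels(series)) {
    abort(sprintf("map has length %d, expected %d in-mask voxels",
                  length(map), n_voxels(series)))
  }
  arr <- array(0, dim = series$grid_dims)
  arr[series$voxel_index] <- map
  arr
}

#' Extract a causal sliding window from a series
#'
#' Returns the `length` most recent volumes ending at time index `end`
#' (0-based, inclusive at both ends), in acquisition order — the
#' `Delta x v` window matrix on which the recursive monitoring engines
#' run their decompositions.
#'
#' @param series a [volume_series()] or a plain time-by-voxel matrix.
#' @param end 0-based index of the last volume in the window.
#' @param length window length in TRs (>= 2).
#' @return numeric matrix `length x v`.
#' @export
extract_window <- function(series, end, length) {
  data <- if (inherits(series, "volume_series")) series$data else as.matrix(series)
  if (length < 2L) abort("window `length` must be at least 2")
  if (end < length - 1L) {
    abort(sprintf("window of length %d ending at index %d extends before the first volume",
                  length, end))
  }
  if (end > nrow(data) - 1L) abort("`end` is past the last acquired volume")
  data[(end - length + 2L):(end + 1L), , drop = FALSE]
}

#' Take a single volume from a series
#'
#' @param series a [volume_series()].
#' @param index 0-based time index.
#' @return list with `values` (in-mask intensities) and `index`.
#' @export
get_volume <- function(series, index) {
  if (index < 0L || index > n_volumes(series) - 1L) abort("`index` out of range")
  list(values = series$data[index + 1L, ], index = as.integer(index))
}
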