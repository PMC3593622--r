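#' Read a 4D BOLD series from NIfTI
#'
#' Loads a 4D NIfTI image, optionally together with a 3D binary mask, and
#' flattens it into the time-by-voxel matrix all decompositions operate on.
#' When no mask is supplied an automatic intensity mask is computed: voxels
#' whose temporal mean exceeds `mask_threshold` times the global mean of the
#' temporal means are retained.
#'
#' @param path path to a readable 4D NIfTI file.
#' @param mask_path optional path to a 3D NIfTI mask on the same grid;
#'   non-zero voxels are included.
#' @param mask_threshold fraction of the global mean used by the automatic
#'   mask (default 0.2).
#' @param subject_id label; defaults to the file name.
#' @return a [volume_series()].
#' @export
read_series <- function(path, mask_path = NULL, mask_threshold = 0.2,
                        subject_id = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) abort("`path` must be a 4D NIfTI image")
  d <- dim(arr)
  if (d[4] < 2L) abort("series must contain at least 2 time points")
  flat <- array(arr, dim = c(prod(d[1:3]), d[4]))

  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) abort(sprintf("no such file: %s", mask_path))
    mask_arr <- as.array(RNifti::readNifti(mask_path))
    if (length(dim(mask_arr)) == 4L && dim(mask_arr)[4] == 1L) {
      mask_arr <- array(mask_arr, dim = dim(mask_arr)[1:3])
    }
    if (!identical(dim(mask_arr)[1:3], d[1:3])) {
      abort("mask grid does not match image grid")
    }
    mask <- array(mask_arr != 0, dim = d[1:3])
  } else {
    tmean <- rowMeans(flat)
    mask <- array(tmean > mask_threshold * mean(tmean), dim = d[1:3])
  }
  if (sum(mask) < 1L) abort("mask selects no voxels")

  pd <- RNifti::pixdim(img)
  volume_series(
    data = t(flat[which(mask), , drop = FALSE]),
    mask = mask,
    voxel_size = pd[1:3],
    tr = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1,
    subject_id = subject_id %||% basename(path),
    reference = img
  )
}

#' Write a volume series to a 4D NIfTI file
#'
#' Out-of-mask voxels are written as zero; in-mask data round-trips
#' bit-exactly through [read_series()] when the written mask is supplied.
#'
#' @param series a [volume_series()].
#' @param path output path for the 4D image (`.nii` / `.nii.gz`).
#' @param mask_path optional output path for the binary mask.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, mask_path = NULL) {
  arr <- series_to_array(series)
  img <- RNifti::asNifti(arr, reference = series$reference)
  RNifti::pixdim(img) <- c(series$voxel_size, series$tr)
  RNifti::writeNifti(img, path, datatype = "double")
  if (!is.null(mask_path)) {
    m <- RNifti::asNifti(array(as.numeric(series$mask), dim = series$grid_dims),
                         reference = series$reference)
    RNifti::pixdim(m) <- series$voxel_size
    RNifti::writeNifti(m, mask_path, datatype = "uint8")
  }
  invisible(path)
}

#' Write a spatial map to a 3D NIfTI file
#'
#' @param map numeric vector over in-mask voxels.
#' @param series the [volume_series()] defining geometry.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, series, path) {
  arr <- map_to_array(map, series)
  img <- RNifti::asNifti(arr, reference = series$reference)
  RNifti::pixdim(img) <- series$voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a spatial map written by [write_map()] back as an in-mask vector
#'
#' @param path path to a 3D NIfTI map.
#' @param series the [volume_series()] whose mask defines voxel order.
#' @return numeric vector of length `v`.
#' @export
read_map <- function(path, series) {
  arr <- as.array(RNifti::readNifti(path))
  if (!identical(dim(arr)[1:3], series$grid_dims)) {
    abort("map grid does not match series grid")
  }
  arr[series$voxel_index]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
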