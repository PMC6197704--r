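#' Convert a smoothing FWHM to a Gaussian sigma in voxels
#'
#' `sigma = (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))` per axis.
#'
#' @param fwhm_mm Full-width-half-maximum in mm (scalar, >= 0).
#' @param voxel_size_mm Per-axis voxel size in mm.
#' @return Numeric vector of per-axis sigmas in voxel units.
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  stop_if_not(fwhm_mm >= 0, "fwhm_to_sigma: fwhm_mm must be >= 0")
  (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
}

# 1D convolution matrix: kernel truncated at 4 sigma, renormalized to unit
# sum, nearest-edge replication at the boundaries.
conv_matrix_1d <- function(d, sigma) {
  if (sigma <= 0) return(diag(d))
  R <- max(1L, ceiling(4 * sigma))
  off <- (-R):R
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- pmin(pmax(i + off, 1L), d)   # replicate edges
    for (t in seq_along(off)) M[i, j[t]] <- M[i, j[t]] + k[t]
  }
  M
}

# Separable Gaussian smoothing of one 3D array.
gaussian_smooth_array <- function(arr, fwhm_mm, voxel_size_mm) {
  dims <- dim(arr)
  stop_if_not(length(dims) == 3L, "gaussian_smooth_array: expected a 3D array")
  sig <- fwhm_to_sigma(fwhm_mm, rep(voxel_size_mm, length.out = 3))
  out <- arr
  for (axis in 1:3) {
    if (sig[axis] <= 0) next
    M <- conv_matrix_1d(dims[axis], sig[axis])
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(out, perm)
    da <- dim(a)
    a <- M %*% matrix(a, da[1], da[2] * da[3])
    dim(a) <- da
    out <- aperm(a, order(perm))
  }
  out
}

#' Smooth a voxel image set with a Gaussian kernel
#'
#' Separable Gaussian convolution with per-axis sigma (in voxels) equal
#' to `(fwhm_mm / voxel_size_mm) / (2 sqrt(2 ln 2))`; kernel truncated at
#' 4 sigma and renormalized to unit sum; boundaries handled by
#' nearest-edge replication. `fwhm_mm = 0` is the identity.
#'
#' @param images A `voxel_image_set`.
#' @param fwhm_mm Full-width-half-maximum in mm (>= 0).
#' @return A `voxel_image_set` with smoothed data.
#' @export
gaussian_smooth <- function(images, fwhm_mm) {
  stop_if_not(fwhm_mm >= 0, "gaussian_smooth: fwhm_mm must be >= 0")
  n <- dim(images$data)[4]
  out <- images
  for (j in seq_len(n)) {
    out$data[, , , j] <- gaussian_smooth_array(images$data[, , , j],
                                               fwhm_mm, images$voxel_size_mm)
  }
  out
}

#' Vectorize masked voxels into a subject x voxel feature matrix
#'
#' Extracts in-mask voxels in a fixed x-fastest raster order (the first
#' grid axis varies quickest), one row per subject. The mapping from
#' feature columns back to grid coordinates is retained so weight
#' vectors can be re-projected onto the grid.
#'
#' @param images A `voxel_image_set`.
#' @param mask Logical 3D array; defaults to the image set's own mask.
#' @return A `feature_matrix`: `values` (subject x voxel matrix),
#'   `voxel_index` (voxel x 3 integer grid coordinates, 1-based),
#'   `grid_dims`, `voxel_size_mm`, `mask`.
#' @export
vectorize <- function(images, mask = images$mask) {
  stop_if_not(identical(dim(mask), dim(images$data)[1:3]),
              "vectorize: mask dimensions do not match the image grid")
  lin <- which(mask)                    # column-major = x-fastest raster
  idx <- which(mask, arr.ind = TRUE)
  n <- dim(images$data)[4]
  vals <- matrix(0, n, length(lin))
  nv <- prod(dim(mask))
  for (j in seq_len(n)) {
    v <- images$data[, , , j]
    vals[j, ] <- v[lin]
  }
  rownames(vals) <- images$subjects
  structure(list(values = vals, voxel_index = idx, linear_index = lin,
                 grid_dims = dim(mask), voxel_size_mm = images$voxel_size_mm,
                 mask = mask),
            class = "feature_matrix")
}

#' Project a voxel-space vector back onto the 3D grid
#'
#' Inverse of [vectorize()] for a single vector (for example a weight
#' map or one subject's row): values land at their original grid
#' coordinates, zero elsewhere.
#'
#' @param v Numeric vector with one entry per in-mask voxel.
#' @param features A `feature_matrix` (for the voxel index).
#' @return A 3D array on the original grid.
#' @export
devectorize <- function(v, features) {
  stop_if_not(length(v) == nrow(features$voxel_index),
              "devectorize: vector length does not match the mask (%d vs %d)",
              length(v), nrow(features$voxel_index))
  out <- array(0, features$grid_dims)
  out[features$linear_index] <- v
  out
}

#' Total tissue volume per subject
#'
#' Intracranial volume as the sum of voxel values times the voxel volume
#' in mm^3, applied to total-tissue (or any nonnegative) maps.
#'
#' @param images A `voxel_image_set` with nonnegative data.
#' @return Numeric vector, one volume (mm^3) per subject.
#' @export
compute_icv <- function(images) {
  stop_if_not(all(images$data >= 0),
              "compute_icv: negative voxel values are not a tissue map")
  vox_mm3 <- prod(images$voxel_size_mm)
  n <- dim(images$data)[4]
  vapply(seq_len(n), function(j) sum(images$data[, , , j]) * vox_mm3, 0)
}

#' Write a voxel image set (plus mask) as NIfTI-1 files
#'
#' One 3D volume per subject plus `mask.nii`; voxel geometry is recorded
#' in the NIfTI header via a diagonal affine.
#'
#' @param images A `voxel_image_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_image_set <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(images$data)[4]
  paths <- character(n)
  for (j in seq_len(n)) {
    paths[j] <- file.path(dir, sprintf("%s.nii", images$subjects[j]))
    write_nifti_volume(images$data[, , , j], paths[j], images$voxel_size_mm)
  }
  mp <- file.path(dir, "mask.nii")
  write_nifti_volume(images$mask * 1, mp, images$voxel_size_mm)
  invisible(c(paths, mp))
}

write_nifti_volume <- function(arr, path, voxel_size_mm) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_size_mm, length.out = 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a directory of per-subject NIfTI volumes into a voxel image set
#'
#' @param files Character vector of NIfTI paths, one per subject.
#' @param mask_file Path to the mask NIfTI (nonzero = in mask).
#' @param subjects Subject labels; default from file names.
#' @param modulated Metadata flag carried on the set.
#' @return A `voxel_image_set`.
#' @export
read_image_set <- function(files, mask_file, subjects = NULL,
                           modulated = FALSE) {
  mask_img <- RNifti::readNifti(mask_file)
  mask <- array(as.vector(mask_img) != 0, dim(mask_img))
  vox <- RNifti::pixdim(mask_img)[1:3]
  dims <- dim(mask)
  data <- array(0, c(dims, length(files)))
  for (j in seq_along(files)) {
    v <- RNifti::readNifti(files[j])
    stop_if_not(identical(dim(v)[1:3], dims),
                "read_image_set: %s does not match the mask grid", files[j])
    data[, , , j] <- as.vector(v)
  }
  if (is.null(subjects)) subjects <- sub("\\.nii(\\.gz)?$", "", basename(files))
  structure(list(data = data, grid_dims = dims, voxel_size_mm = vox,
                 mask = mask, modulated = modulated, subjects = subjects),
            class = "voxel_image_set")
}
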