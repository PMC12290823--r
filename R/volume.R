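#' Volumetric image with a world-space affine
#'
#' A `volume` is the package's carrier for 3D scalar grids (masks, statistic
#' maps, label maps) and 4D BOLD series: a numeric array plus a 4x4
#' voxel-to-world affine in RAS+ millimetres.  World coordinates follow the
#' NIfTI convention `world = affine %*% c(i-1, j-1, k-1, 1)` for 1-based
#' voxel index `(i, j, k)`.
#'
#' @param data numeric array, 3D or 4D (fourth dimension = time).
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world
#'   millimetres (RAS+).
#' @return An object of class `volume`.
#' @export
volume <- function(data, affine) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("'data' must be a 3D or 4D array")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix")
  structure(list(data = data, affine = affine), class = "volume")
}

is_volume <- function(x) inherits(x, "volume")

#' @export
dim.volume <- function(x) dim(x$data)

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %s voxels, voxel size %s mm\n",
              paste(d, collapse = " x "),
              paste(signif(voxel_sizes(x), 4), collapse = " x ")))
  invisible(x)
}

#' Voxel edge lengths in millimetres
#'
#' @param vol a `volume` (or a 4x4 affine matrix).
#' @return Numeric length-3 vector of per-axis voxel sizes.
#' @export
voxel_sizes <- function(vol) {
  aff <- if (is_volume(vol)) vol$affine else vol
  sqrt(colSums(aff[1:3, 1:3]^2))
}

grid_dim3 <- function(vol) dim(vol$data)[1:3]

#' Construct a regular RAS+ grid volume
#'
#' Convenience constructor for an axis-aligned grid: voxel `(1,1,1)` has its
#' center at `origin` and axes increase along world x/y/z by `voxel_size`.
#'
#' @param dim3 integer length-3 grid shape.
#' @param voxel_size numeric length-3 voxel edge lengths in mm.
#' @param origin world-mm coordinate of the first voxel center.
#' @param data optional array to wrap (defaults to zeros).
#' @return A `volume`.
#' @export
make_grid <- function(dim3, voxel_size, origin = -(dim3 - 1) * voxel_size / 2,
                      data = NULL) {
  dim3 <- as.integer(dim3)
  if (any(dim3 < 1L)) stop("grid dimensions must be positive")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  aff <- diag(c(voxel_size, 1))
  aff[1:3, 4] <- origin
  if (is.null(data)) data <- array(0, dim = dim3)
  volume(data, aff)
}

#' Convert voxel indices to world coordinates
#'
#' @param vol a `volume`.
#' @param idx n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of world-mm coordinates of the voxel centers.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  h <- cbind(idx - 1, 1)
  out <- h %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

#' Convert world coordinates to (fractional) voxel indices
#'
#' @param vol a `volume`.
#' @param xyz n x 3 matrix of world-mm coordinates.
#' @return n x 3 matrix of 1-based fractional voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(vol$affine))
  out[, 1:3, drop = FALSE] + 1
}

#' World coordinates of all voxels where a predicate holds
#'
#' @param vol a 3D `volume`.
#' @param which_fun selects voxels from the data array; default keeps
#'   positive voxels.
#' @return n x 3 matrix of world-mm voxel-center coordinates.
#' @export
positive_voxel_coords <- function(vol, which_fun = function(v) v > 0) {
  idx <- which(which_fun(vol$data), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3L))
  voxel_to_world(vol, idx)
}

affines_match <- function(a, b, tol = 1e-4) {
  max(abs(a$affine - b$affine)) <= tol &&
    identical(grid_dim3(a), grid_dim3(b))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!affines_match(a, b))
    stop(sprintf("%s are not on the same grid (affine/shape mismatch)", what))
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Loads a NIfTI-1/2 file, reorients it to canonical RAS+ and returns a
#' [volume()].  NaNs are replaced by zero with a warning (they would poison
#' masks and distance searches).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param expect_3d error if the image is not 3D.
#' @return A `volume`.
#' @export
load_volume <- function(path, expect_3d = FALSE) {
  img <- RNifti::readNifti(path)
  if (!(length(dim(img)) %in% c(3L, 4L)))
    stop(sprintf("'%s' is not a 3D or 4D image", path))
  if (expect_3d && length(dim(img)) != 3L)
    stop(sprintf("'%s': expected a 3D image, got %dD", path, length(dim(img))))
  if (RNifti::orientation(img) != "RAS")
    RNifti::orientation(img) <- "RAS"
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(img))   # plain numeric array
  if (anyNA(dat)) {
    warning(sprintf("'%s' contains NaN/NA voxels; treated as 0", path))
    dat[is.na(dat)] <- 0
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume(dat, aff)
}

#' Write a volume as NIfTI
#'
#' @param vol a `volume`.
#' @param path output path; `.nii.gz` is honoured.
#' @return Invisibly, `path`.
#' @export
save_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  vs <- voxel_sizes(vol)
  RNifti::pixdim(img) <- vs
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a binary map onto another grid by nearest neighbour
#'
#' Each target voxel center is mapped through the affines into the source
#' grid and takes the value of the nearest source voxel (0 outside the
#' source extent).  Intended for binarized maps moving to the common 1 mm
#' analysis grid; nearest-neighbour keeps them binary.
#'
#' @param vol source `volume` (3D).
#' @param target a `volume` defining the output grid.
#' @return A `volume` on the target grid.
#' @export
resample_to_grid <- function(vol, target) {
  d <- grid_dim3(target)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  xyz <- voxel_to_world(target, idx)
  src <- round(world_to_voxel(vol, xyz))
  sd3 <- grid_dim3(vol)
  ok <- src[, 1] >= 1 & src[, 1] <= sd3[1] &
        src[, 2] >= 1 & src[, 2] <= sd3[2] &
        src[, 3] >= 1 & src[, 3] <= sd3[3]
  out <- numeric(nrow(idx))
  if (any(ok)) {
    lin <- (src[ok, 3] - 1) * sd3[1] * sd3[2] + (src[ok, 2] - 1) * sd3[1] +
      src[ok, 1]
    out[ok] <- vol$data[lin]
  }
  volume(array(out, dim = d), target$affine)
}
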