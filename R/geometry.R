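#' Round a nonnegative distance to integer millimetres
#'
#' Nearest integer with halves rounded away from zero (so 6.5 mm -> 7 mm),
#' matching the convention that sub-voxel (< 1 mm) increments are not
#' meaningful on the 1 mm anatomical grid.
#'
#' @param x nonnegative numeric vector.
#' @return Integer vector.
#' @examples
#' round_mm(c(3.7, 6.5, 10.1))   # 4, 7, 10
#' @export
round_mm <- function(x) {
  if (any(x < 0)) stop("distances must be nonnegative")
  as.integer(floor(x + 0.5))
}

#' Voxelized sphere around a DES coordinate
#'
#' Voxels whose world-space centers lie within `radius_mm` of the
#' coordinate are set to 1.  At least one voxel is always included: if no
#' center falls inside the radius, the nearest voxel is used and the result
#' is flagged (`attr(., "nearest_only")`).
#'
#' @param coord_mm world RAS+ coordinate (length 3).
#' @param radius_mm sphere radius in mm (default 5).
#' @param grid a `volume` defining the grid.
#' @return Binary `volume`.
#' @export
sphere_roi <- function(coord_mm, radius_mm = 5, grid) {
  if (radius_mm <= 0) stop("radius must be positive")
  d <- grid_dim3(grid)
  fv <- world_to_voxel(grid, matrix(coord_mm, 1))
  if (any(fv < 0.5) || any(fv > d + 0.5))
    stop(sprintf("DES point (%.1f, %.1f, %.1f) mm lies outside the grid",
                 coord_mm[1], coord_mm[2], coord_mm[3]))
  vs <- voxel_sizes(grid)
  rad_vox <- ceiling(radius_mm / vs) + 1
  ctr <- round(fv)
  rng <- lapply(1:3, function(a)
    max(1, ctr[a] - rad_vox[a]):min(d[a], ctr[a] + rad_vox[a]))
  idx <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  xyz <- voxel_to_world(grid, idx)
  dd <- sqrt(rowSums((xyz - matrix(coord_mm, nrow(xyz), 3, byrow = TRUE))^2))
  inside <- dd <= radius_mm + 1e-9
  nearest_only <- FALSE
  if (!any(inside)) {
    inside <- seq_along(dd) == which.min(dd)
    nearest_only <- TRUE
  }
  out <- array(0, dim = d)
  out[idx[inside, , drop = FALSE]] <- 1
  res <- volume(out, grid$affine)
  attr(res, "nearest_only") <- nearest_only
  res
}

#' Center of gravity of a binary region
#'
#' Unweighted mean of the member voxel centers in world millimetres.
#'
#' @param roi binary `volume`.
#' @return Length-3 world-mm coordinate.
#' @export
center_of_gravity <- function(roi) {
  xyz <- positive_voxel_coords(roi)
  if (nrow(xyz) == 0L) stop("empty region of interest")
  colMeans(xyz)
}

fft_pad_dims <- function(d, kd) {
  vapply(seq_along(d), function(a) stats::nextn(d[a] + kd[a] - 1L, c(2, 3, 5)),
         integer(1))
}

#' Morphological dilation by a world-millimetre radius
#'
#' Dilates a binary volume with a spherical structuring element of the
#' given radius (in world mm, honouring anisotropic voxels), implemented by
#' FFT convolution with the voxelized ball.
#'
#' @param vol binary `volume`.
#' @param radius_mm structuring-element radius.
#' @return Binary `volume`.
#' @export
dilate_mm <- function(vol, radius_mm) {
  if (radius_mm <= 0) stop("dilation radius must be positive")
  vs <- voxel_sizes(vol)
  half <- as.integer(ceiling(radius_mm / vs))
  off <- expand.grid(i = -half[1]:half[1], j = -half[2]:half[2],
                     k = -half[3]:half[3])
  ok <- (off$i * vs[1])^2 + (off$j * vs[2])^2 + (off$k * vs[3])^2 <=
    radius_mm^2 + 1e-9
  kd <- 2L * half + 1L
  kern <- array(0, dim = kd)
  kern[cbind(off$i[ok] + half[1] + 1L, off$j[ok] + half[2] + 1L,
             off$k[ok] + half[3] + 1L)] <- 1
  d <- grid_dim3(vol)
  pd <- fft_pad_dims(d, kd)
  A <- array(0, dim = pd); A[1:d[1], 1:d[2], 1:d[3]] <- (vol$data > 0) * 1
  B <- array(0, dim = pd); B[1:kd[1], 1:kd[2], 1:kd[3]] <- kern
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    prod(pd)
  out <- conv[half[1] + (1:d[1]), half[2] + (1:d[2]), half[3] + (1:d[3])]
  volume(array(as.numeric(out > 0.5), dim = d), vol$affine)
}

#' Surgical-field mask from DES spheres
#'
#' Union of the DES spheres, binarized, dilated with a spherical
#' structuring element of `dilation_mm` (world mm), and intersected with
#' the brain mask.  Used only to restrict (accelerate) the minimum-distance
#' search; the full-map fallback in [min_distance()] keeps results
#' identical when the mask is empty of suprathreshold voxels.
#'
#' @param spheres list of binary `volume`s on one grid.
#' @param brain_mask binary `volume` on the same grid.
#' @param dilation_mm dilation radius in mm (default 15).
#' @return Binary `volume`.
#' @export
surgical_field_mask <- function(spheres, brain_mask, dilation_mm = 15) {
  if (length(spheres) == 0L) stop("no DES spheres supplied")
  u <- spheres[[1]]$data > 0
  for (s in spheres[-1]) {
    stop_if_grid_mismatch(spheres[[1]], s, "DES spheres")
    u <- u | (s$data > 0)
  }
  uni <- volume(array(as.numeric(u), dim = dim(u)), spheres[[1]]$affine)
  stop_if_grid_mismatch(uni, brain_mask, "spheres and brain mask")
  dil <- dilate_mm(uni, dilation_mm)
  volume(array(dil$data * (brain_mask$data > 0), dim = dim(u)), uni$affine)
}

#' Minimum Euclidean distance from a DES point to a binary map
#'
#' Searches over the world-space centers of suprathreshold voxels.  If a
#' search mask is given and contains at least one suprathreshold voxel, the
#' search is restricted to it; otherwise the full map is searched and the
#' record is flagged `used_fallback`.  If the full map has no positive
#' voxels the distance is undefined (`NA`) and a warning is issued; such
#' records are excluded downstream.
#'
#' @param cog world-mm coordinate (length 3), normally the center of
#'   gravity of the DES sphere.
#' @param binary_map binary `volume`.
#' @param search_mask optional binary `volume` on the same grid.
#' @return List with `raw_distance_mm`, `distance_mm` (integer, via
#'   [round_mm()]), `used_fallback`, and `defined`.
#' @export
min_distance <- function(cog, binary_map, search_mask = NULL) {
  used_fallback <- FALSE
  sel <- binary_map$data > 0
  if (!is.null(search_mask)) {
    stop_if_grid_mismatch(binary_map, search_mask, "map and search mask")
    masked <- sel & (search_mask$data > 0)
    if (any(masked)) sel <- masked else used_fallback <- TRUE
  }
  if (!any(sel)) {
    warning("binary map has no positive voxels; distance undefined")
    return(list(raw_distance_mm = NA_real_, distance_mm = NA_integer_,
                used_fallback = used_fallback, defined = FALSE))
  }
  idx <- which(sel, arr.ind = TRUE)
  xyz <- voxel_to_world(binary_map, idx)
  dd <- sqrt(rowSums((xyz - matrix(cog, nrow(xyz), 3, byrow = TRUE))^2))
  raw <- min(dd)
  list(raw_distance_mm = raw, distance_mm = round_mm(raw),
       used_fallback = used_fallback, defined = TRUE)
}
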