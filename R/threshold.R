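#' Prepare a statistical map for thresholding
#'
#' Constrains the map to the gray-matter mask and clips negative values to
#' zero (anticorrelations and task deactivations are not of interest for
#' eloquent-cortex mapping, and keeping them would skew the intensity
#' rescaling toward low values).  Idempotent.
#'
#' @param stat_map 3D `volume`.
#' @param gm_mask binary `volume` on the same grid.
#' @return A `volume` that is zero outside the mask and nonnegative inside.
#' @export
prepare_map <- function(stat_map, gm_mask) {
  stop_if_grid_mismatch(stat_map, gm_mask, "map and gray-matter mask")
  out <- pmax(stat_map$data, 0) * (gm_mask$data > 0)
  volume(array(out, dim = dim(stat_map$data)), stat_map$affine)
}

#' Rescale positive map intensities to ranked k-means labels
#'
#' One-dimensional k-means on the positive voxel intensities.  Positive
#' voxels are labelled by the rank of their cluster center (1 = lowest);
#' zero voxels stay 0.  If there are fewer distinct positive values than
#' `K`, the distinct values themselves are ranked.  The clustering is the
#' exact optimum of the within-cluster sum of squares (weighted 1-D
#' dynamic program), hence fully deterministic; on a tied boundary a value
#' belongs to the lower cluster.  The labelling is invariant to strictly
#' increasing transforms of the intensities that preserve the optimal
#' cluster boundaries.
#'
#' @param prepared_map nonnegative `volume` from [prepare_map()].
#' @param K number of clusters (the default analysis uses 101 so labels
#'   span 1..101).
#' @return A `volume` of integer labels in `0..K`, with attributes
#'   `centers` and `sse`.
#' @export
kmeans_rescale <- function(prepared_map, K = 101) {
  if (K < 1) stop("K must be >= 1")
  v <- prepared_map$data
  pos <- which(v > 0)
  if (length(pos) == 0L) stop("empty map: no positive voxels")
  x <- v[pos]
  ux <- sort(unique(x))
  out <- array(0, dim = dim(v))
  if (length(ux) <= K) {
    out[pos] <- match(x, ux)
    centers <- ux
    sse <- 0
  } else {
    w <- tabulate(match(x, ux), nbins = length(ux))
    fit <- .kmeans1d_dp(ux, as.numeric(w), as.integer(K))
    out[pos] <- fit$cluster[match(x, ux)]
    centers <- fit$centers
    sse <- fit$sse
  }
  res <- volume(out, prepared_map$affine)
  attr(res, "centers") <- centers
  attr(res, "sse") <- sse
  res
}

#' Automatic minimum threshold and binarization of a label map
#'
#' Computes `m` (mean) and `s` (population standard deviation) of the
#' nonzero labels and retains voxels with label `>= T` where
#' `T = m + alpha * s`.
#'
#' @param label_map integer label `volume` from [kmeans_rescale()].
#' @param alpha SD multiplier in the threshold rule (default 1).
#' @return Object of class `threshold_result`: list with `label_map`, `m`,
#'   `s`, `T`, and `binary_map`.
#' @export
auto_threshold_binary <- function(label_map, alpha = 1) {
  if (!is.finite(alpha)) stop("alpha must be finite")
  lab <- label_map$data[label_map$data > 0]
  if (length(lab) == 0L) stop("all labels are zero")
  m <- mean(lab)
  s <- sqrt(mean((lab - m)^2))
  T <- m + alpha * s
  bin <- array(as.numeric(label_map$data >= T & label_map$data > 0),
               dim = dim(label_map$data))
  structure(list(label_map = label_map, m = m, s = s, T = T, alpha = alpha,
                 binary_map = volume(bin, label_map$affine)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> m = %.3f, s = %.3f, T = m + %g*s = %.3f; %d voxels retained\n",
    x$m, x$s, x$alpha, x$T, sum(x$binary_map$data > 0)))
  invisible(x)
}

#' Full map-thresholding stage
#'
#' [prepare_map()] then [kmeans_rescale()] then [auto_threshold_binary()].
#'
#' @param stat_map 3D statistic `volume`.
#' @param gm_mask binary gray-matter `volume`.
#' @param K number of k-means bins (default 101, labels 1..101).
#' @param alpha SD multiplier for the minimum-threshold rule (default 1).
#' @return A `threshold_result`.
#' @examples
#' g <- make_grid(c(12, 12, 6), c(2, 2, 2))
#' gm <- g; gm$data[] <- 1
#' m <- g; m$data[] <- rlnorm(length(m$data))
#' threshold_map(m, gm, K = 10)
#' @export
threshold_map <- function(stat_map, gm_mask, K = 101, alpha = 1) {
  prep <- prepare_map(stat_map, gm_mask)
  labels <- kmeans_rescale(prep, K)
  auto_threshold_binary(labels, alpha)
}
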