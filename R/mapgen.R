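#' Double-gamma haemodynamic response function
#'
#' `h(t) = g(t; a1, b1) - c * g(t; a2, b2)` where `g` is the gamma density
#' with shape `a` and scale `b`.  With the canonical parameters the response
#' peaks at `(a1 - 1) * b1 = 5` s and shows a late undershoot.  The kernel is
#' returned unnormalized (it is a difference of unit-area densities; any
#' overall scale cancels in the GLM z statistic).
#'
#' @param t numeric vector of times in seconds, nonnegative and increasing.
#' @param a1,b1 shape/scale of the main response (defaults 6, 1).
#' @param a2,b2 shape/scale of the undershoot (defaults 16, 1).
#' @param c undershoot ratio (default 1/6).
#' @return Numeric vector `h(t)`.
#' @examples
#' t <- seq(0, 32, by = 0.1)
#' h <- double_gamma_hrf(t)
#' t[which.max(h)]   # peaks at 5 s
#' @export
double_gamma_hrf <- function(t, a1 = 6, b1 = 1, a2 = 16, b2 = 1, c = 1 / 6) {
  if (any(c(a1, b1, a2, b2) <= 0)) stop("HRF shape/scale must be positive")
  if (any(t < 0)) stop("'t' must be nonnegative")
  if (is.unsorted(t)) stop("'t' must be increasing")
  stats::dgamma(t, shape = a1, scale = b1) -
    c * stats::dgamma(t, shape = a2, scale = b2)
}

#' Convolve a block design with the HRF and sample at the TR
#'
#' Builds a boxcar (1 during task blocks, 0 during control) on a fine time
#' grid, convolves it with [double_gamma_hrf()] (Riemann sum, so the output
#' scales as `integral h * boxcar`), and samples the result at acquisition
#' times `0, TR, ..., (n_vols-1)*TR`.
#'
#' @param blocks data.frame with columns `onset` and `duration` (seconds).
#' @param TR repetition time in seconds.
#' @param n_vols number of volumes.
#' @param hrf_params optional list of [double_gamma_hrf()] parameters.
#' @param dt fine-grid step in seconds.
#' @return Numeric regressor of length `n_vols`.
#' @export
build_task_regressor <- function(blocks, TR, n_vols, hrf_params = list(),
                                 dt = 0.1) {
  if (nrow(blocks) > 0) {
    o <- order(blocks$onset)
    b <- blocks[o, , drop = FALSE]
    if (any(b$duration < 0) || any(b$onset < 0))
      stop("block onsets/durations must be nonnegative")
    ends <- b$onset + b$duration
    if (nrow(b) > 1 && any(b$onset[-1] < ends[-nrow(b)] - 1e-9))
      stop("task blocks overlap")
    if (max(ends) > n_vols * TR + 1e-9)
      stop("task blocks extend beyond the scan duration")
  }
  t_fine <- seq(0, (n_vols - 1) * TR, by = dt)
  box <- numeric(length(t_fine))
  for (r in seq_len(nrow(blocks))) {
    on <- blocks$onset[r]
    box[t_fine >= on - 1e-9 & t_fine < on + blocks$duration[r] - 1e-9] <- 1
  }
  h <- do.call(double_gamma_hrf,
               c(list(t = seq(0, 32, by = dt)), hrf_params))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(t_fine)] * dt
  idx <- round(seq(0, n_vols - 1) * TR / dt) + 1
  conv[idx]
}

colwise_sd <- function(Y) {
  n <- nrow(Y)
  mu <- colMeans(Y)
  v <- (colSums(Y^2) - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}

series_as_matrix <- function(series) {
  d <- dim(series)
  nd <- length(d)
  if (nd == 2L) return(series)  # already time x voxels
  if (nd != 4L) stop("series must be a 4D array or a time x voxel matrix")
  t(matrix(series, nrow = prod(d[1:3]), ncol = d[4]))
}

matrix_as_series <- function(mat, dim4) array(t(mat), dim = dim4)

fft_convolve_time <- function(X, kernel) {
  # columnwise linear convolution, returning the 'same' central part
  n <- nrow(X)
  m <- length(kernel)
  N <- stats::nextn(n + m - 1L, 2)
  K <- stats::fft(c(kernel, rep(0, N - m)))
  Xp <- rbind(X, matrix(0, N - n, ncol(X)))
  out <- Re(stats::mvfft(stats::mvfft(Xp) * K, inverse = TRUE)) / N
  half <- (m - 1L) %/% 2L
  out[(half + 1L):(half + n), , drop = FALSE]
}

#' Temporal filtering of a BOLD series
#'
#' `highpass_gaussian` subtracts a Gaussian-weighted running mean with
#' standard deviation `sigma_TR` (in TR units), edge-renormalized — the
#' high-pass behaviour of the usual `-bptf`-style filter.  `bandpass`
#' retains only Fourier components with frequency inside `band` Hz
#' (inclusive); the DC component is removed.
#'
#' @param series 4D array, `volume`, or time x voxel matrix.
#' @param kind `"highpass_gaussian"` or `"bandpass"`.
#' @param TR repetition time in seconds.
#' @param sigma_TR high-pass kernel SD in TRs (default 20).
#' @param band numeric `(low, high)` in Hz (default `c(0.001, 0.01)`).
#' @return Filtered object of the same type as the input.
#' @export
temporal_filter <- function(series, kind = c("highpass_gaussian", "bandpass"),
                            TR, sigma_TR = 20, band = c(0.001, 0.01)) {
  kind <- match.arg(kind)
  vol_in <- is_volume(series)
  arr <- if (vol_in) series$data else series
  X <- series_as_matrix(arr)
  n <- nrow(X)
  if (kind == "highpass_gaussian") {
    if (n <= 3 * sigma_TR)
      stop("series too short for the requested high-pass scale")
    half <- ceiling(4 * sigma_TR)
    k <- stats::dnorm(seq(-half, half), sd = sigma_TR)
    num <- fft_convolve_time(X, k)
    den <- fft_convolve_time(matrix(1, n, 1), k)
    Y <- X - num / as.vector(den)
  } else {
    nyq <- 1 / (2 * TR)
    if (band[1] < 0 || band[2] <= band[1] || band[2] >= nyq)
      stop("band must satisfy 0 <= low < high < Nyquist")
    k <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L))  # two-sided bin index
    freq <- k / (n * TR)
    keep <- freq >= band[1] & freq <= band[2] & k > 0L
    F <- stats::mvfft(X)
    F[!keep, ] <- 0
    Y <- Re(stats::mvfft(F, inverse = TRUE)) / n
  }
  out <- if (is.matrix(arr)) Y else matrix_as_series(Y, dim(arr))
  if (vol_in) volume(out, series$affine) else out
}

confound_design <- function(confounds, n) {
  C <- as.matrix(confounds)
  if (nrow(C) != n) stop("confound rows must equal the number of volumes")
  D <- cbind(intercept = 1, C)
  q <- qr(D)
  if (q$rank < ncol(D)) {
    bad <- colnames(D)[-seq_len(q$rank)]
    stop(sprintf("confound matrix is rank deficient (collinear: %s)",
                 paste(bad, collapse = ", ")))
  }
  list(D = D, qr = q)
}

#' Project confounds out of a series
#'
#' Voxelwise least-squares residual after regressing on the confounds plus
#' an intercept.
#'
#' @param series 4D array, `volume`, or time x voxel matrix.
#' @param confounds numeric matrix/vector, one row per volume.
#' @return Residual series, same type as the input.
#' @export
regress_confounds <- function(series, confounds) {
  vol_in <- is_volume(series)
  arr <- if (vol_in) series$data else series
  X <- series_as_matrix(arr)
  cd <- confound_design(confounds, nrow(X))
  Y <- qr.resid(cd$qr, X)
  out <- if (is.matrix(arr)) Y else matrix_as_series(Y, dim(arr))
  if (vol_in) volume(out, series$affine) else out
}

t_to_z <- function(tval, df, zmax = 40) {
  z <- sign(tval) * stats::qnorm(stats::pt(abs(tval), df, lower.tail = FALSE),
                                 lower.tail = FALSE)
  z[is.na(z)] <- 0
  pmax(pmin(z, zmax), -zmax)
}

#' Voxelwise GLM z-statistic map for a task regressor
#'
#' Ordinary least squares of every voxel's time course on
#' `[regressor, confounds, intercept]`; the regressor's t statistic is
#' converted to a z score by matching upper-tail probabilities at the
#' residual degrees of freedom and capped at `±zmax`.
#'
#' @param series 4D `volume` (or array with `affine` supplied).
#' @param regressor numeric vector, length = number of volumes.
#' @param confounds optional confound matrix.
#' @param zmax cap for the z statistic (default 40; noise-free fits report
#'   the cap).
#' @param affine required if `series` is a bare array.
#' @return List with `zmap` (a `volume`), `beta` (a `volume`), and `df`.
#' @export
glm_zmap <- function(series, regressor, confounds = NULL, zmax = 40,
                     affine = NULL) {
  if (is_volume(series)) {
    arr <- series$data; aff <- series$affine
  } else {
    arr <- series; aff <- if (is.null(affine)) diag(4) else affine
  }
  Y <- series_as_matrix(arr)
  n <- nrow(Y)
  if (length(regressor) != n) stop("regressor length must equal n_vols")
  if (stats::var(regressor) <= 0) stop("regressor has zero variance")
  X <- cbind(reg = regressor,
             if (!is.null(confounds)) as.matrix(confounds), intercept = 1)
  q <- qr(X)
  if (q$rank < ncol(X)) stop("design matrix is rank deficient")
  df <- n - ncol(X)
  if (df <= 0) stop("nonpositive residual degrees of freedom")
  beta <- qr.coef(q, Y)
  res <- qr.resid(q, Y)
  sigma2 <- colSums(res^2) / df
  xtxinv11 <- chol2inv(qr.R(q))[1, 1]
  se <- sqrt(sigma2 * xtxinv11)
  tval <- ifelse(se > 0, beta[1, ] / se, sign(beta[1, ]) * Inf)
  z <- t_to_z(tval, df, zmax)
  d3 <- if (is.matrix(arr)) c(ncol(Y), 1L, 1L) else dim(arr)[1:3]
  list(zmap = volume(array(z, dim = d3), aff),
       beta = volume(array(beta[1, ], dim = d3), aff),
       df = df)
}

#' Seed-to-voxel connectivity map
#'
#' The seed time course is the mean over seed voxels of the (already
#' filtered/denoised) series; the map value is the regression slope of each
#' voxel's series on the variance-standardized seed course.  Pearson r is
#' returned alongside for QA.
#'
#' @param series 4D `volume`.
#' @param seed_mask 3D binary `volume` on the same grid.
#' @return List with `beta` (a `volume`), `r` (a `volume`), and
#'   `seed_course`.
#' @export
seed_connectivity_map <- function(series, seed_mask) {
  d <- dim(series$data)
  stopifnot(length(d) == 4L)
  if (!identical(grid_dim3(seed_mask), d[1:3]))
    stop("seed mask is not on the series grid")
  sel <- which(seed_mask$data > 0)
  if (length(sel) == 0L) stop("seed mask is empty")
  Y <- series_as_matrix(series$data)
  s <- rowMeans(Y[, sel, drop = FALSE])
  if (stats::sd(s) == 0) stop("seed time course has zero variance")
  s_std <- (s - mean(s)) / stats::sd(s)
  n <- length(s)
  beta <- as.vector(crossprod(Y, s_std)) / (n - 1) -
    colMeans(Y) * mean(s_std) * n / (n - 1)
  sdy <- colwise_sd(Y)
  r <- ifelse(sdy > 0, beta / sdy, 0)
  d3 <- d[1:3]
  list(beta = volume(array(beta, dim = d3), series$affine),
       r = volume(array(r, dim = d3), series$affine),
       seed_course = s)
}

#' Combine multi-echo series into a single T2*-weighted series
#'
#' A voxelwise T2* is estimated by a log-linear fit of the time-averaged
#' signal against echo time; echoes are then averaged with weights
#' `w_e proportional to TE_e * exp(-TE_e / T2*)`, normalized to sum to one.
#' Voxels with a nonpositive mean signal at any echo, or a non-decaying
#' log-linear fit, fall back to uniform weights and are flagged in a QA
#' mask.
#'
#' @param echo_series list of 4D `volume`s, one per echo, same grid/length.
#' @param echo_times_ms numeric echo times in milliseconds, increasing.
#' @return List with `series` (combined 4D `volume`), `t2star` (`volume`,
#'   ms), and `qa_fallback` (binary `volume`).
#' @export
combine_echoes <- function(echo_series, echo_times_ms) {
  ne <- length(echo_series)
  if (ne < 2L) stop("at least two echoes are required")
  if (length(echo_times_ms) != ne) stop("one echo time per echo series")
  if (any(echo_times_ms <= 0) || is.unsorted(echo_times_ms, strictly = TRUE))
    stop("echo times must be positive and strictly increasing")
  d <- dim(echo_series[[1]]$data)
  for (e in seq_len(ne)) {
    if (!identical(dim(echo_series[[e]]$data), d))
      stop("echo series have mismatched dimensions")
  }
  nvox <- prod(d[1:3])
  M <- vapply(echo_series,
              function(v) rowMeans(matrix(v$data, nrow = nvox)), numeric(nvox))
  ok <- rowSums(M <= 0) == 0
  te <- echo_times_ms
  # slope of log(mean) on TE, vectorized over voxels
  L <- matrix(NA_real_, nvox, ne)
  L[ok, ] <- log(M[ok, , drop = FALSE])
  teC <- te - mean(te)
  slope <- as.vector(L %*% teC) / sum(teC^2)
  decaying <- ok & !is.na(slope) & slope < 0
  t2star <- rep(NA_real_, nvox)
  t2star[decaying] <- -1 / slope[decaying]
  W <- matrix(1 / ne, nvox, ne)
  W[decaying, ] <- outer(t2star[decaying], te,
                         function(tt, e) e * exp(-e / tt))
  W <- W / rowSums(W)
  comb <- matrix(0, nvox, d[4])
  for (e in seq_len(ne)) {
    comb <- comb + W[, e] * matrix(echo_series[[e]]$data, nrow = nvox)
  }
  aff <- echo_series[[1]]$affine
  list(series = volume(array(comb, dim = d), aff),
       t2star = volume(array(t2star, dim = d[1:3]), aff),
       qa_fallback = volume(array(as.numeric(!decaying), dim = d[1:3]), aff))
}

reflect_index <- function(i, L) {
  # scipy-style 'reflect' (edge duplicated): d c b a | a b c d | d c b a
  p <- 2L * L
  i <- ((i - 1L) %% p + p) %% p + 1L
  ifelse(i > L, p - i + 1L, i)
}

smooth_matrix_1d <- function(L, sigma_vox) {
  if (sigma_vox <= 0) return(diag(L))
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  k <- k / sum(k)
  M <- matrix(0, L, L)
  for (o in seq(-half, half)) {
    src <- reflect_index(seq_len(L) + o, L)
    M[cbind(seq_len(L), src)] <- M[cbind(seq_len(L), src)] + k[o + half + 1L]
  }
  M
}

# Sparse separable smoothing operators: per-axis banded matrices lifted to
# the full voxel space by Kronecker products with identities, applied to a
# voxel x time matrix (column-major, axis 1 fastest).  Avoids any array
# permutation.
smooth_operators <- function(d3, sig_vox) {
  Ms <- lapply(1:3, function(a)
    Matrix::Matrix(smooth_matrix_1d(d3[a], sig_vox[a]), sparse = TRUE))
  list(
    Matrix::kronecker(Matrix::Diagonal(d3[2] * d3[3]), Ms[[1]]),
    Matrix::kronecker(Matrix::Diagonal(d3[3]),
                      Matrix::kronecker(Ms[[2]], Matrix::Diagonal(d3[1]))),
    Matrix::kronecker(Ms[[3]], Matrix::Diagonal(d3[1] * d3[2])))
}

smooth_voxmat <- function(X, d3, fwhm_mm, voxel_size) {
  if (fwhm_mm == 0) return(X)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  ops <- smooth_operators(d3, sigma_mm / voxel_size)
  for (K in ops) X <- K %*% X   # Matrix intermediates; densify once
  as.matrix(X)
}

#' Spatial Gaussian smoothing in millimetres
#'
#' Separable 3D Gaussian with `sigma_mm = fwhm / (2 sqrt(2 log 2))` per
#' axis, converted to voxel units from the affine (anisotropic voxels
#' honoured).  Reflective boundaries preserve constant volumes; `fwhm = 0`
#' is the identity.  4D inputs are smoothed volume by volume.
#'
#' @param vol 3D or 4D `volume`.
#' @param fwhm_mm full width at half maximum in mm (default 6).
#' @return Smoothed `volume`.
#' @export
gaussian_smooth <- function(vol, fwhm_mm = 6) {
  if (fwhm_mm < 0) stop("fwhm must be nonnegative")
  if (fwhm_mm == 0) return(vol)
  d <- dim(vol$data)
  d3 <- d[1:3]
  nt <- if (length(d) == 4L) d[4] else 1L
  X <- matrix(vol$data, prod(d3), nt)
  X <- smooth_voxmat(X, d3, fwhm_mm, voxel_sizes(vol))
  volume(array(X, dim = d), vol$affine)
}

#' Temporal SNR and framewise displacement
#'
#' tSNR is the voxelwise temporal mean divided by the temporal SD (infinite
#' where the SD is zero; such voxels are flagged).  Framewise displacement
#' follows the usual convention
#' `FD_t = sum |delta translations| + 50 mm * sum |delta rotations|`.
#'
#' @param series 4D `volume`.
#' @param motion_params matrix with 6 columns (3 translations in mm,
#'   3 rotations in radians), one row per volume.
#' @return List with `tsnr` (`volume`), `fd` (per-volume vector, first
#'   element 0), `mean_fd`, and `n_zero_sd`.
#' @export
qa_metrics <- function(series, motion_params) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6L) stop("motion_params must have 6 columns")
  d <- dim(series$data)
  if (nrow(motion_params) != d[4])
    stop("motion_params rows must equal the number of volumes")
  nt <- d[4]
  Yv <- matrix(series$data, prod(d[1:3]), nt)  # voxel x time, no transpose
  mu <- rowMeans(Yv)
  v <- (rowSums(Yv^2) - nt * mu^2) / (nt - 1)
  sdv <- sqrt(pmax(v, 0))
  tsnr <- ifelse(sdv > 0, mu / sdv, Inf)
  dm <- abs(diff(motion_params))
  fd <- c(0, rowSums(dm[, 1:3, drop = FALSE]) +
            50 * rowSums(dm[, 4:6, drop = FALSE]))
  list(tsnr = volume(array(tsnr, dim = d[1:3]), series$affine),
       fd = fd, mean_fd = mean(fd[-1]), n_zero_sd = sum(sdv == 0))
}
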