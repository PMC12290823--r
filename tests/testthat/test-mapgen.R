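test_that("double-gamma HRF has the canonical shape", {
  t <- seq(0, 32, by = 0.1)
  h <- double_gamma_hrf(t)
  expect_equal(h[1], 0)
  expect_equal(t[which.max(h)], 5)          # gamma mode (a-1)*b = 5 s
  expect_true(any(h < 0))                   # undershoot present
  expect_true(all(double_gamma_hrf(t, c = 0) >= 0))
  expect_error(double_gamma_hrf(t, a1 = -1), "positive")
})

test_that("task regressor: degenerate and spectral cases", {
  expect_equal(build_task_regressor(data.frame(onset = numeric(0),
                                               duration = numeric(0)),
                                    TR = 1.5, n_vols = 40),
               rep(0, 40))
  # near-impulse block reproduces the sampled HRF up to the Riemann scale
  dt <- 0.1
  r <- build_task_regressor(data.frame(onset = 0, duration = dt),
                            TR = 1, n_vols = 30, dt = dt)
  h <- double_gamma_hrf(seq(0, 29, by = 1))
  expect_lt(max(abs(r / dt - h)), 0.02 * max(h))
  # 30 s on/off for 160 volumes at TR 1.5 -> dominant period 40 samples
  blocks <- data.frame(onset = seq(30, 210, by = 60), duration = 30)
  reg <- build_task_regressor(blocks, TR = 1.5, n_vols = 160)
  sp <- Mod(fft(reg - mean(reg)))[2:80]
  expect_equal(which.max(sp) + 1L, 5L)      # bin 5 <-> period 160/4 = 40
  expect_error(build_task_regressor(data.frame(onset = c(0, 10),
                                               duration = c(20, 10)),
                                    TR = 1, n_vols = 60), "overlap")
})

test_that("temporal filters behave as high-pass / band-pass", {
  n <- 200; TR <- 1
  const <- matrix(5, n, 3)
  expect_lt(max(abs(temporal_filter(const, "highpass_gaussian", TR = TR,
                                    sigma_TR = 10))), 1e-8)
  tt <- seq_len(n)
  inband <- sin(2 * pi * 0.02 * tt)         # inside a 0.01-0.05 Hz band
  out <- temporal_filter(matrix(inband), "bandpass", TR = TR,
                         band = c(0.01, 0.05))
  expect_lt(abs(max(Mod(fft(out))) / max(Mod(fft(inband))) - 1), 0.05)
  hi <- sin(2 * pi * 0.45 * tt)             # 10x the upper cutoff, ~Nyquist
  outh <- temporal_filter(matrix(hi), "bandpass", TR = TR,
                          band = c(0.005, 0.045))
  expect_lt(stats::sd(outh) / stats::sd(hi), 0.1)
  # idempotence of the FFT band-pass
  once <- temporal_filter(matrix(rnorm(n)), "bandpass", TR = TR,
                          band = c(0.01, 0.05))
  twice <- temporal_filter(once, "bandpass", TR = TR, band = c(0.01, 0.05))
  expect_lt(max(abs(once - twice)), 1e-8)
  expect_error(temporal_filter(const, "bandpass", TR = 1,
                               band = c(0.1, 0.6)), "Nyquist")
})

test_that("confound regression projects exactly and reports collinearity", {
  set.seed(21)
  n <- 60
  X <- matrix(rnorm(3 * n), n, 3)
  # regressing a voxel's own series leaves ~0
  r <- regress_confounds(X, X[, 1])
  expect_lt(max(abs(r[, 1])), 1e-10)
  # residuals orthogonal to the confounds
  C <- matrix(rnorm(2 * n), n, 2)
  r2 <- regress_confounds(X, C)
  expect_lt(max(abs(crossprod(r2, C))), 1e-8 * max(abs(X)) * n)
  # orthogonal confound changes nothing but the mean
  co <- rep(c(1, -1), n / 2)
  y <- matrix(rep(c(1, 1), n / 2) + 0)      # constant, orthogonal to co
  expect_lt(max(abs(regress_confounds(y, co) - (y - mean(y)))), 1e-10)
  expect_error(regress_confounds(X, cbind(C, C[, 1])), "rank deficient")
})

test_that("GLM z-maps: exact fit, null calibration, sign equivariance", {
  set.seed(31)
  n <- 80
  reg <- rep(c(0, 1), each = 10, times = 4)[1:n]
  # noise-free: beta exact, z at the cap
  y <- matrix(3 * reg + 5)
  g <- glm_zmap(array(y, dim = c(1, 1, 1, n)), reg, affine = diag(4))
  expect_equal(as.vector(g$beta$data), 3, tolerance = 1e-10)
  expect_equal(as.vector(g$zmap$data), 40)
  # pure noise: z approximately standard normal over voxels
  Y <- array(rnorm(n * 10000), dim = c(100, 100, 1, n))
  gz <- glm_zmap(Y, reg, affine = diag(4))
  expect_lt(abs(mean(gz$zmap$data)), 0.05)
  expect_lt(abs(stats::var(as.vector(gz$zmap$data)) - 1), 0.1)
  gzf <- glm_zmap(Y, -reg, affine = diag(4))
  expect_equal(gzf$zmap$data, -gz$zmap$data, tolerance = 1e-10)
})

test_that("seed connectivity: exact correlations and null level", {
  set.seed(41)
  n <- 120
  s <- rnorm(n)
  d3 <- c(3, 1, 1)
  arr <- array(0, dim = c(d3, n))
  arr[1, 1, 1, ] <- s
  arr[2, 1, 1, ] <- -s
  arr[3, 1, 1, ] <- rnorm(n)
  ser <- volume(arr, diag(4))
  seed <- volume(array(c(1, 0, 0), dim = d3), diag(4))
  sc <- seed_connectivity_map(ser, seed)
  expect_equal(sc$r$data[1, 1, 1], 1, tolerance = 1e-10)
  expect_equal(sc$r$data[2, 1, 1], -1, tolerance = 1e-10)
  # independent voxels: mean r within 2/sqrt(n)
  nv <- 2000
  arr2 <- array(rnorm(nv * n), dim = c(nv, 1, 1, n))
  arr2[1, 1, 1, ] <- s
  sc2 <- seed_connectivity_map(volume(arr2, diag(4)),
                               volume(array(c(1, rep(0, nv - 1)),
                                            dim = c(nv, 1, 1)), diag(4)))
  expect_lt(abs(mean(sc2$r$data[-1, , ])), 2 / sqrt(n))
  expect_error(seed_connectivity_map(ser, volume(array(0, dim = d3),
                                                 diag(4))), "empty")
})

test_that("echo combination recovers T2* and degenerates gracefully", {
  te <- c(8, 33, 58)
  d3 <- c(4, 4, 2); n <- 10
  # noise-free mono-exponential with T2* = 40 ms
  mk <- function(scale) volume(array(scale, dim = c(d3, n)), diag(4))
  ser <- lapply(te, function(e) mk(1000 * exp(-e / 40)))
  cb <- combine_echoes(ser, te)
  expect_lt(max(abs(cb$t2star$data - 40)), 1e-6)
  expect_equal(sum(cb$qa_fallback$data), 0)
  # two identical echoes: combined equals the input (weights sum to 1)
  set.seed(51)
  a <- array(abs(rnorm(prod(d3) * n)) + 1, dim = c(d3, n))
  same <- list(volume(a, diag(4)), volume(a, diag(4)))
  expect_equal(combine_echoes(same, c(10, 30))$series$data, a,
               tolerance = 1e-10)
  expect_error(combine_echoes(ser[1], te[1]), "two echoes")
})

test_that("echo combination improves tSNR over the best single echo", {
  set.seed(61)
  te <- c(8, 33, 58); t2s <- 40; n <- 120
  nvox <- 10000
  clean <- lapply(te, function(e) matrix(1000 * exp(-e / t2s), nvox, n))
  # thermal noise scaling with the echo's signal level (the generator's
  # noise model); the T2*-weighted average then strictly beats any single
  # echo by Cauchy-Schwarz
  noisy <- lapply(clean, function(M)
    M + rnorm(length(M), sd = 0.02 * M[1, 1]))
  vols <- lapply(noisy, function(M)
    volume(array(M, dim = c(nvox, 1, 1, n)), diag(4)))
  cb <- combine_echoes(vols, te)
  tsnr <- function(M) {
    mu <- rowMeans(M); sdv <- apply(M, 1, sd); median(mu / sdv)
  }
  comb_mat <- matrix(cb$series$data, nvox, n)
  best_single <- max(vapply(noisy, tsnr, numeric(1)))
  expect_gt(tsnr(comb_mat), best_single)
})

test_that("Gaussian smoothing: identity, mass preservation, kernel value", {
  v <- make_grid(c(11, 11, 11), c(1, 1, 1))
  v$data[] <- rnorm(length(v$data))
  expect_equal(gaussian_smooth(v, 0)$data, v$data)
  cst <- make_grid(c(9, 9, 9), c(1, 1, 1)); cst$data[] <- 3.5
  expect_lt(max(abs(gaussian_smooth(cst, 6)$data - 3.5)), 1e-10)
  # delta impulse: neighbour/center ratio equals exp(-1/(2 sigma^2))
  imp <- make_grid(c(21, 21, 21), c(1, 1, 1)); imp$data[11, 11, 11] <- 1
  sm <- gaussian_smooth(imp, 6)
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  expect_equal(sm$data[12, 11, 11] / sm$data[11, 11, 11],
               exp(-1 / (2 * sigma^2)), tolerance = 1e-6)
})

test_that("QA metrics: framewise displacement and tSNR", {
  n <- 50
  ser <- volume(array(100 + rnorm(1000 * n), dim = c(10, 10, 10, n)),
                diag(4))
  mot <- matrix(0, n, 6)
  qa <- qa_metrics(ser, mot)
  expect_equal(qa$mean_fd, 0)
  expect_lt(abs(median(qa$tsnr$data) - 100) / 100, 0.05)
  mot2 <- mot; mot2[25, 1] <- 1   # 1 mm translation step
  qa2 <- qa_metrics(ser, mot2)
  expect_equal(qa2$fd[25], 1)
  expect_equal(qa2$fd[26], 1)     # step back down
  # rotations use the 50 mm lever arm
  mot3 <- mot; mot3[10, 4] <- 0.01
  expect_equal(qa_metrics(ser, mot3)$fd[10], 0.5)
})
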