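# Independent oracles and small fixture builders used across the suite.

# Exact 1-D k-means by the O(K n^2) dynamic program (weighted).
# Independent of the package's divide-and-conquer implementation.
dp_kmeans_sse <- function(x, w = rep(1, length(x)), K) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  n <- length(x)
  W <- cumsum(w); WX <- cumsum(w * x); WXX <- cumsum(w * x^2)
  W0 <- c(0, W); WX0 <- c(0, WX); WXX0 <- c(0, WXX)
  cost <- function(j, i) {  # vectorized over j
    sw <- W0[i + 1] - W0[j]
    sx <- WX0[i + 1] - WX0[j]
    sxx <- WXX0[i + 1] - WXX0[j]
    pmax(sxx - sx^2 / sw, 0)
  }
  D <- cost(1, 1:n)
  if (K > 1) {
    for (k in 2:K) {
      Dn <- rep(Inf, n)
      for (i in k:n) {
        j <- k:i
        Dn[i] <- min(D[j - 1] + cost(j, i))
      }
      Dn[k - 1] <- 0
      D <- Dn
    }
  }
  D[n]
}

# Brute-force minimum Euclidean distance: plain loop over positive voxels.
brute_min_distance <- function(cog, vol, mask = NULL) {
  best <- Inf
  d <- dim(vol$data)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (vol$data[i, j, k] <= 0) next
    if (!is.null(mask) && mask$data[i, j, k] <= 0) next
    p <- as.vector(vol$affine %*% c(i - 1, j - 1, k - 1, 1))[1:3]
    best <- min(best, sqrt(sum((p - cog)^2)))
  }
  best
}

# Tie-corrected Mann-Whitney AUC by exhaustive pair counting, scoring
# "smaller distance = positive".
mw_auc <- function(d_pos, d_neg) {
  s <- 0
  for (dp in d_pos) for (dn in d_neg)
    s <- s + (dp < dn) + 0.5 * (dp == dn)
  s / (length(d_pos) * length(d_neg))
}

# Random binary volume on a small grid.
random_binary_volume <- function(dim3 = c(8, 8, 8), p = 0.3,
                                 voxel = c(1, 1, 1)) {
  g <- make_grid(dim3, voxel)
  g$data[] <- as.numeric(stats::runif(prod(dim3)) < p)
  g
}

# Random distance-record table.
random_records <- function(n_sub = 6, methods = "tbfMRI") {
  rows <- expand.grid(subject = sprintf("S%02d", seq_len(n_sub)),
                      method = methods, func = c("hands", "feet"),
                      response = c("pDES", "nDES"),
                      stringsAsFactors = FALSE)
  rows <- rows[stats::runif(nrow(rows)) < 0.8, , drop = FALSE]
  rows$distance_mm <- sample(0:20, nrow(rows), replace = TRUE)
  rows
}

# Dense-grid 2-D trapezoid integration of the two-part marginal
# likelihood (independent of the Gauss-Hermite path).
dense_two_part_loglik <- function(params, data, n_nodes = 2001, span = 8) {
  ba <- params$beta_a; bb <- params$beta_b
  su <- params$sigma_u; sv <- params$sigma_v
  rho <- params$rho; se <- params$sigma_eps
  u <- seq(-span * su, span * su, length.out = n_nodes)
  v <- seq(-span * sv, span * sv, length.out = n_nodes)
  S <- matrix(c(su^2, rho * su * sv, rho * su * sv, sv^2), 2)
  Si <- solve(S)
  dens <- outer(u, v, function(U, V)
    exp(-(Si[1, 1] * U^2 + 2 * Si[1, 2] * U * V + Si[2, 2] * V^2) / 2)) /
    (2 * pi * sqrt(det(S)))
  du <- diff(u)[1]; dv <- diff(v)[1]
  wu <- rep(du, n_nodes); wu[c(1, n_nodes)] <- du / 2
  wv <- rep(dv, n_nodes); wv[c(1, n_nodes)] <- dv / 2
  total <- 0
  X <- cbind(1)  # intercept-only oracle fixtures
  for (s in unique(data$subject)) {
    ys <- data$y[data$subject == s]
    LA <- matrix(0, n_nodes, 1)
    lA <- vapply(u, function(U) {
      p <- stats::plogis(ba[1] + U)
      sum(ifelse(ys == 0, log(p), log1p(-p)))
    }, numeric(1))
    lB <- vapply(v, function(V)
      sum(stats::dlnorm(ys[ys > 0], bb[1] + V, se, log = TRUE)),
      numeric(1))
    G <- exp(outer(lA, lB, "+")) * dens
    total <- total + log(sum(G * outer(wu, wv)))
  }
  total
}

# A small, fast phantom configuration for structural tests (not the study
# conditions; those are the package defaults).
tiny_phantom_config <- function(n_subjects = 2, seed = 7) {
  phantom_config(
    n_subjects = n_subjects,
    feet_subjects = 1,
    fov_mm = c(56, 56, 44),
    task_design = list(block_s = 30, n_block_pairs = 2, TR = 1.5,
                       n_vols = 80, amplitude = 30, noise_sd = 20),
    rest_params = list(band_hz = c(0.004, 0.012), amplitude = 30,
                       noise_sd = 20, ar1 = 0.3,
                       TR_sTE2 = 0.9, n_vols_sTE2 = 160,
                       TR_mTE = 1.15, n_vols_mTE = 140,
                       s0_artifact_sd = 0.005),
    activation_centers = list(hands = rbind(c(-12, -5, 12), c(12, -5, 12)),
                              feet = rbind(c(-3, -6, 15), c(3, -6, 15))),
    activation_radius_mm = 5,
    des_counts = list(n_pos = 1:2, n_neg = 2:4),
    ndes_distance = list(median_mm = 9, sdlog = 0.5),
    pdes_margin_mm = 8,
    seed = seed)
}
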