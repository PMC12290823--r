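#' Phantom study configuration
#'
#' Defines the synthetic validation cohort: grid geometry, the four
#' acquisition schemes (task-based 1.8 x 1.8 x 3.2 mm; single-echo rest at
#' 2 x 2 x 2.2 mm; single-echo rest at 3 mm = middle echo of the
#' multi-echo scheme; multi-echo rest at 3 mm with echo times 8/33/58 ms),
#' the activation truth geometry, the block task design (pairs of
#' 30-second task/control blocks), resting-state fluctuation parameters,
#' the mono-exponential multi-echo signal model, and the DES sampling
#' scheme (few positive sites near truth, many negative sites at
#' right-skewed lognormal distances, counts varying per subject).
#'
#' @param n_subjects number of phantom subjects (default 16).
#' @param functions mapped functions, subset of `c("hands", "feet")`.
#' @param feet_subjects how many subjects (from the first) also get feet
#'   mapping (default 5; hands are mapped for everyone).
#' @param fov_mm world-space field of view in mm.
#' @param voxel_size_mm named list of per-method voxel sizes.
#' @param activation_centers named list (per function) of matrices of
#'   world-mm blob centers.
#' @param activation_radius_mm truth blob radius (default 6).
#' @param secondary_offset_mm world-mm offset of the secondary
#'   (supplementary-motor / premotor-like) activation blobs relative to
#'   the primary centers; motor tasks and the resting sensorimotor
#'   network both engage these regions, at reduced amplitude
#'   (`secondary_gain`).  Secondary blobs are part of the imaged maps but
#'   not of the DES ground truth.
#' @param secondary_gain relative amplitude of the secondary blobs.
#' @param lesion optional `list(center, radius_mm)` carved out of the
#'   brain and gray-matter masks.
#' @param task_design list: `block_s`, `n_block_pairs`, `TR`, `n_vols`,
#'   `amplitude`, `noise_sd`.
#' @param rest_params list: `band_hz` (network fluctuation band),
#'   `amplitude`, `noise_sd`, `ar1`, `TR_sTE2`, `n_vols_sTE2`, `TR_mTE`,
#'   `n_vols_mTE`, `s0_artifact_sd`, and the resting-network geometry
#'   `network_extension_mm` / `network_extension_gain`: the resting-state
#'   network fluctuates over the task truth plus a surrounding cortical
#'   band (at reduced amplitude), reproducing the widespread,
#'   less-specific connectivity maps seen in sensorimotor cohorts relative
#'   to task activation.
#' @param echo_times_ms multi-echo times in ms, strictly increasing.
#' @param t2star_ms gray-matter T2* in ms.
#' @param s0 baseline signal intensity.
#' @param des_counts list of integer ranges `n_pos`, `n_neg` sampled per
#'   subject.
#' @param amplitude_sdlog_subject,amplitude_sdlog_scan lognormal SDs of the
#'   BOLD response amplitude across subjects and across scans within a
#'   subject.  Session-to-session response variability is a well-documented
#'   feature of BOLD cohorts; it induces the subject-level correlated
#'   variation in map quality (and hence in distances) that the two-part
#'   model's random intercepts absorb.
#' @param ndes_distance list `median_mm`, `sdlog` of the lognormal
#'   negative-site distance distribution.
#' @param pdes_margin_mm positive sites lie within this margin of truth
#'   (default 16 mm: stimulation hits are near, not inside, the imaged
#'   activation; thresholded maps extend a few millimetres beyond truth,
#'   so placed-to-truth distances are calibrated to give measured
#'   map-to-site distances in the published clinical range).
#' @param ndes_margin_mm negative sites lie at least this far from truth
#'   (default 5 mm); positive- and negative-site distance distributions
#'   overlap, as in real cohorts.
#' @param seed master RNG seed; per-subject streams are derived from it.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(
    n_subjects = 16,
    functions = c("hands", "feet"),
    feet_subjects = 5,
    fov_mm = c(80, 80, 60),
    voxel_size_mm = list(tbfMRI = c(1.8, 1.8, 3.2),
                         sTE2mm = c(2, 2, 2.2),
                         sTE3mm = c(3, 3, 3),
                         mTE = c(3, 3, 3)),
    activation_centers = list(
      hands = rbind(c(-20, -8, 18), c(20, -8, 18)),
      feet = rbind(c(-4, -10, 24), c(4, -10, 24))),
    activation_radius_mm = 6,
    secondary_offset_mm = c(0, 14, 0),
    secondary_gain = 0.7,
    lesion = NULL,
    task_design = list(block_s = 30, n_block_pairs = 4, TR = 1.5,
                       n_vols = 160, amplitude = 20, noise_sd = 20),
    rest_params = list(band_hz = c(0.003, 0.009), amplitude = 20,
                       noise_sd = 20, ar1 = 0.3,
                       TR_sTE2 = 0.9, n_vols_sTE2 = 500,
                       TR_mTE = 1.15, n_vols_mTE = 400,
                       s0_artifact_sd = 0.005,
                       network_extension_mm = 8,
                       network_extension_gain = 0.6),
    echo_times_ms = c(8, 33, 58),
    t2star_ms = 40,
    s0 = 1000,
    des_counts = list(n_pos = 0:3, n_neg = 3:8),
    ndes_distance = list(median_mm = 17, sdlog = 0.6),
    pdes_margin_mm = 16,
    ndes_margin_mm = 5,
    amplitude_sdlog_subject = 0.15,
    amplitude_sdlog_scan = 0.25,
    seed = 1) {
  stopifnot(n_subjects >= 1, all(functions %in% c("hands", "feet")),
            all(fov_mm > 0), activation_radius_mm > 0,
            task_design$block_s > 0, task_design$TR > 0,
            all(echo_times_ms > 0), t2star_ms > 0, s0 > 0)
  if (is.unsorted(echo_times_ms, strictly = TRUE))
    stop("echo times must be strictly increasing")
  if (ndes_distance$median_mm <= activation_radius_mm)
    stop("nDES median distance must exceed the activation radius")
  cfg <- as.list(environment())
  # partial sub-lists are merged over the defaults
  for (nm in c("task_design", "rest_params", "ndes_distance",
               "des_counts", "voxel_size_mm"))
    cfg[[nm]] <- utils::modifyList(eval(formals(phantom_config)[[nm]]),
                                   cfg[[nm]])
  class(cfg) <- "phantom_config"
  cfg
}

subject_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + 104729 * index) %% 2147483647)
}

ellipsoid_rho <- function(xyz, semi) {
  sqrt((xyz[, 1] / semi[1])^2 + (xyz[, 2] / semi[2])^2 +
         (xyz[, 3] / semi[3])^2)
}

phantom_semi_axes <- function(cfg) cfg$fov_mm / 2 - c(4, 4, 3)

phantom_masks_on_grid <- function(cfg, grid) {
  d <- grid_dim3(grid)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  xyz <- voxel_to_world(grid, idx)
  semi <- phantom_semi_axes(cfg)
  rho <- ellipsoid_rho(xyz, semi)
  brain <- rho <= 1
  gm <- rho >= 0.70 & rho <= 1
  if (!is.null(cfg$lesion)) {
    inles <- sqrt(rowSums((xyz - matrix(cfg$lesion$center, nrow(xyz), 3,
                                        byrow = TRUE))^2)) <=
      cfg$lesion$radius_mm
    brain <- brain & !inles
    gm <- gm & !inles
  }
  blob_union <- function(ctrs, check = FALSE) {
    ctrs <- as.matrix(ctrs)
    hit <- rep(FALSE, nrow(xyz))
    for (r in seq_len(nrow(ctrs))) {
      if (check) {
        fv <- world_to_voxel(grid, matrix(ctrs[r, ], 1))
        if (any(fv < 0.5) || any(fv > d + 0.5))
          stop(sprintf(
            "activation center (%.1f, %.1f, %.1f) mm outside grid",
            ctrs[r, 1], ctrs[r, 2], ctrs[r, 3]))
      }
      hit <- hit | sqrt(rowSums((xyz - matrix(ctrs[r, ], nrow(xyz), 3,
                                              byrow = TRUE))^2)) <=
        cfg$activation_radius_mm
    }
    hit & gm
  }
  truth <- lapply(cfg$activation_centers, blob_union, check = TRUE)
  secondary <- lapply(cfg$activation_centers, function(ctrs)
    blob_union(sweep(as.matrix(ctrs), 2, cfg$secondary_offset_mm, "+")))
  seeds <- lapply(cfg$activation_centers, function(ctrs) {
    ctrs <- as.matrix(ctrs)
    hit <- rep(FALSE, nrow(xyz))
    for (r in seq_len(nrow(ctrs))) {
      dd <- sqrt(rowSums((xyz - matrix(ctrs[r, ], nrow(xyz), 3,
                                       byrow = TRUE))^2))
      hit <- hit | dd <= max(4, max(voxel_sizes(grid)) * 0.75)
      hit[which.min(dd)] <- TRUE   # seed never empty on coarse grids
    }
    hit
  })
  as_vol <- function(v) volume(array(as.numeric(v), dim = d), grid$affine)
  list(brain = as_vol(brain), gm = as_vol(gm),
       truth = lapply(truth, as_vol),
       secondary = lapply(secondary, as_vol),
       seeds = lapply(seeds, as_vol))
}

band_limited_signal <- function(n, TR, band, ar1 = 0) {
  x <- stats::rnorm(n)
  y <- temporal_filter(matrix(x, ncol = 1), "bandpass", TR = TR, band = band)
  y <- as.vector(y)
  s <- stats::sd(y)
  if (s == 0) stop("degenerate band-limited signal")
  y / s
}

ar1_noise <- function(n, nvox, sd, ar1) {
  # voxel x time orientation
  w <- matrix(stats::rnorm(n * nvox, sd = sd), nvox, n)
  if (ar1 != 0) {
    for (t in 2:n) w[, t] <- ar1 * w[, t - 1] + w[, t]
    w <- w * sqrt(1 - ar1^2)  # keep marginal sd comparable
  }
  w
}

# assemble a full-grid 4D series from a brain-voxel submatrix (voxels
# outside the brain stay at the constant baseline; no noise is simulated
# there, as nothing downstream uses it)
series_from_brain <- function(V, sel, d3, n, baseline, affine) {
  M <- matrix(baseline, prod(d3), n)
  M[sel, ] <- V
  volume(array(M, dim = c(d3, n)), affine)
}

random_walk_motion <- function(n) {
  cbind(matrix(cumsum(stats::rnorm(3 * n, sd = 0.02)), n, 3),
        matrix(cumsum(stats::rnorm(3 * n, sd = 2e-4)), n, 3))
}

#' Mono-exponential multi-echo signal model
#'
#' `S(TE_e, t) = S0(t) * exp(-TE_e * R2*(t))` evaluated voxelwise: neuronal
#' BOLD fluctuations enter through `R2*(t)` (TE-dependent), artifactual
#' fluctuations through `S0(t)` (TE-independent).
#'
#' @param s0 baseline signal: numeric vector over time, or array whose
#'   last dimension is time.
#' @param r2star relaxation rate in 1/ms, same shape as `s0`.
#' @param echo_times_ms positive echo times in ms.
#' @return List of per-echo arrays shaped like `s0`.
#' @export
simulate_multiecho_series <- function(s0, r2star, echo_times_ms) {
  if (length(echo_times_ms) < 1L) stop("at least one echo time required")
  if (any(echo_times_ms <= 0)) stop("echo times must be positive")
  if (!identical(dim(s0), dim(r2star)) || length(s0) != length(r2star))
    stop("s0 and r2star must have the same shape")
  lapply(echo_times_ms, function(te) s0 * exp(-te * r2star))
}

#' Sample synthetic DES coordinates around an activation truth
#'
#' Positive (pDES) sites are placed within `margin_mm` of the truth map;
#' negative (nDES) sites at distances drawn from a lognormal distribution
#' (median `median_mm`), inside the brain and at least `margin_mm` beyond
#' the truth.  Placement uses the brute-force distance-to-truth of every
#' brain voxel, so the realized distances match the draws to grid
#' resolution.
#'
#' @param truth_map binary `volume` of the activation truth (nonempty).
#' @param brain_mask binary `volume` on the same grid.
#' @param n_pos,n_neg numbers of positive/negative sites.
#' @param ndes_dist list `median_mm`, `sdlog`.
#' @param margin_mm class-separating margin in mm (default 5).
#' @param max_tries placement retries per site before erroring.
#' @return data.frame with `response`, `x_mm`, `y_mm`, `z_mm`,
#'   `truth_distance_mm` (generator-side bookkeeping).
#' @export
sample_des_points <- function(truth_map, brain_mask, n_pos, n_neg,
                              ndes_dist = list(median_mm = 12, sdlog = 0.6),
                              margin_mm = 5, max_tries = 200) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  tarr <- truth_map$data > 0
  if (!any(tarr)) stop("truth map is empty")
  stop_if_grid_mismatch(truth_map, brain_mask, "truth and brain mask")
  # only surface voxels of the truth set matter for outside distances
  surf <- boundary_voxels(tarr)
  tcoords <- voxel_to_world(truth_map, which(surf, arr.ind = TRUE))
  dist_to_truth <- function(pts) {
    apply(pts, 1, function(p) sqrt(min(colSums((t(tcoords) - p)^2))))
  }
  bsel <- which(brain_mask$data > 0)
  # candidate placement sites: a capped subsample of brain voxels keeps the
  # distance-map cost bounded; realized distances are recomputed exactly
  if (length(bsel) > 40000L)
    bsel <- sort(sample(bsel, 40000L))
  bidx <- arrayInd(bsel, grid_dim3(brain_mask))
  bcoords <- voxel_to_world(brain_mask, bidx)
  d2 <- rep(Inf, nrow(bcoords))
  for (r in seq_len(nrow(tcoords))) {
    d2 <- pmin(d2, (bcoords[, 1] - tcoords[r, 1])^2 +
                 (bcoords[, 2] - tcoords[r, 2])^2 +
                 (bcoords[, 3] - tcoords[r, 3])^2)
  }
  dbrain <- sqrt(d2)
  dbrain[tarr[bsel] > 0] <- 0
  half_vox <- max(voxel_sizes(brain_mask)) / 2
  place_at <- function(target, min_ok, max_ok, jitter) {
    for (tr in seq_len(max_tries)) {
      tgt <- target()
      if (tgt < min_ok - 1e-9 || tgt > max_ok + 1e-9) next
      cand <- which(abs(dbrain - tgt) <= half_vox)
      if (length(cand) == 0L) next
      pt <- bcoords[cand[sample.int(length(cand), 1)], ]
      if (jitter > 0) pt <- pt + stats::runif(3, -jitter, jitter)
      dd <- dist_to_truth(matrix(pt, 1))
      if (dd >= min_ok - 1e-9 && dd <= max_ok + 1e-9)
        return(c(pt, dd))
    }
    NULL
  }
  rows <- list()
  for (i in seq_len(n_pos)) {
    hit <- if (margin_mm <= 0) {
      tc <- positive_voxel_coords(truth_map)
      p <- tc[sample.int(nrow(tc), 1), ]
      c(p, 0)
    } else {
      place_at(function() stats::runif(1, 0, margin_mm), 0, margin_mm,
               jitter = 0.3)
    }
    if (is.null(hit)) stop("could not place a pDES point inside the brain")
    rows[[length(rows) + 1L]] <-
      data.frame(response = "pDES", x_mm = hit[1], y_mm = hit[2],
                 z_mm = hit[3], truth_distance_mm = hit[4])
  }
  meanlog <- log(ndes_dist$median_mm)
  for (i in seq_len(n_neg)) {
    hit <- place_at(function() stats::rlnorm(1, meanlog, ndes_dist$sdlog),
                    margin_mm, Inf, jitter = 0.3)
    if (is.null(hit))
      stop("could not place an nDES point at the requested distance inside the brain")
    rows[[length(rows) + 1L]] <-
      data.frame(response = "nDES", x_mm = hit[1], y_mm = hit[2],
                 z_mm = hit[3], truth_distance_mm = hit[4])
  }
  if (length(rows) == 0L)
    return(data.frame(response = character(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      truth_distance_mm = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

boundary_voxels <- function(mask) {
  d <- dim(mask)
  inner <- mask
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, dim = d)
    src <- dst <- lapply(d, seq_len)
    n <- d[ax]
    if (by == 1) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  core <- mask
  for (ax in 1:3) for (by in c(1, -1)) {
    sh <- shift_and(mask, ax, by)
    core <- core & sh
  }
  mask & !core
}

phantom_method_grid <- function(cfg, method) {
  vs <- cfg$voxel_size_mm[[method]]
  make_grid(ceiling(cfg$fov_mm / vs), vs)
}

subject_functions <- function(cfg, index) {
  f <- intersect(cfg$functions, "hands")
  if ("feet" %in% cfg$functions && index <= cfg$feet_subjects)
    f <- c(f, "feet")
  if (length(f) == 0L) f <- cfg$functions
  f
}

#' Generate one phantom subject
#'
#' Builds the subject's anatomical 1 mm grid with brain and gray-matter
#' masks and per-function truth maps, the per-method 4D series (task block
#' design; single-echo rest; three-echo rest whose middle echo doubles as
#' the 3 mm single-echo scheme), motion parameters, and a DES coordinate
#' table.  All randomness comes from a subject-specific stream derived
#' from the master seed and the subject index, so subjects are
#' reproducible independently of each other.
#'
#' @param config a [phantom_config()].
#' @param index subject index in `1..n_subjects`.
#' @return Object of class `subject_phantom`: list with `subject_id`,
#'   `anat` (grids/masks/truth), `methods` (per-method series, TR, motion,
#'   seed and gray-matter masks), and `des` (coordinate table).
#' @export
make_subject_phantom <- function(config, index) {
  cfg <- config
  set.seed(subject_seed(cfg$seed, index))
  subject_id <- sprintf("PH%03d", index)
  funcs <- subject_functions(cfg, index)
  # subject- and scan-level BOLD response gains (session variability)
  subj_gain <- stats::rlnorm(1, 0, cfg$amplitude_sdlog_subject)
  scan_gain <- function() subj_gain *
    stats::rlnorm(1, 0, cfg$amplitude_sdlog_scan)

  anat_grid <- make_grid(cfg$fov_mm, c(1, 1, 1))
  anat <- phantom_masks_on_grid(cfg, anat_grid)

  methods <- list()
  # ---- task-based fMRI: one series per mapped function
  tgrid <- phantom_method_grid(cfg, "tbfMRI")
  tmasks <- phantom_masks_on_grid(cfg, tgrid)
  td <- cfg$task_design
  blocks <- data.frame(onset = (seq_len(td$n_block_pairs) * 2 - 1) *
                         td$block_s,
                       duration = td$block_s)
  reg <- build_task_regressor(blocks, td$TR, td$n_vols)
  reg_n <- (reg - mean(reg)) / stats::sd(reg)
  selt <- which(tmasks$brain$data > 0)
  task_series <- list()
  task_motion <- list()
  task_weight <- function(masks, f)
    pmax(masks$truth[[f]]$data, cfg$secondary_gain *
           masks$secondary[[f]]$data)
  for (f in funcs) {
    V <- cfg$s0 +
      ar1_noise(td$n_vols, length(selt), td$noise_sd, cfg$rest_params$ar1) +
      outer(task_weight(tmasks, f)[selt] * td$amplitude * scan_gain(),
            reg_n)
    task_series[[f]] <- series_from_brain(V, selt, grid_dim3(tgrid),
                                          td$n_vols, cfg$s0, tgrid$affine)
    task_motion[[f]] <- random_walk_motion(td$n_vols)
  }
  methods$tbfMRI <- list(grid = tgrid, series = task_series,
                         motion = task_motion, TR = td$TR,
                         regressor = reg, blocks = blocks,
                         gm = tmasks$gm, seeds = tmasks$seeds,
                         truth = tmasks$truth)

  rp <- cfg$rest_params
  latent <- list()  # per function, one network fluctuation per rest scan
  # ---- single-echo rest at 2 mm
  g2 <- phantom_method_grid(cfg, "sTE2mm")
  m2 <- phantom_masks_on_grid(cfg, g2)
  n2 <- rp$n_vols_sTE2
  lat2 <- lapply(funcs, function(f)
    band_limited_signal(n2, rp$TR_sTE2, rp$band_hz))
  names(lat2) <- funcs
  # resting-state networks: truth plus a surrounding cortical band at
  # reduced amplitude (connectivity maps are more widespread than task
  # activation)
  network_weights <- function(masks) {
    lapply(funcs, function(f) {
      core <- pmax(masks$truth[[f]]$data, cfg$secondary_gain *
                     masks$secondary[[f]]$data)
      both <- volume(array(as.numeric(core > 0), dim = dim(core)),
                     masks$truth[[f]]$affine)
      net <- dilate_mm(both, rp$network_extension_mm)$data > 0
      net <- net & masks$gm$data > 0
      pmax(core, rp$network_extension_gain * as.numeric(net))
    }) |> stats::setNames(funcs)
  }
  sel2 <- which(m2$brain$data > 0)
  gain2 <- scan_gain()
  nw2 <- network_weights(m2)
  V2 <- cfg$s0 + ar1_noise(n2, length(sel2), rp$noise_sd, rp$ar1)
  for (f in funcs)
    V2 <- V2 + outer(nw2[[f]][sel2] * rp$amplitude * gain2, lat2[[f]])
  methods$sTE2mm <- list(grid = g2,
                         series = series_from_brain(V2, sel2,
                                                    grid_dim3(g2), n2,
                                                    cfg$s0, g2$affine),
                         motion = random_walk_motion(n2), TR = rp$TR_sTE2,
                         gm = m2$gm, seeds = m2$seeds, truth = m2$truth)

  # ---- multi-echo rest at 3 mm (middle echo reused as the 3 mm
  # single-echo scheme)
  g3 <- phantom_method_grid(cfg, "mTE")
  m3 <- phantom_masks_on_grid(cfg, g3)
  n3 <- rp$n_vols_mTE
  lat3 <- lapply(funcs, function(f)
    band_limited_signal(n3, rp$TR_mTE, rp$band_hz))
  names(lat3) <- funcs
  sel3 <- which(m3$brain$data > 0)
  frac <- rp$amplitude * scan_gain() / cfg$s0
  te_mid <- cfg$echo_times_ms[ceiling(length(cfg$echo_times_ms) / 2)]
  nw3 <- network_weights(m3)
  dr2 <- matrix(0, length(sel3), n3)
  for (f in funcs)
    dr2 <- dr2 - (frac / te_mid) * outer(nw3[[f]][sel3], lat3[[f]])
  r2star <- 1 / cfg$t2star_ms + dr2
  s0_t <- cfg$s0 * (1 + rp$s0_artifact_sd *
                      band_limited_signal(n3, rp$TR_mTE, c(0.01, 0.05)))
  s0_mat <- matrix(s0_t, length(sel3), n3, byrow = TRUE)
  echoes <- simulate_multiecho_series(s0_mat, r2star, cfg$echo_times_ms)
  echo_vols <- vector("list", length(echoes))
  for (e in seq_along(echoes)) {
    te <- cfg$echo_times_ms[e]
    noise <- ar1_noise(n3, length(sel3),
                       rp$noise_sd * exp(-te / cfg$t2star_ms), rp$ar1)
    echo_vols[[e]] <- series_from_brain(echoes[[e]] + noise, sel3,
                                        grid_dim3(g3), n3,
                                        cfg$s0 * exp(-te / cfg$t2star_ms),
                                        g3$affine)
  }
  mot3 <- random_walk_motion(n3)
  methods$mTE <- list(grid = g3, echoes = echo_vols,
                      echo_times_ms = cfg$echo_times_ms,
                      motion = mot3, TR = rp$TR_mTE,
                      gm = m3$gm, seeds = m3$seeds, truth = m3$truth)
  methods$sTE3mm <- list(grid = g3,
                         series = echo_vols[[ceiling(length(echo_vols) / 2)]],
                         motion = mot3, TR = rp$TR_mTE,
                         gm = m3$gm, seeds = m3$seeds, truth = m3$truth)

  # ---- DES coordinates: function-specific positives, global negatives
  n_pos <- sample(cfg$des_counts$n_pos, 1)
  n_neg <- sample(cfg$des_counts$n_neg, 1)
  truth_union <- anat$truth[[funcs[1]]]
  if (length(funcs) > 1) {
    u <- Reduce(`|`, lapply(anat$truth[funcs], function(v) v$data > 0))
    truth_union <- volume(array(as.numeric(u), dim = dim(u)),
                          anat_grid$affine)
  }
  des <- list()
  if (n_pos > 0) {
    per_f <- tabulate(sample.int(length(funcs), n_pos, replace = TRUE),
                      nbins = length(funcs))
    for (fi in seq_along(funcs)) {
      if (per_f[fi] == 0) next
      pts <- sample_des_points(anat$truth[[funcs[fi]]], anat$brain,
                               n_pos = per_f[fi], n_neg = 0,
                               ndes_dist = cfg$ndes_distance,
                               margin_mm = cfg$pdes_margin_mm)
      pts$func <- funcs[fi]
      des[[length(des) + 1L]] <- pts
    }
  }
  if (n_neg > 0) {
    pts <- sample_des_points(truth_union, anat$brain, n_pos = 0,
                             n_neg = n_neg, ndes_dist = cfg$ndes_distance,
                             margin_mm = cfg$ndes_margin_mm)
    pts$func <- NA_character_   # negatives count against every function
    des[[length(des) + 1L]] <- pts
  }
  des <- if (length(des) > 0) do.call(rbind, des) else
    data.frame(response = character(0), x_mm = numeric(0),
               y_mm = numeric(0), z_mm = numeric(0),
               truth_distance_mm = numeric(0), func = character(0))
  des <- cbind(subject = subject_id, des)
  rownames(des) <- NULL

  structure(list(subject_id = subject_id, index = index, functions = funcs,
                 anat = c(list(grid = anat_grid), anat),
                 methods = methods, des = des, config = cfg),
            class = "subject_phantom")
}

#' @export
print.subject_phantom <- function(x, ...) {
  cat(sprintf("<subject_phantom> %s: functions %s; %d pDES, %d nDES\n",
              x$subject_id, paste(x$functions, collapse = "/"),
              sum(x$des$response == "pDES"), sum(x$des$response == "nDES")))
  invisible(x)
}

#' Generative parameters of the two-part distance model
#'
#' Defaults describe a cohort resembling the validation study's regime:
#' 200 subjects, one row per method x DES response, a strong DES-response
#' effect in both parts, no method effects, and moderately correlated
#' subject-level random intercepts.
#'
#' @param beta_a logit-scale coefficients `(intercept, pDES, sTE2mm,
#'   sTE3mm, mTE)` for the overlap probability.
#' @param beta_b log-mm coefficients, same order, for positive distances.
#' @param sigma_u,sigma_v random-intercept SDs of the two parts.
#' @param rho their correlation in `[-1, 1]`.
#' @param sigma_eps residual SD of log-distance.
#' @param n_subjects number of subjects.
#' @param reps_per_cell repetitions of each method x response cell per
#'   subject (scalar or range to sample from).
#' @param seed RNG seed used by [simulate_two_part_records()].
#' @return Object of class `two_part_sim_params`.
#' @export
two_part_sim_params <- function(beta_a = c(0.5, 1.5, 0, 0, 0),
                                beta_b = c(2.3, -0.8, 0, 0, 0),
                                sigma_u = 1, sigma_v = 0.5, rho = 0.5,
                                sigma_eps = 0.6, n_subjects = 200,
                                reps_per_cell = 1, seed = 1) {
  if (sigma_u < 0 || sigma_v < 0 || sigma_eps < 0)
    stop("variance components must be nonnegative")
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  S <- matrix(c(sigma_u^2, rho * sigma_u * sigma_v,
                rho * sigma_u * sigma_v, sigma_v^2), 2)
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop("random-effect covariance is not positive semidefinite")
  structure(list(beta_a = beta_a, beta_b = beta_b, sigma_u = sigma_u,
                 sigma_v = sigma_v, rho = rho, sigma_eps = sigma_eps,
                 n_subjects = n_subjects, reps_per_cell = reps_per_cell,
                 seed = seed), class = "two_part_sim_params")
}

#' Simulate semicontinuous distance records from the two-part model
#'
#' Per subject, `(u_i, v_i)` is drawn from the bivariate normal; each row
#' is zero with probability `expit(x' beta_A + u_i)` and otherwise
#' `y = exp(x' beta_B + v_i + eps)`.  Rows carry subject, DES response and
#' method covariates in the same coding as [fit_two_part()].
#'
#' @param params a [two_part_sim_params()].
#' @return data.frame with `subject`, `response`, `method`, `y`, `z`.
#' @export
simulate_two_part_records <- function(params) {
  p <- params
  set.seed(p$seed)
  methods <- c("tbfMRI", "sTE2mm", "sTE3mm", "mTE")
  responses <- c("nDES", "pDES")
  Sig <- matrix(c(p$sigma_u^2, p$rho * p$sigma_u * p$sigma_v,
                  p$rho * p$sigma_u * p$sigma_v, p$sigma_v^2), 2)
  ch <- chol_psd(Sig)
  re <- matrix(stats::rnorm(2 * p$n_subjects), p$n_subjects, 2) %*% ch
  rows <- vector("list", p$n_subjects)
  for (i in seq_len(p$n_subjects)) {
    reps <- if (length(p$reps_per_cell) > 1)
      sample(p$reps_per_cell, 1) else p$reps_per_cell
    cells <- expand.grid(response = responses, method = methods,
                         rep = seq_len(reps), stringsAsFactors = FALSE)
    x <- cbind(1, as.numeric(cells$response == "pDES"),
               as.numeric(cells$method == "sTE2mm"),
               as.numeric(cells$method == "sTE3mm"),
               as.numeric(cells$method == "mTE"))
    pz <- stats::plogis(as.vector(x %*% p$beta_a) + re[i, 1])
    z <- stats::rbinom(nrow(x), 1, pz)
    y <- ifelse(z == 1, 0,
                exp(as.vector(x %*% p$beta_b) + re[i, 2] +
                      stats::rnorm(nrow(x), 0, p$sigma_eps)))
    rows[[i]] <- data.frame(subject = sprintf("S%03d", i),
                            response = cells$response,
                            method = cells$method, y = y, z = z)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
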