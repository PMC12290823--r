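test_that("cutoff thresholding produces consistent semicontinuous data", {
  rr <- data.frame(subject = "S1", response = "nDES", method = "tbfMRI",
                   distance_mm = c(0, 3, 7, 12))
  out <- threshold_semicontinuous(rr, 4)
  expect_equal(out$y, c(0, 0, 7, 12))
  expect_equal(out$z, as.integer(out$y == 0))
  out1 <- threshold_semicontinuous(rr, 1)
  expect_equal(out1$y, c(0, 3, 7, 12))
  outx <- threshold_semicontinuous(rr, 4, rule = "exact_zero")
  expect_equal(outx$y, c(0, 3, 7, 12))
  expect_error(threshold_semicontinuous(rr, 0), "positive integer")
  # all-zero outcomes make the lognormal part unfittable
  allz <- threshold_semicontinuous(rr, 20)
  allz$subject <- c("S1", "S1", "S2", "S2")
  expect_error(fit_two_part(allz), "no positive part")
})

test_that("marginal likelihood: closed form at zero variances and dense-grid
          agreement", {
  d <- data.frame(subject = rep(c("a", "b"), each = 4),
                  y = c(0, 2, 0, 6, 0, 0, 3, 9))
  par0 <- list(beta_a = 0.3, beta_b = 1.2, sigma_u = 0, sigma_v = 0,
               rho = 0, sigma_eps = 0.7)
  ll <- two_part_loglik(par0, d, quad_order = 15)
  p <- stats::plogis(0.3)
  closed <- sum(ifelse(d$y == 0, log(p), log(1 - p))) +
    sum(stats::dlnorm(d$y[d$y > 0], 1.2, 0.7, log = TRUE))
  expect_equal(ll, closed, tolerance = 1e-10)
  # tiny dataset vs 2-D trapezoid oracle on a +/- 8 SD grid
  dd <- data.frame(subject = rep(c("s1", "s2"), each = 3),
                   y = c(0, 3, 5, 0, 0, 7))
  par <- list(beta_a = 0.2, beta_b = 1.5, sigma_u = 0.8, sigma_v = 0.5,
              rho = 0.4, sigma_eps = 0.6)
  ll_gh <- two_part_loglik(par, dd, quad_order = 31)
  ll_dense <- dense_two_part_loglik(par, dd)
  expect_lt(abs(ll_gh - ll_dense), 1e-6)
  # quadrature convergence
  expect_lt(abs(two_part_loglik(par, dd, 11) - ll_gh), 1e-4)
  expect_error(two_part_loglik(modifyList(par, list(rho = 2)), dd), "invalid")
})

test_that("degenerate MLEs match the closed forms", {
  d <- data.frame(subject = rep(c("a", "b"), each = 5),
                  y = c(0, 0, 0, exp(1), 0, 0, exp(2), exp(3), 0, exp(2)))
  f <- fit_two_part(d, random_effects = FALSE, nstarts = 1)
  expect_equal(unname(f$beta_a[1]), stats::qlogis(0.6), tolerance = 1e-5)
  expect_equal(unname(f$beta_b[1]), 2, tolerance = 1e-5)
  expect_equal(f$sigma_eps^2, mean((c(1, 2, 3, 2) - 2)^2), tolerance = 1e-4)
})

test_that("the mixed fit recovers generative parameters within 3 SE", {
  p <- two_part_sim_params()   # 200 subjects, seed 1
  dat <- simulate_two_part_records(p)
  f <- fit_two_part(dat, quad_order = 9, nstarts = 1)
  truth <- c(p$beta_a, p$beta_b, p$sigma_u, p$sigma_v, p$rho, p$sigma_eps)
  est <- coef(f)
  se <- sqrt(diag(vcov(f)))
  expect_true(all(abs(est - truth) <= 3 * se))
  expect_s3_class(f, "twopart")
  expect_equal(f$df, 198)
  # methods on the fit
  expect_equal(length(coef(f)), 14)
  expect_true(is.matrix(vcov(f)))
  expect_lt(abs(as.numeric(logLik(f)) - f$loglik), 1e-12)
  sm <- summary(f)
  expect_true(all(c("Estimate", "Std. Error") %in%
                    colnames(sm$coefficients)))
  pr <- predict(f, type = "prob_zero")
  expect_true(all(pr > 0 & pr < 1))
  sim <- simulate(f, nsim = 1, seed = 3)
  expect_equal(nrow(sim), nrow(dat))
})

test_that("generator: zero-inflation level and correlated random effects", {
  # no random effects, intercept-only zero probability 0.3
  p0 <- two_part_sim_params(beta_a = c(stats::qlogis(0.3), 0, 0, 0, 0),
                            sigma_u = 0, sigma_v = 0, rho = 0,
                            n_subjects = 1500, seed = 5)
  d0 <- simulate_two_part_records(p0)
  n <- nrow(d0)
  phat <- mean(d0$z)
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # degenerate positive part
  pB <- two_part_sim_params(beta_b = c(log(10), 0, 0, 0, 0),
                            sigma_v = 1e-12, sigma_eps = 1e-12,
                            n_subjects = 30, seed = 6)
  dB <- simulate_two_part_records(pB)
  expect_true(all(abs(dB$y[dB$y > 0] - 10) < 1e-6))
  # strong rho couples subject-level zero rate and positive magnitude:
  # both parts share high-positive-association random intercepts
  pr <- two_part_sim_params(rho = 0.9, sigma_u = 2, sigma_v = 2,
                            n_subjects = 200, seed = 7)
  dr <- simulate_two_part_records(pr)
  zf <- tapply(dr$z, dr$subject, mean)
  ly <- tapply(ifelse(dr$y > 0, log(dr$y), NA), dr$subject, mean,
               na.rm = TRUE)
  keep <- is.finite(ly)
  expect_gt(stats::cor(zf[keep], ly[keep]), 0)
})

test_that("step-up FWE adjustments: exact cases and p.adjust agreement", {
  expect_equal(adaptive_hochberg(0.01, "hochberg"), 0.01)
  expect_equal(adaptive_hochberg(rep(1, 5), "hochberg"), rep(1, 5))
  expect_equal(adaptive_hochberg(c(0.01, 0.04), "hochberg"), c(0.02, 0.04))
  set.seed(101)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    expect_equal(adaptive_hochberg(p, "hochberg"),
                 stats::p.adjust(p, "hochberg"), tolerance = 1e-12)
    adp <- adaptive_hochberg(p, "adaptive")
    expect_true(all(adp <= adaptive_hochberg(p, "hochberg") + 1e-12))
    expect_true(all(adp >= p - 1e-12))
    expect_true(all(adp <= 1))
  }
  expect_error(adaptive_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("post-hoc method contrasts reproduce coefficient differences", {
  p <- two_part_sim_params(n_subjects = 80, seed = 8)
  dat <- simulate_two_part_records(p)
  f <- fit_two_part(dat, quad_order = 7, nstarts = 1)
  ct <- posthoc_contrasts(f)
  expect_equal(nrow(ct), 10)
  expect_true(all(ct$p_adj >= ct$p - 1e-12))
  expect_true(all(ct$p_adj <= 1))
  # tbfMRI vs sTE2mm in part A is minus the sTE2mm dummy
  est <- ct$estimate[ct$part == "A" &
                       ct$label == "tbfMRI v sTE-rsfMRI 2 mm"]
  expect_equal(est, -unname(coef(f)["A:methodsTE2mm"]), tolerance = 1e-10)
  # sTE2mm vs sTE3mm is the dummy difference
  est2 <- ct$estimate[ct$part == "B" & ct$label == "sTE-rsfMRI 2 mm v 3 mm"]
  expect_equal(est2, unname(coef(f)["B:methodsTE2mm"] -
                              coef(f)["B:methodsTE3mm"]), tolerance = 1e-10)
})

test_that("adjusted method contrasts control the family-wise error under the
          null", {
  reps <- 40
  err <- 0L
  fams <- 0L
  for (r in seq_len(reps)) {
    p <- two_part_sim_params(n_subjects = 60, seed = 1000 + r)
    dat <- simulate_two_part_records(p)   # method effects are all zero
    f <- try(fit_two_part(dat, quad_order = 5, nstarts = 1), silent = TRUE)
    if (inherits(f, "try-error")) next
    ct <- posthoc_contrasts(f)
    for (part in c("A", "B")) {
      fams <- fams + 1L
      err <- err + as.integer(any(ct$p_adj[ct$part == part] < 0.05))
    }
  }
  expect_gt(fams, 60)
  expect_lte(err / fams, 0.075)
})
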