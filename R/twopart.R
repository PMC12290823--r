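#' Threshold distance records into semicontinuous two-part data
#'
#' At an agreement cutoff, records with distance below the cutoff count as
#' overlap (`y = 0`); the rest keep their integer distance.  The zero
#' indicator `z = 1{y == 0}` defines the logistic part of the two-part
#' model.  The alternative rule `"exact_zero"` zeroes only true-zero
#' distances.
#'
#' @param records data.frame with `subject`, `response`, `method`,
#'   `distance_mm` (and optionally `func`).
#' @param cutoff positive integer cutoff in mm.
#' @param rule `"below_cutoff"` (default) or `"exact_zero"`.
#' @return data.frame with `subject`, `response`, `method`, `y`, `z`.
#' @export
threshold_semicontinuous <- function(records, cutoff,
                                     rule = c("below_cutoff", "exact_zero")) {
  rule <- match.arg(rule)
  if (cutoff <= 0 || cutoff != round(cutoff))
    stop("cutoff must be a positive integer")
  records <- records[!is.na(records$distance_mm), , drop = FALSE]
  y <- records$distance_mm
  zero <- if (rule == "below_cutoff") y < cutoff else y == 0
  out <- data.frame(subject = records$subject,
                    response = records$response,
                    method = records$method,
                    y = ifelse(zero, 0, y))
  out$z <- as.integer(out$y == 0)
  out
}

# Design matrix: intercept + pDES indicator + method dummies vs tbfMRI.
# Columns present in the data decide the covariates; single-level factors
# contribute nothing.
twopart_design <- function(data) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(data$response) && length(unique(data$response)) > 1L) {
    if (!all(data$response %in% c("pDES", "nDES")))
      stop("response must be 'pDES' or 'nDES'")
    X <- cbind(X, responsepDES = as.numeric(data$response == "pDES"))
  }
  if (!is.null(data$method)) {
    lev <- intersect(c("tbfMRI", "sTE2mm", "sTE3mm", "mTE"),
                     unique(as.character(data$method)))
    if (length(lev) == 0L) lev <- sort(unique(as.character(data$method)))
    if (length(lev) > 1L) {
      for (l in lev[-1])
        X <- cbind(X, stats::setNames(
          matrix(as.numeric(data$method == l)), NULL))
      colnames(X)[(ncol(X) - length(lev) + 2):ncol(X)] <-
        paste0("method", lev[-1])
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("two-part design matrix is rank deficient")
  X
}

twopart_prepare <- function(data) {
  if (is.null(data$subject) || is.null(data$y))
    stop("data must have 'subject' and 'y' columns")
  if (any(data$y < 0)) stop("distances must be nonnegative")
  X <- twopart_design(data)
  z <- as.integer(data$y == 0)
  subj <- factor(data$subject)
  posrows <- which(z == 0L)
  list(X = X, z = z, subject = subj, m = nlevels(subj),
       posrows = posrows, logy = log(data$y[posrows]),
       pos_subj = subj[posrows])
}

log_sum_exp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

twopart_loglik_prep <- function(prep, beta_a, beta_b, sigma_u, sigma_v, rho,
                                sigma_eps, gh) {
  X <- prep$X
  etaA <- as.vector(X %*% beta_a)
  a <- gh$x; w <- gh$w
  K <- length(a)
  u <- sqrt(2) * sigma_u * a
  # n x K Bernoulli log-likelihood contributions
  EA <- outer(etaA, u, "+")
  LA <- matrix(0, nrow(X), K)
  z1 <- prep$z == 1L
  LA[z1, ] <- -log1p(exp(-EA[z1, , drop = FALSE]))
  LA[!z1, ] <- -log1p(exp(EA[!z1, , drop = FALSE]))
  SA <- rowsum(LA, as.integer(prep$subject))          # m x K, level order
  # positive-part sufficient statistics per subject
  m <- prep$m
  n1 <- S1 <- S2 <- Cst <- numeric(m)
  if (length(prep$posrows) > 0L) {
    if (sigma_eps <= 0) return(-Inf)
    r <- prep$logy - as.vector(X[prep$posrows, , drop = FALSE] %*% beta_b)
    gi <- as.integer(prep$pos_subj)
    n1 <- tabulate(gi, nbins = m)
    sums <- rowsum(cbind(r, r^2, prep$logy), gi)
    at <- as.integer(rownames(sums))
    S1[at] <- sums[, 1]
    S2[at] <- sums[, 2]
    sumlogy <- numeric(m)
    sumlogy[at] <- sums[, 3]
    Cst <- -sumlogy - n1 * log(sigma_eps * sqrt(2 * pi))
  }
  kk <- rep(seq_len(K), times = K)
  ll <- rep(seq_len(K), each = K)
  vv <- sqrt(2) * sigma_v * (rho * a[kk] + sqrt(1 - rho^2) * a[ll])
  logw <- log(w[kk]) + log(w[ll]) - log(pi)
  base <- Cst - S2 / (2 * max(sigma_eps, .Machine$double.xmin)^2)
  TT <- SA[, kk, drop = FALSE] +
    outer(S1, vv) / max(sigma_eps, .Machine$double.xmin)^2 -
    outer(n1, vv^2) / (2 * max(sigma_eps, .Machine$double.xmin)^2)
  TT <- sweep(TT, 2, logw, "+") + base
  sum(log_sum_exp_rows(TT))
}

#' Marginal log-likelihood of the two-part mixed model
#'
#' Per subject i with rows j, the two-part model posits
#' `logit P(y_ij = 0) = x_ij' beta_A + u_i` and, for positive outcomes,
#' `log y_ij ~ N(x_ij' beta_B + v_i, sigma_eps^2)`, with `(u_i, v_i)`
#' bivariate normal with SDs `sigma_u`, `sigma_v` and correlation `rho`.
#' The random effects are integrated out by two-dimensional Gauss-Hermite
#' quadrature (the lognormal part collapses to per-subject sufficient
#' statistics, so cost is linear in the data).
#'
#' @param params list with `beta_a`, `beta_b`, `sigma_u`, `sigma_v`, `rho`,
#'   `sigma_eps`.
#' @param data data.frame as for [fit_two_part()].
#' @param quad_order Gauss-Hermite order per dimension (default 15).
#' @return The marginal log-likelihood (scalar; `-Inf` if not finite at
#'   these parameters).
#' @export
two_part_loglik <- function(params, data, quad_order = 15) {
  if (quad_order < 1) stop("quad_order must be >= 1")
  if (params$sigma_u < 0 || params$sigma_v < 0 || abs(params$rho) > 1)
    stop("invalid variance parameters")
  prep <- twopart_prepare(data)
  gh <- pracma::gaussHermite(quad_order)
  ll <- twopart_loglik_prep(prep, params$beta_a, params$beta_b,
                            params$sigma_u, params$sigma_v, params$rho,
                            params$sigma_eps, gh)
  if (!is.finite(ll)) -Inf else ll
}

theta_to_params <- function(theta, p, random_effects) {
  theta <- unname(theta)
  beta_a <- theta[seq_len(p)]
  beta_b <- theta[p + seq_len(p)]
  if (random_effects) {
    list(beta_a = beta_a, beta_b = beta_b,
         sigma_u = exp(theta[2 * p + 1]), sigma_v = exp(theta[2 * p + 2]),
         rho = tanh(theta[2 * p + 3]), sigma_eps = exp(theta[2 * p + 4]))
  } else {
    list(beta_a = beta_a, beta_b = beta_b, sigma_u = 0, sigma_v = 0,
         rho = 0, sigma_eps = exp(theta[2 * p + 1]))
  }
}

#' Fit the two-part logistic-lognormal mixed model
#'
#' Maximum marginal likelihood over `(beta_A, beta_B, log sigma_u,
#' log sigma_v, atanh rho, log sigma_eps)` by BFGS from part-wise starting
#' values (separate logistic and lognormal fits, small positive variance
#' components, zero correlation), with optional additional jittered starts
#' to guard against local optima.  Standard errors come from the inverse
#' observed Hessian, transformed to the natural scale; the default degrees
#' of freedom for Wald tests are `n_subjects - 2` (subjects minus the
#' number of random effects, the NLMIXED convention).
#'
#' @param data data.frame with columns `subject`, `y` (nonnegative,
#'   semicontinuous), and optionally `response` (`pDES`/`nDES`) and
#'   `method` (`tbfMRI`, `sTE2mm`, `sTE3mm`, `mTE`); see
#'   [threshold_semicontinuous()].
#' @param quad_order Gauss-Hermite order per dimension (default 15).
#' @param nstarts number of optimizer starts (default 3).
#' @param random_effects set `FALSE` to force `sigma_u = sigma_v = 0`
#'   (independent logistic + lognormal fits).
#' @param df degrees of freedom for Wald tests; default `n_subjects - 2`.
#' @param maxit BFGS iteration cap per start.
#' @return Object of class `twopart`.
#' @examples
#' dat <- simulate_two_part_records(two_part_sim_params(n_subjects = 40))
#' fit <- fit_two_part(dat, quad_order = 7, nstarts = 1)
#' summary(fit)
#' posthoc_contrasts(fit)
#' @export
fit_two_part <- function(data, quad_order = 15, nstarts = 3,
                         random_effects = TRUE, df = NULL, maxit = 400) {
  prep <- twopart_prepare(data)
  if (prep$m < 2) stop("need at least two subjects")
  if (all(prep$z == 1L)) stop("no positive part data: all outcomes are zero")
  if (all(prep$z == 0L)) stop("no zero outcomes: the logistic part is empty")
  p <- ncol(prep$X)
  gh <- pracma::gaussHermite(quad_order)

  suppressWarnings({
    g0 <- stats::glm.fit(prep$X, prep$z, family = stats::binomial())
    b0a <- g0$coefficients
    l0 <- stats::lm.fit(prep$X[prep$posrows, , drop = FALSE], prep$logy)
    b0b <- l0$coefficients
  })
  b0a[!is.finite(b0a)] <- 0
  b0b[!is.finite(b0b)] <- 0
  s_eps0 <- max(stats::sd(l0$residuals), 0.1)
  theta0 <- if (random_effects) {
    c(b0a, b0b, log(0.3), log(0.3), 0, log(s_eps0))
  } else {
    c(b0a, b0b, log(s_eps0))
  }

  negll <- function(theta) {
    par <- theta_to_params(theta, p, random_effects)
    ll <- twopart_loglik_prep(prep, par$beta_a, par$beta_b, par$sigma_u,
                              par$sigma_v, par$rho, par$sigma_eps, gh)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # deterministic jitters so repeated fits are identical
  jit <- function(k) 0.25 * sin(seq_along(theta0) * k + k)
  best <- NULL
  for (k in seq_len(nstarts)) {
    start <- if (k == 1) theta0 else theta0 + jit(k)
    opt <- stats::optim(start, negll, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$value >= 1e10)
    stop("two-part likelihood not finite at the optimum")
  theta <- best$par
  par <- theta_to_params(theta, p, random_effects)

  H <- stats::optimHess(theta, negll)
  vcov_theta <- tryCatch(solve(H), error = function(e) {
    warning("observed Hessian is singular; using pseudo-inverse")
    pinv_sym(H)
  })
  # delta method to the natural scale
  jac <- rep(1, length(theta))
  if (random_effects) {
    jac[2 * p + 1] <- par$sigma_u
    jac[2 * p + 2] <- par$sigma_v
    jac[2 * p + 3] <- 1 - par$rho^2
    jac[2 * p + 4] <- par$sigma_eps
  } else {
    jac[2 * p + 1] <- par$sigma_eps
  }
  vcov_nat <- vcov_theta * outer(jac, jac)
  cn <- colnames(prep$X)
  nm <- c(paste0("A:", cn), paste0("B:", cn),
          if (random_effects) c("sigma_u", "sigma_v", "rho", "sigma_eps")
          else "sigma_eps")
  dimnames(vcov_nat) <- list(nm, nm)
  est <- c(par$beta_a, par$beta_b,
           if (random_effects) c(par$sigma_u, par$sigma_v, par$rho,
                                 par$sigma_eps) else par$sigma_eps)
  names(est) <- nm

  structure(list(
    coefficients = est, beta_a = stats::setNames(par$beta_a, cn),
    beta_b = stats::setNames(par$beta_b, cn),
    sigma_u = par$sigma_u, sigma_v = par$sigma_v, rho = par$rho,
    sigma_eps = par$sigma_eps, vcov = vcov_nat, loglik = -best$value,
    df = if (is.null(df)) prep$m - 2L else df,
    n_subjects = prep$m, nobs = nrow(prep$X), n_zero = sum(prep$z),
    design_colnames = cn, random_effects = random_effects,
    quad_order = quad_order, convergence = best$convergence,
    data = data, call = match.call()), class = "twopart")
}

pinv_sym <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' @export
print.twopart <- function(x, ...) {
  cat("Two-part logistic-lognormal mixed model\n")
  cat(sprintf("  %d observations, %d subjects (%d zero outcomes)\n",
              x$nobs, x$n_subjects, x$n_zero))
  cat(sprintf("  logLik = %.3f, df = %d, quad order = %d\n",
              x$loglik, x$df, x$quad_order))
  cat("Part A (logit of overlap probability):\n")
  print(round(x$beta_a, 4))
  cat("Part B (log distance, positive part):\n")
  print(round(x$beta_b, 4))
  cat(sprintf("Random effects: sigma_u = %.3f, sigma_v = %.3f, rho = %.3f; sigma_eps = %.3f\n",
              x$sigma_u, x$sigma_v, x$rho, x$sigma_eps))
  invisible(x)
}

#' @export
coef.twopart <- function(object, ...) object$coefficients

#' @export
vcov.twopart <- function(object, ...) object$vcov

#' @export
logLik.twopart <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$nobs, class = "logLik")
}

#' @export
summary.twopart <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  tval <- object$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), object$df)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = tval, `Pr(>|t|)` = pval)
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.twopart"
  out
}

#' @export
print.summary.twopart <- function(x, ...) {
  print(x$fit)
  cat("\nWald tests (df =", x$fit$df, "):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Predictions from a two-part fit
#'
#' With random effects at zero (population center): `"prob_zero"` returns
#' `expit(x' beta_A)`, the overlap probability; `"mean_positive"` returns
#' `exp(x' beta_B + sigma_eps^2 / 2)`, the conditional mean distance given
#' non-overlap; `"linpred"` returns both linear predictors.
#'
#' @param object a `twopart` fit.
#' @param newdata data.frame with the covariate columns used in the fit
#'   (defaults to the training data).
#' @param type prediction type.
#' @param ... unused.
#' @return Numeric vector, or a two-column matrix for `"linpred"`.
#' @export
predict.twopart <- function(object, newdata = NULL,
                            type = c("prob_zero", "mean_positive", "linpred"),
                            ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  newdata$y <- if (is.null(newdata$y)) 1 else newdata$y
  newdata$subject <- if (is.null(newdata$subject)) "s" else newdata$subject
  X <- twopart_design(newdata)
  miss <- setdiff(object$design_colnames, colnames(X))
  if (length(miss) > 0)
    X <- cbind(X, matrix(0, nrow(X), length(miss),
                         dimnames = list(NULL, miss)))
  X <- X[, object$design_colnames, drop = FALSE]
  etaA <- as.vector(X %*% object$beta_a)
  etaB <- as.vector(X %*% object$beta_b)
  switch(type,
         prob_zero = stats::plogis(etaA),
         mean_positive = exp(etaB + object$sigma_eps^2 / 2),
         linpred = cbind(A = etaA, B = etaB))
}

#' Simulate from a fitted two-part model
#'
#' Draws new outcomes for the fit's covariate roster using the fitted
#' parameters (fresh subject random effects each replicate).
#'
#' @param object a `twopart` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return List of data.frames shaped like the training data.
#' @export
simulate.twopart <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dat <- object$data
  prep <- twopart_prepare(dat)
  X <- prep$X
  subj <- prep$subject
  m <- nlevels(subj)
  out <- vector("list", nsim)
  Sig <- matrix(c(object$sigma_u^2,
                  object$rho * object$sigma_u * object$sigma_v,
                  object$rho * object$sigma_u * object$sigma_v,
                  object$sigma_v^2), 2)
  ch <- chol_psd(Sig)
  for (r in seq_len(nsim)) {
    re <- matrix(stats::rnorm(2 * m), m, 2) %*% ch
    u <- re[, 1][as.integer(subj)]
    v <- re[, 2][as.integer(subj)]
    pz <- stats::plogis(as.vector(X %*% object$beta_a) + u)
    z <- stats::rbinom(nrow(X), 1, pz)
    y <- ifelse(z == 1, 0,
                exp(as.vector(X %*% object$beta_b) + v +
                      stats::rnorm(nrow(X), 0, object$sigma_eps)))
    d <- dat
    d$y <- y
    d$z <- z
    out[[r]] <- d
  }
  if (nsim == 1) out[[1]] else out
}

chol_psd <- function(S, tol = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values < -tol * max(abs(e$values), 1)))
    stop("random-effect covariance is not positive semidefinite")
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))  # upper-triangular-like factor
}

#' Hochberg and adaptive-Hochberg step-up adjusted p-values
#'
#' `"hochberg"` is the 1988 step-up procedure:
#' `p~_(i) = min(1, min_{j >= i} (m - j + 1) p_(j))` for ascending sorted
#' p-values.  `"adaptive"` replaces `m` in the multiplier by the
#' Hochberg-Benjamini estimate of the number of true null hypotheses,
#' clamped to `[1, m]` (multipliers never drop below 1).
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param variant `"adaptive"` (default) or `"hochberg"`.
#' @return Adjusted p-values in the original order.
#' @export
adaptive_hochberg <- function(pvals, variant = c("adaptive", "hochberg")) {
  variant <- match.arg(variant)
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals)))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  ps <- pvals[o]
  m_eff <- m
  if (variant == "adaptive" && m >= 2) {
    nj <- (m + 1 - seq_len(m)) / (1 - ps)
    nj[!is.finite(nj)] <- Inf
    jstar <- which(diff(nj) > 0)[1]
    m0 <- if (is.na(jstar)) nj[m] else nj[jstar + 1]
    m_eff <- min(m, max(1, ceiling(m0)))
  }
  mult <- pmax(m_eff - seq_len(m) + 1, 1)
  adj <- rev(cummin(rev(pmin(mult * ps, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Post-hoc pairwise method contrasts from a two-part fit
#'
#' The five pairwise contrasts among the four acquisition methods (task
#' fMRI as reference: tbfMRI vs sTE 2 mm, tbfMRI vs sTE 3 mm, tbfMRI vs
#' mTE, sTE 2 mm vs sTE 3 mm, sTE 3 mm vs mTE), computed separately for
#' the logistic (A) and lognormal (B) parts, with t statistics at the
#' fit's degrees of freedom and family-wise-error adjusted p-values within
#' each part (a family of five).
#'
#' @param fit a `twopart` fit whose design includes method dummies.
#' @param fwe `"adaptive"` (default) or `"hochberg"`.
#' @return data.frame with columns `label`, `part`, `estimate`, `se`, `t`,
#'   `df`, `p`, `p_adj`.
#' @export
posthoc_contrasts <- function(fit, fwe = c("adaptive", "hochberg")) {
  fwe <- match.arg(fwe)
  cn <- fit$design_colnames
  need <- c("methodsTE2mm", "methodsTE3mm", "methodmTE")
  if (!all(need %in% cn))
    stop("fit does not include the four-method design (missing method dummies)")
  pairs <- list(
    c("tbfMRI v sTE-rsfMRI 2 mm", "tbfMRI", "sTE2mm"),
    c("tbfMRI v sTE-rsfMRI 3 mm", "tbfMRI", "sTE3mm"),
    c("tbfMRI v mTE-rsfMRI", "tbfMRI", "mTE"),
    c("sTE-rsfMRI 2 mm v 3 mm", "sTE2mm", "sTE3mm"),
    c("sTE-rsfMRI 3 mm v mTE", "sTE3mm", "mTE"))
  dummy_of <- function(mth) if (mth == "tbfMRI") NULL else paste0("method", mth)
  rows <- list()
  for (part in c("A", "B")) {
    nm_all <- names(fit$coefficients)
    cvecs <- lapply(pairs, function(pr) {
      cv <- stats::setNames(numeric(length(nm_all)), nm_all)
      d1 <- dummy_of(pr[2]); d2 <- dummy_of(pr[3])
      if (!is.null(d1)) cv[paste0(part, ":", d1)] <- 1
      if (!is.null(d2)) cv[paste0(part, ":", d2)] <- cv[paste0(part, ":", d2)] - 1
      cv
    })
    est <- vapply(cvecs, function(cv) sum(cv * fit$coefficients), numeric(1))
    se <- vapply(cvecs, function(cv)
      sqrt(max(as.vector(t(cv) %*% fit$vcov %*% cv), 0)), numeric(1))
    tval <- ifelse(se > 0, est / se, 0)
    pval <- ifelse(se > 0, 2 * stats::pt(-abs(tval), fit$df), 1)
    rows[[part]] <- data.frame(
      label = vapply(pairs, `[`, character(1), 1), part = part,
      estimate = est, se = se, t = tval, df = fit$df, p = pval,
      p_adj = adaptive_hochberg(pval, fwe))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
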