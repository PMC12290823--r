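#' Average distance records per subject, function and response
#'
#' Collapses repeated DES measurements so that each subject contributes at
#' most one pDES and one nDES value per function (and method): the mean of
#' the integer distances, kept as a float.  This compensates for the very
#' unequal number of stimulation sites per patient before ROC analysis.
#'
#' @param records data.frame with columns `subject`, `method`, `func`,
#'   `response`, `distance_mm`.
#' @return data.frame with one row per subject x method x func x response,
#'   with `distance_mm` the group mean and `n` the group size.
#' @export
average_records <- function(records) {
  if (nrow(records) == 0L)
    return(cbind(records[0, c("subject", "method", "func", "response")],
                 distance_mm = numeric(0), n = integer(0)))
  records <- records[!is.na(records$distance_mm), , drop = FALSE]
  key <- interaction(records$subject, records$method, records$func,
                     records$response, drop = TRUE)
  first <- !duplicated(key)
  out <- records[first, c("subject", "method", "func", "response")]
  out$distance_mm <- as.vector(tapply(records$distance_mm, key, mean))[
    match(key[first], levels(key))]
  out$n <- as.vector(table(key))[match(key[first], levels(key))]
  rownames(out) <- NULL
  out
}

#' ROC curve for fMRI-DES distance agreement
#'
#' A distance below the cutoff counts as a positive (agreeing) result, so
#' sensitivity at cutoff c is the fraction of pDES records with d < c and
#' specificity the fraction of nDES records with d >= c.  Candidate cutoffs
#' are the midpoints between consecutive sorted unique distances plus
#' below-minimum and above-maximum sentinels; AUC is the trapezoid area
#' over (1 - specificity, sensitivity), which equals the tie-corrected
#' Mann-Whitney statistic.
#'
#' @param records data.frame with `response` (`"pDES"`/`"nDES"`) and
#'   `distance_mm` (normally the averaged records).
#' @return Object of class `roc_result` with `cutoffs`, `sens`, `spec`,
#'   `youden`, `auc`, `n_pos`, `n_neg`.
#' @examples
#' rec <- data.frame(response = rep(c("pDES", "nDES"), c(4, 6)),
#'                   distance_mm = c(1, 3, 4, 8, 6, 9, 12, 15, 18, 25))
#' roc <- roc_curve(rec)
#' roc$auc
#' select_cutoffs_local_maxima(roc)
#' @export
roc_curve <- function(records) {
  d <- records$distance_mm
  pos <- records$response == "pDES"
  if (!any(pos) || all(pos))
    stop("ROC needs at least one pDES and one nDES record")
  u <- sort(unique(d))
  cuts <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  sens <- vapply(cuts, function(cc) mean(d[pos] < cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(d[!pos] >= cc), numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  structure(list(cutoffs = cuts, sens = sens, spec = spec,
                 youden = sens + spec - 1, auc = auc,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d pDES, %d nDES, %d cutoffs)\n",
              x$auc, x$n_pos, x$n_neg, length(x$cutoffs)))
  invisible(x)
}

#' Distance cutoffs at local maxima of the Youden index
#'
#' Scans the Youden index (sensitivity + specificity - 1) along the
#' candidate cutoffs and returns the local maxima (strictly greater than
#' both neighbours; a plateau counts once, at its smallest cutoff; the
#' curve ends count as neighbours of value -Inf).  The top `k` by Youden
#' value are returned sorted by cutoff, together with their integer-rounded
#' versions.
#'
#' @param roc a `roc_result`.
#' @param k maximum number of cutoffs (default 3).
#' @return List with `cutoffs`, `cutoffs_mm` (integers via [round_mm()]),
#'   and `youden`.
#' @export
select_cutoffs_local_maxima <- function(roc, k = 3) {
  j <- roc$youden
  r <- rle(j)
  vals <- r$values
  starts <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  left <- c(-Inf, vals[-length(vals)])
  right <- c(vals[-1], -Inf)
  is_max <- vals > left & vals > right
  if (!any(is_max)) {  # constant curve: plateau rule, smallest cutoff
    warning("Youden index has no local maximum; returning its global maximum")
    is_max <- seq_along(vals) == which.max(vals)
  }
  idx <- starts[is_max]
  ord <- order(j[idx], decreasing = TRUE)
  keep <- sort(idx[ord][seq_len(min(k, length(idx)))])
  list(cutoffs = roc$cutoffs[keep],
       cutoffs_mm = round_mm(pmax(roc$cutoffs[keep], 0)),
       youden = j[keep])
}

delong_placements <- function(d_pos, d_neg) {
  # smaller distance = stronger evidence of agreement (positive)
  psi <- function(dp, dn) (dp < dn) + 0.5 * (dp == dn)
  M <- outer(d_pos, d_neg, psi)
  list(v10 = rowMeans(M), v01 = colMeans(M), auc = mean(M))
}

#' DeLong test for paired ROC curves
#'
#' Compares the AUCs of two fMRI methods on paired records (same subject x
#' function x response groups in both).  Uses the placement-value
#' covariance estimator and a two-sided normal approximation.  If the
#' variance of the AUC difference is (numerically) zero — e.g. identical
#' distances in both methods — the difference is reported with p = 1 and a
#' flag.
#'
#' @param records_a,records_b averaged record data.frames for the two
#'   methods (columns `subject`, `func`, `response`, `distance_mm`).
#' @return List with `auc_a`, `auc_b`, `auc_diff`, `z`, `p`, `n_pos`,
#'   `n_neg`, `degenerate`.
#' @export
delong_test <- function(records_a, records_b) {
  ka <- paste(records_a$subject, records_a$func, records_a$response)
  kb <- paste(records_b$subject, records_b$func, records_b$response)
  common <- intersect(ka, kb)
  a <- records_a[match(common, ka), ]
  b <- records_b[match(common, kb), ]
  pos <- a$response == "pDES"
  if (sum(pos) < 1 || sum(!pos) < 1)
    stop("paired records must contain both pDES and nDES groups")
  pa <- delong_placements(a$distance_mm[pos], a$distance_mm[!pos])
  pb <- delong_placements(b$distance_mm[pos], b$distance_mm[!pos])
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    # zero estimated variance: identical AUCs are a sure tie (p = 1);
    # different AUCs with no sampling variability are a sure difference
    return(list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff,
                z = if (abs(diff) < 1e-12) 0 else sign(diff) * Inf,
                p = if (abs(diff) < 1e-12) 1 else 0,
                n_pos = m, n_neg = n, degenerate = TRUE))
  }
  z <- diff / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff, z = z,
       p = 2 * stats::pnorm(-abs(z)), n_pos = m, n_neg = n,
       degenerate = FALSE)
}

#' Classify fMRI-DES agreement at a distance cutoff
#'
#' A pair with distance below the cutoff is a positive result: a true
#' positive for pDES, a false positive for nDES.  Distances at or above
#' the cutoff are negative results: true negatives for nDES, false
#' negatives for pDES.
#'
#' @param distance_mm integer distance(s).
#' @param response `"pDES"` or `"nDES"` (vectorized).
#' @param cutoff integer cutoff in mm.
#' @return Character vector in `{"TP","FP","TN","FN"}`.
#' @export
classify_agreement <- function(distance_mm, response, cutoff) {
  if (!all(response %in% c("pDES", "nDES")))
    stop("response must be 'pDES' or 'nDES'")
  below <- distance_mm < cutoff
  ifelse(below,
         ifelse(response == "pDES", "TP", "FP"),
         ifelse(response == "nDES", "TN", "FN"))
}

#' Confusion table of binary agreement at a cutoff
#'
#' @param records data.frame with `distance_mm` and `response`.
#' @param cutoff integer cutoff in mm.
#' @return List with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `cutoff`.
#' @export
confusion_counts <- function(records, cutoff) {
  lab <- classify_agreement(records$distance_mm, records$response, cutoff)
  tp <- sum(lab == "TP"); fp <- sum(lab == "FP")
  tn <- sum(lab == "TN"); fn <- sum(lab == "FN")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       cutoff = cutoff)
}

#' Dice and Jaccard overlap of two binary maps
#'
#' `DSC = 2|A..B| / (|A| + |B|)` and `JI = |A..B| / |A..B|` (intersection
#' over union); the two are linked by `JI = DSC / (2 - DSC)`.  If both maps
#' are empty the result is defined as 0 with a flag (avoiding 0/0).
#'
#' @param map_a,map_b binary `volume`s on the same grid.
#' @return List with `dsc`, `ji`, `size_a`, `size_b`, `intersection`,
#'   `union`, `both_empty`.
#' @export
dice_jaccard <- function(map_a, map_b) {
  stop_if_grid_mismatch(map_a, map_b, "overlap maps")
  a <- map_a$data > 0
  b <- map_b$data > 0
  na <- sum(a); nb <- sum(b)
  ab <- sum(a & b)
  un <- sum(a | b)
  if (na + nb == 0L)
    return(list(dsc = 0, ji = 0, size_a = 0L, size_b = 0L,
                intersection = 0L, union = 0L, both_empty = TRUE))
  list(dsc = 2 * ab / (na + nb), ji = ab / un, size_a = na, size_b = nb,
       intersection = ab, union = un, both_empty = FALSE)
}
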