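#' Read a DES coordinate table
#'
#' Tab-separated table with columns `subject_id`, `function`, `response`,
#' `x_mm`, `y_mm`, `z_mm` (world RAS+ millimetres).  Response labels must
#' be `pDES`/`nDES`; the `function` field may be empty/NA for negative
#' sites, which count against every mapped function.  Duplicate rows are
#' dropped with a warning.
#'
#' @param path TSV file path.
#' @return data.frame with columns `subject`, `func`, `response`, `x_mm`,
#'   `y_mm`, `z_mm`.
#' @export
load_des_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("subject_id", "function", "response", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop(sprintf("DES table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (!all(tab$response %in% c("pDES", "nDES")))
    stop("response labels must be 'pDES' or 'nDES'")
  dup <- duplicated(tab)
  if (any(dup)) {
    warning(sprintf("%d duplicated DES row(s) removed", sum(dup)))
    tab <- tab[!dup, , drop = FALSE]
  }
  out <- data.frame(subject = tab$subject_id,
                    func = ifelse(is.na(tab[["function"]]) |
                                    tab[["function"]] == "",
                                  NA_character_, tab[["function"]]),
                    response = tab$response,
                    x_mm = as.numeric(tab$x_mm), y_mm = as.numeric(tab$y_mm),
                    z_mm = as.numeric(tab$z_mm))
  rownames(out) <- NULL
  out
}

#' Write a DES coordinate table
#'
#' @param des data.frame as returned by [load_des_table()] (or the `des`
#'   element of a phantom subject).
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_des_table <- function(des, path) {
  out <- data.frame(subject_id = des$subject,
                    "function" = if (!is.null(des$func)) des$func else NA,
                    response = des$response, x_mm = des$x_mm,
                    y_mm = des$y_mm, z_mm = des$z_mm, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate fMRI-map / DES pairings
#'
#' A positive DES site is paired only with the same-function map of each
#' method; a negative DES site (no elicited response) is paired with every
#' function's map.  One row per map x DES pairing.
#'
#' @param des DES data.frame (`subject`, `func`, `response`, coordinates);
#'   `func = NA` marks sites paired with all functions.
#' @param roster data.frame of available maps with columns `subject`,
#'   `method`, `func`.
#' @return data.frame with one row per pairing (`subject`, `method`,
#'   `func`, `response`, coordinates if present).
#' @export
des_pairings <- function(des, roster) {
  out <- list()
  for (r in seq_len(nrow(roster))) {
    subj <- roster$subject[r]; mth <- roster$method[r]; fn <- roster$func[r]
    sel <- des$subject == subj &
      (des$response == "nDES" | is.na(des$func) | des$func == fn)
    # positives must match the map's function
    sel <- sel & !(des$response == "pDES" &
                     (!is.na(des$func) & des$func != fn))
    sel <- sel & !(des$response == "pDES" & is.na(des$func))
    if (!any(sel)) next
    d <- des[sel, , drop = FALSE]
    d$method <- mth
    d$func <- fn
    out[[length(out) + 1L]] <- d
  }
  if (length(out) == 0L) {
    des0 <- des[0, , drop = FALSE]
    des0$method <- character(0)
    return(des0)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

fd_from_motion <- function(motion) {
  dm <- abs(diff(as.matrix(motion)))
  c(0, rowSums(dm[, 1:3, drop = FALSE]) +
      50 * rowSums(dm[, 4:6, drop = FALSE]))
}

generate_stat_maps <- function(ph, smooth_fwhm = 6, highpass_sigma = 20,
                               band = c(0.001, 0.01)) {
  maps <- list()
  qa <- list()
  rest_betas <- function(series, motion, TR, seeds, gm, d3, affine) {
    nt <- dim(series$data)[4]
    Xv <- matrix(series$data, prod(d3), nt)
    Xv <- smooth_voxmat(Xv, d3, smooth_fwhm, voxel_sizes(series))
    keep <- gm$data > 0
    for (f in names(seeds)) keep <- keep | seeds[[f]]$data > 0
    keep_idx <- which(keep)
    X <- t(Xv[keep_idx, , drop = FALSE])
    fd <- fd_from_motion(motion)
    X <- regress_confounds(X, fd / max(mean(fd[-1]), 1e-6))
    X <- temporal_filter(X, "bandpass", TR = TR, band = band)
    out <- list()
    for (f in names(seeds)) {
      sel <- match(which(seeds[[f]]$data > 0), keep_idx)
      s <- rowMeans(X[, sel, drop = FALSE])
      s_std <- (s - mean(s)) / stats::sd(s)
      beta <- as.vector(crossprod(X, s_std)) / (length(s) - 1)
      full <- numeric(prod(d3))
      full[keep_idx] <- beta
      out[[f]] <- volume(array(full, dim = d3), affine)
    }
    out
  }
  for (mth in names(ph$methods)) {
    m <- ph$methods[[mth]]
    if (mth == "tbfMRI") {
      for (f in names(m$series)) {
        ser <- m$series[[f]]
        fd <- fd_from_motion(m$motion[[f]])
        d3t <- grid_dim3(ser)
        Xv <- matrix(ser$data, prod(d3t), dim(ser$data)[4])
        Xv <- smooth_voxmat(Xv, d3t, smooth_fwhm, voxel_sizes(ser))
        keep_idx <- which(m$gm$data > 0)
        X <- t(Xv[keep_idx, , drop = FALSE])
        X <- regress_confounds(X, fd / max(mean(fd[-1]), 1e-6))
        X <- temporal_filter(X, "highpass_gaussian", TR = m$TR,
                             sigma_TR = highpass_sigma)
        g <- glm_zmap(X, m$regressor, affine = ser$affine)
        d3 <- grid_dim3(ser)
        full <- numeric(prod(d3))
        full[keep_idx] <- g$zmap$data
        maps[[mth]][[f]] <- volume(array(full, dim = d3), ser$affine)
      }
      qa[[mth]] <- qa_metrics(m$series[[ph$functions[1]]],
                              m$motion[[ph$functions[1]]])
    } else {
      ser <- if (mth == "mTE")
        combine_echoes(m$echoes, m$echo_times_ms)$series else m$series
      qa[[mth]] <- qa_metrics(ser, m$motion)
      sds <- m$seeds[ph$functions]
      maps[[mth]] <- rest_betas(ser, m$motion, m$TR, sds, m$gm,
                                grid_dim3(ser), ser$affine)
    }
  }
  list(maps = maps, qa = qa)
}

binarize_subject_maps <- function(ph, stat_maps, K = 101, alpha = 1) {
  out <- list()
  thr <- list()
  for (mth in names(stat_maps)) {
    gm <- ph$methods[[mth]]$gm
    for (f in names(stat_maps[[mth]])) {
      tr <- threshold_map(stat_maps[[mth]][[f]], gm, K = K, alpha = alpha)
      thr[[mth]][[f]] <- tr
      out[[mth]][[f]] <- resample_to_grid(tr$binary_map, ph$anat$grid)
    }
  }
  list(binary_anat = out, thresholds = thr)
}

subject_distance_records <- function(ph, binary_anat, sphere_radius = 5,
                                     dilation_mm = 15) {
  des <- ph$des
  if (nrow(des) == 0L) return(NULL)
  grid <- ph$anat$grid
  spheres <- lapply(seq_len(nrow(des)), function(i)
    sphere_roi(c(des$x_mm[i], des$y_mm[i], des$z_mm[i]), sphere_radius,
               grid))
  cogs <- t(vapply(spheres, center_of_gravity, numeric(3)))
  sfield <- surgical_field_mask(spheres, ph$anat$brain, dilation_mm)
  rows <- list()
  for (mth in names(binary_anat)) {
    for (f in names(binary_anat[[mth]])) {
      bm <- binary_anat[[mth]][[f]]
      sel <- which(des$response == "nDES" | is.na(des$func) |
                     des$func == f)
      sel <- setdiff(sel, which(des$response == "pDES" &
                                  (is.na(des$func) | des$func != f)))
      for (i in sel) {
        md <- min_distance(cogs[i, ], bm, sfield)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = ph$subject_id, method = mth, func = f,
          response = des$response[i],
          raw_distance_mm = md$raw_distance_mm,
          distance_mm = md$distance_mm,
          used_fallback = md$used_fallback, defined = md$defined)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

subject_similarity <- function(ph, binary_anat) {
  mths <- names(binary_anat)
  rows <- list()
  for (f in ph$functions) {
    for (a in seq_along(mths)) {
      for (b in seq_len(length(mths))) {
        if (b <= a) next
        dj <- dice_jaccard(binary_anat[[mths[a]]][[f]],
                           binary_anat[[mths[b]]][[f]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = ph$subject_id, func = f, method_a = mths[a],
          method_b = mths[b], dsc = dj$dsc, ji = dj$ji)
      }
    }
  }
  do.call(rbind, rows)
}

descriptive_table <- function(records) {
  key <- interaction(records$func, records$response, records$method,
                     drop = TRUE)
  first <- !duplicated(key)
  stats_for <- function(d) {
    c(mean = mean(d), sd = stats::sd(d), median = stats::median(d),
      iqr = stats::IQR(d), var = stats::var(d),
      range = diff(range(d)), n = length(d))
  }
  out <- records[first, c("func", "response", "method")]
  sm <- t(vapply(levels(key), function(l)
    stats_for(records$distance_mm[key == l]), numeric(7)))
  out <- cbind(out, sm[match(key[first], levels(key)), , drop = FALSE])
  rownames(out) <- NULL
  out[order(out$func, out$response, out$method), ]
}

#' Run the full map-vs-DES validation pipeline
#'
#' End-to-end analysis over a phantom cohort: per subject, statistic maps
#' are generated for the four acquisition schemes, thresholded
#' (gray-matter mask, positivity clip, k-means rescale, automatic minimum
#' threshold), binarized and resampled to the 1 mm anatomical grid;
#' DES spheres, the surgical-field mask and minimum Euclidean distances
#' are computed; records are averaged per subject for ROC analysis;
#' distance cutoffs are taken from the local Youden maxima of the
#' task-fMRI ROC; DeLong tests compare method ROCs; binary agreement is
#' tabulated at each cutoff; Dice/Jaccard similarity is computed between
#' method pairs; and the two-part mixed model is fitted at each cutoff
#' with FWE-adjusted pairwise method contrasts.
#'
#' @param config a [phantom_config()] (the simulated-cohort path).
#' @param cutoffs `"auto"` (ROC-derived, default) or explicit positive
#'   integers.
#' @param K,alpha thresholding parameters (see [threshold_map()]).
#' @param sphere_radius_mm,dilation_mm DES geometry parameters.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param verbose print stage progress.
#' @return Object of class `validation_report`.
#' @export
run_validation <- function(config, cutoffs = "auto", K = 101, alpha = 1,
                           sphere_radius_mm = 5, dilation_mm = 15,
                           out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  records <- list()
  sims <- list()
  qas <- list()
  for (i in seq_len(config$n_subjects)) {
    ph <- tryCatch(make_subject_phantom(config, i),
                   error = function(e)
                     stop(sprintf("stage simulate, subject %d: %s", i,
                                  conditionMessage(e))))
    if (verbose) message(sprintf("[%s] maps", ph$subject_id))
    gm <- tryCatch(generate_stat_maps(ph),
                   error = function(e)
                     stop(sprintf("stage mapgen, subject %s: %s",
                                  ph$subject_id, conditionMessage(e))))
    bz <- tryCatch(binarize_subject_maps(ph, gm$maps, K = K, alpha = alpha),
                   error = function(e)
                     stop(sprintf("stage threshold, subject %s: %s",
                                  ph$subject_id, conditionMessage(e))))
    rec <- tryCatch(subject_distance_records(ph, bz$binary_anat,
                                             sphere_radius_mm, dilation_mm),
                    error = function(e)
                      stop(sprintf("stage distances, subject %s: %s",
                                   ph$subject_id, conditionMessage(e))))
    records[[i]] <- rec
    sims[[i]] <- subject_similarity(ph, bz$binary_anat)
    qas[[i]] <- data.frame(
      subject = ph$subject_id, method = names(gm$qa),
      median_tsnr = vapply(gm$qa, function(q)
        stats::median(q$tsnr$data[is.finite(q$tsnr$data)]), numeric(1)),
      mean_fd = vapply(gm$qa, function(q) q$mean_fd, numeric(1)))
  }
  records <- do.call(rbind, records)
  records <- records[records$defined, , drop = FALSE]
  similarity <- do.call(rbind, sims)
  qa <- do.call(rbind, qas)
  rownames(qa) <- NULL

  avg <- average_records(records)
  mths <- unique(records$method)
  rocs <- lapply(stats::setNames(mths, mths), function(m)
    roc_curve(avg[avg$method == m, ]))
  if (identical(cutoffs, "auto")) {
    cut_sel <- select_cutoffs_local_maxima(rocs[["tbfMRI"]], k = 3)
    cutoffs_mm <- unique(cut_sel$cutoffs_mm)
    cutoffs_mm <- cutoffs_mm[cutoffs_mm > 0]
  } else {
    if (any(cutoffs <= 0 | cutoffs != round(cutoffs)))
      stop("explicit cutoffs must be positive integers")
    cut_sel <- NULL
    cutoffs_mm <- as.integer(cutoffs)
  }

  pairs <- utils::combn(mths, 2)
  delong <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dl <- delong_test(avg[avg$method == a, ], avg[avg$method == b, ])
    data.frame(method_a = a, method_b = b, auc_a = dl$auc_a,
               auc_b = dl$auc_b, auc_diff = dl$auc_diff, z = dl$z, p = dl$p)
  }))

  confusion <- do.call(rbind, lapply(cutoffs_mm, function(cc)
    do.call(rbind, lapply(mths, function(m) {
      ct <- confusion_counts(records[records$method == m, ], cc)
      cta <- confusion_counts(avg[avg$method == m, ], cc)
      data.frame(cutoff = cc, method = m, tp = ct$tp, fp = ct$fp,
                 tn = ct$tn, fn = ct$fn,
                 sensitivity_raw = ct$sensitivity,
                 specificity_raw = ct$specificity,
                 sensitivity_avg = cta$sensitivity,
                 specificity_avg = cta$specificity)
    }))))

  twopart <- lapply(stats::setNames(cutoffs_mm, paste0("cutoff_", cutoffs_mm)),
                    function(cc) {
                      dat <- threshold_semicontinuous(records, cc)
                      fit <- tryCatch(fit_two_part(dat),
                                      error = function(e) e)
                      if (inherits(fit, "error"))
                        return(list(error = conditionMessage(fit)))
                      list(fit = fit, summary = summary(fit)$coefficients,
                           contrasts = posthoc_contrasts(fit))
                    })

  report <- structure(list(
    records = records, averaged = avg, descriptives = descriptive_table(records),
    rocs = rocs, cutoff_selection = cut_sel, cutoffs_mm = cutoffs_mm,
    delong = delong, confusion = confusion, similarity = similarity,
    twopart = twopart, qa = qa,
    provenance = list(seed = config$seed, n_subjects = config$n_subjects,
                      K = K, alpha = alpha,
                      sphere_radius_mm = sphere_radius_mm,
                      dilation_mm = dilation_mm,
                      package_version = as.character(
                        utils::packageVersion("desconcord")))),
    class = "validation_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(
    x, file.path(out_dir, f), row.names = FALSE)
  wcsv(report$records, "records.csv")
  wcsv(report$averaged, "records_averaged.csv")
  wcsv(report$descriptives, "descriptives.csv")
  wcsv(report$delong, "delong.csv")
  wcsv(report$confusion, "confusion.csv")
  wcsv(report$similarity, "similarity.csv")
  wcsv(report$qa, "qa.csv")
  contr <- do.call(rbind, lapply(names(report$twopart), function(nm) {
    tw <- report$twopart[[nm]]
    if (is.null(tw$contrasts)) return(NULL)
    cbind(cutoff = nm, tw$contrasts)
  }))
  if (!is.null(contr)) wcsv(contr, "twopart_contrasts.csv")
  roc_out <- lapply(report$rocs, function(r)
    list(auc = r$auc, cutoffs = r$cutoffs, sens = r$sens, spec = r$spec))
  jsonlite::write_json(
    list(rocs = roc_out, cutoffs_mm = report$cutoffs_mm,
         provenance = report$provenance),
    file.path(out_dir, "roc.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Map-vs-DES validation report\n")
  cat(sprintf("  %d distance records from %d subjects\n",
              nrow(x$records), length(unique(x$records$subject))))
  for (m in names(x$rocs))
    cat(sprintf("  AUC %-8s %.3f\n", m, x$rocs[[m]]$auc))
  cat(sprintf("  ROC cutoffs: %s mm\n",
              paste(x$cutoffs_mm, collapse = ", ")))
  for (nm in names(x$twopart)) {
    tw <- x$twopart[[nm]]
    if (!is.null(tw$error)) {
      cat(sprintf("  two-part %s: failed (%s)\n", nm, tw$error))
    } else {
      pA <- tw$summary["A:responsepDES", "Pr(>|t|)"]
      pB <- tw$summary["B:responsepDES", "Pr(>|t|)"]
      cat(sprintf(
        "  two-part %s: DES response p(A) = %.2g, p(B) = %.2g; max |t| method contrast %.2f\n",
        nm, pA, pB, max(abs(tw$contrasts$t))))
    }
  }
  invisible(x)
}
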