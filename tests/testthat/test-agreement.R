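rec <- function(subject, response, d, func = "hands", method = "tbfMRI") {
  data.frame(subject = subject, method = method, func = func,
             response = response, distance_mm = d)
}

test_that("per-subject averaging collapses repeated DES measurements", {
  one <- rec("S1", "pDES", 7)
  expect_equal(average_records(one)$distance_mm, 7)
  three <- rec(rep("S1", 3), rep("nDES", 3), c(10, 12, 14))
  av <- average_records(three)
  expect_equal(nrow(av), 1)
  expect_equal(av$distance_mm, 12)
  expect_equal(av$n, 3)
  # random tables match an independent group-by mean
  set.seed(91)
  rr <- random_records()
  rr <- rbind(rr, rr)   # force repeats
  av2 <- average_records(rr)
  for (i in seq_len(nrow(av2))) {
    sel <- rr$subject == av2$subject[i] & rr$func == av2$func[i] &
      rr$response == av2$response[i] & rr$method == av2$method[i]
    expect_equal(av2$distance_mm[i], mean(rr$distance_mm[sel]))
  }
})

test_that("ROC curves score d-below-cutoff as positive", {
  r1 <- roc_curve(rec(paste0("S", 1:4), c("pDES", "pDES", "nDES", "nDES"),
                      c(2, 3, 8, 9)))
  expect_equal(r1$auc, 1)
  r2 <- roc_curve(rec(paste0("S", 1:4), c("pDES", "pDES", "nDES", "nDES"),
                      c(5, 7, 5, 7)))
  expect_equal(r2$auc, 0.5)
  r3 <- roc_curve(rec(paste0("S", 1:4), c("pDES", "pDES", "nDES", "nDES"),
                      c(2, 8, 3, 9)))
  expect_equal(r3$auc, 0.75)   # 3 of 4 pairs concordant
  expect_true(all(diff(r3$sens) >= 0))
  expect_true(all(diff(r3$spec) <= 0))
  expect_error(roc_curve(rec("S1", "pDES", 3)), "pDES and.*nDES")
})

test_that("ROC AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(92)
  for (i in 1:50) {
    np <- sample(2:10, 1); nn <- sample(2:15, 1)
    dp <- sample(0:12, np, replace = TRUE)
    dn <- sample(0:18, nn, replace = TRUE)
    rr <- rec(paste0("S", seq_len(np + nn)),
              c(rep("pDES", np), rep("nDES", nn)), c(dp, dn))
    expect_equal(roc_curve(rr)$auc, mw_auc(dp, dn), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(93)
  d <- c(sample(0:10, 8, TRUE), sample(3:20, 12, TRUE))
  lab <- c(rep("pDES", 8), rep("nDES", 12))
  rr <- rec(paste0("S", 1:20), lab, d)
  ours <- roc_curve(rr)$auc
  ref <- suppressMessages(
    pROC::auc(pROC::roc(lab == "pDES", d, direction = ">")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("cutoff selection finds Youden local maxima with plateau rule", {
  # two clear peaks: pDES cluster below 4 and below 9
  rr <- rec(paste0("S", 1:12),
            c(rep("pDES", 5), rep("nDES", 7)),
            c(1, 2, 3, 8, 8, 5, 5, 6, 12, 13, 14, 15))
  roc <- roc_curve(rr)
  sel <- select_cutoffs_local_maxima(roc, k = 3)
  expect_true(length(sel$cutoffs) >= 2)
  expect_equal(sel$cutoffs_mm, round_mm(sel$cutoffs))
  expect_true(!is.unsorted(sel$cutoffs))
  # single peak: exactly the argmax
  rr2 <- rec(paste0("S", 1:6), c(rep("pDES", 3), rep("nDES", 3)),
             c(1, 2, 3, 10, 11, 12))
  sel2 <- select_cutoffs_local_maxima(roc_curve(rr2), k = 3)
  expect_equal(length(sel2$cutoffs), 1)
  expect_equal(sel2$youden, 1)
})

test_that("DeLong test: degenerate, separated, and pROC-checked cases", {
  a <- rec(paste0("S", 1:10), rep(c("pDES", "nDES"), each = 5),
           c(1, 2, 3, 2, 4, 9, 11, 13, 10, 12))
  same <- delong_test(a, a)
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  # perfectly separating vs anti-separating at n = 50 per class
  set.seed(94)
  n <- 50
  subj <- paste0("S", seq_len(2 * n))
  lab <- rep(c("pDES", "nDES"), each = n)
  good <- rec(subj, lab, c(runif(n, 0, 4), runif(n, 10, 20)))
  bad <- good; bad$distance_mm <- c(runif(n, 10, 20), runif(n, 0, 4))
  dl <- delong_test(good, bad)
  expect_lt(dl$p, 0.05)
  expect_gt(dl$auc_diff, 0.9)
})

test_that("DeLong variance agrees with pROC and with the bootstrap", {
  skip_if_not_installed("pROC")
  set.seed(95)
  n <- 20
  subj <- paste0("S", 1:n)
  lab <- c(rep("pDES", 8), rep("nDES", 12))
  da <- c(rnorm(8, 4, 2.5), rnorm(12, 9, 3))
  db <- da + rnorm(n, 0, 2)
  ra <- rec(subj, lab, da); rb <- rec(subj, lab, db)
  ours <- delong_test(ra, rb)
  ref <- suppressMessages(pROC::roc.test(
    pROC::roc(lab == "pDES", da, direction = ">"),
    pROC::roc(lab == "pDES", db, direction = ">"),
    method = "delong", paired = TRUE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  # bootstrap variance of the AUC difference within 25%
  B <- 4000
  boot <- replicate(B, {
    ip <- sample(which(lab == "pDES"), replace = TRUE)
    im <- sample(which(lab == "nDES"), replace = TRUE)
    mw_auc(da[ip], da[im]) - mw_auc(db[ip], db[im])
  })
  var_ours <- (ours$auc_diff / ours$z)^2
  expect_lt(abs(var_ours - stats::var(boot)) / stats::var(boot), 0.25)
})

test_that("agreement classification and confusion tables", {
  expect_equal(classify_agreement(3, "pDES", 4), "TP")
  expect_equal(classify_agreement(4, "nDES", 4), "TN")  # boundary negative
  expect_equal(classify_agreement(3, "nDES", 4), "FP")
  expect_equal(classify_agreement(4, "pDES", 4), "FN")
  expect_error(classify_agreement(3, "positive", 4), "response")
  rr <- rec(paste0("S", 1:8), rep(c("pDES", "nDES"), each = 4),
            c(1, 2, 3, 3, 9, 10, 11, 12))
  ct <- confusion_counts(rr, 5)
  expect_equal(c(ct$tp, ct$fp, ct$tn, ct$fn), c(4, 0, 4, 0))
  expect_equal(c(ct$sensitivity, ct$specificity), c(1, 1))
  ct0 <- confusion_counts(rr, 0)
  expect_equal(ct0$tp + ct0$fp, 0)
  # marginals conserved across cutoffs; counts match a brute recount
  set.seed(96)
  rr2 <- rec(paste0("S", 1:30),
             sample(c("pDES", "nDES"), 30, TRUE),
             sample(0:15, 30, TRUE))
  for (cc in c(2, 7, 12)) {
    ct2 <- confusion_counts(rr2, cc)
    expect_equal(ct2$tp + ct2$fn, sum(rr2$response == "pDES"))
    expect_equal(ct2$tn + ct2$fp, sum(rr2$response == "nDES"))
    expect_equal(ct2$tp, sum(rr2$distance_mm < cc & rr2$response == "pDES"))
  }
})

test_that("Dice and Jaccard: closed forms and the DSC-JI identity", {
  g <- make_grid(c(4, 4, 2), c(1, 1, 1))
  a <- g; a$data[1:3] <- 1
  b <- g; b$data[2:6] <- 1
  dj <- dice_jaccard(a, b)
  expect_equal(dj$dsc, 2 * 2 / (3 + 5))
  expect_equal(dj$ji, 2 / 6)
  same <- dice_jaccard(a, a)
  expect_equal(c(same$dsc, same$ji), c(1, 1))
  disj <- g; disj$data[9:10] <- 1
  expect_equal(unlist(dice_jaccard(a, disj)[c("dsc", "ji")]),
               c(dsc = 0, ji = 0))
  both0 <- dice_jaccard(g, g)
  expect_true(both0$both_empty)
  expect_equal(c(both0$dsc, both0$ji), c(0, 0))
  set.seed(97)
  for (i in 1:40) {
    x <- random_binary_volume(); y <- random_binary_volume()
    dj2 <- dice_jaccard(x, y)
    if (!dj2$both_empty) {
      expect_equal(dj2$ji, dj2$dsc / (2 - dj2$dsc), tolerance = 1e-12)
      expect_lte(dj2$ji, dj2$dsc)
    }
  }
})
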