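test_that("dichotomize applies class, age, and cytology rules", {
  df <- data.frame(
    histology = c("EM_G1", "EH", "AEH", "Normal"),
    age = c(60, 45, 55, 54.999),
    cytology = c("positive", "negative", "suspicious_positive", "negative")
  )
  d <- dichotomize(df)
  expect_equal(d$label, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(d$age55, c(TRUE, FALSE, TRUE, FALSE))  # >= 55 inclusive
  expect_equal(d$cytologyPos, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(dichotomize(data.frame(histology = "Carcinoma", age = 50,
                                      cytology = "negative")), "unknown")
})

test_that("logistic OR matches the 2x2 cross-product ratio", {
  # balanced independent table: OR 1, p ~ 1
  out <- rep(c(TRUE, FALSE), each = 20)
  x <- rep(c(1, 0, 1, 0), each = 10)
  nul <- fitLogisticOR(out, x)
  expect_equal(nul$or, 1, tolerance = 1e-6)
  expect_gt(nul$p, 0.99)

  # (8,2 / 2,8): OR = 64/4 = 16, to 6 decimals
  out2 <- rep(c(TRUE, FALSE), each = 10)
  x2 <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  fit <- fitLogisticOR(out2, x2)
  expect_equal(fit$or, 16, tolerance = 1e-6)
  expect_true(fit$ci[1] < 16 && fit$ci[2] > 16)

  expect_error(fitLogisticOR(rep(TRUE, 5), rnorm(5)), "event")
})

test_that("logistic recovery of a designed per-SD log odds ratio", {
  set.seed(2024)
  n <- 1000
  x <- rnorm(n)
  pr <- plogis(-0.2 + 1.0 * x)
  y <- runif(n) < pr
  fit <- fitLogisticOR(y, x)
  expect_equal(fit$logor, 1.0, tolerance = 0.2)
  # adjustment by an independent covariate does not destroy the estimate
  fit2 <- fitLogisticOR(y, x, covariates = data.frame(z = rbinom(n, 1, 0.4)))
  expect_equal(fit2$logor, 1.0, tolerance = 0.25)
  expect_true(fit2$adjusted)
})

test_that("separation is flagged rather than silently diverging", {
  y <- rep(c(TRUE, FALSE), each = 10)
  x <- as.numeric(y)
  fit <- fitLogisticOR(y, x)
  expect_true(fit$separation)
  expect_true(is.infinite(fit$or))
})

test_that("ROC handles separation, ties, and the 3v3 example", {
  sep <- rocCurve(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                  direction = ">")
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_true(sep$cutoff > 3 && sep$cutoff < 5)

  tied <- rocCurve(rep(1, 10), rep(c(TRUE, FALSE), 5), direction = ">")
  expect_equal(tied$auc, 0.5)

  # pos {0.9, 0.8, 0.4}, neg {0.7, 0.3, 0.2}: 8 of 9 pairs concordant
  r <- rocCurve(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), direction = ">")
  expect_equal(r$auc, 8 / 9)

  expect_error(rocCurve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC equals brute-force pair counting and trapezoid integration", {
  set.seed(31)
  for (rep in 1:200) {
    m <- sample(3:12, 1); n <- sample(3:12, 1)
    # mixed continuous and tied scores
    pos <- round(rnorm(m, 1), sample(0:1, 1))
    neg <- round(rnorm(n, 0), sample(0:1, 1))
    r <- rocCurve(c(pos, neg), rep(c(TRUE, FALSE), c(m, n)), direction = ">")
    expect_equal(r$auc, bruteAUC(pos, neg), tolerance = 1e-12)
    # trapezoidal area under the empirical ROC equals the Mann-Whitney AUC
    fpr <- 1 - r$points$specificity
    tpr <- r$points$sensitivity
    o <- order(fpr, tpr)
    trap <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
  }
})

test_that("ROC summary agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  score <- c(rnorm(40, 1), rnorm(50))
  lab <- rep(c(TRUE, FALSE), c(40, 50))
  r <- rocCurve(score, lab, direction = ">")
  pr <- pROC::roc(lab, score, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  civ <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci[1], civ[1], tolerance = 1e-6)
  expect_equal(r$ci[2], civ[3], tolerance = 1e-6)
})

test_that("Youden cutoff maximizes J with ties broken toward specificity", {
  score <- c(1, 2, 3, 4, 10, 11, 12, 13)
  lab <- c(F, F, F, F, T, T, T, T)
  r <- rocCurve(score, lab, direction = ">")
  expect_equal(r$youden, 1)
  expect_true(r$cutoff > 4 && r$cutoff < 10)
  # ambiguous case: two cutoffs reach the same J; the higher-specificity
  # one (larger threshold for direction ">") must be reported
  s2 <- c(1, 2, 3, 10, 2.5, 11, 12, 13)
  l2 <- c(F, F, F, F, T, T, T, T)
  r2 <- rocCurve(s2, l2, direction = ">")
  js <- r2$points$sensitivity + r2$points$specificity - 1
  expect_equal(r2$youden, max(js))
  best <- which(js == max(js))
  expect_equal(r2$specificity, max(r2$points$specificity[best]))
})

test_that("auto direction orients the AUC above one half", {
  set.seed(5)
  score <- c(rnorm(30, 0), rnorm(30, 1))
  lab <- rep(c(TRUE, FALSE), each = 30)   # positives score LOWER
  r <- rocCurve(score, lab)
  expect_equal(r$direction, "<")
  expect_gt(r$auc, 0.5)
})

test_that("combined score: rank invariance and in-sample nesting", {
  set.seed(77)
  n <- 150
  cyto <- rbinom(n, 1, 0.4) == 1
  feat <- rnorm(n) + 0.8 * cyto
  lab <- runif(n) < plogis(-0.5 + 1.5 * cyto + 0.9 * feat)
  cs <- combinedScore(lab, cyto, feat)
  r1 <- rocCurve(cs$score, lab, direction = ">")
  # monotone transform leaves the AUC unchanged
  r2 <- rocCurve(qlogis(pmin(pmax(cs$score, 1e-12), 1 - 1e-12)), lab,
                 direction = ">")
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)

  # with an informative feature, the in-sample combined AUC beats cytology
  # alone in each of 100 replicates
  wins <- vapply(1:100, function(i) {
    set.seed(9000 + i)
    cyto <- rbinom(n, 1, 0.4) == 1
    feat <- rnorm(n)
    lab <- runif(n) < plogis(-0.5 + 1.2 * cyto + 1.0 * feat)
    if (length(unique(lab)) < 2) return(TRUE)
    cs <- combinedScore(lab, cyto, feat)
    aucC <- rocCurve(cs$score, lab, direction = ">")$auc
    aucA <- rocCurve(as.numeric(cyto), lab, direction = ">")$auc
    aucC >= aucA - 1e-12
  }, logical(1))
  expect_true(all(wins))
})

test_that("DeLong paired test: identity, rank invariance, permutation oracle", {
  set.seed(303)
  lab <- rep(c(TRUE, FALSE), each = 15)
  s <- rnorm(30) + lab
  idt <- delongTest(s, s, lab)
  expect_equal(idt$diff, 0)
  expect_equal(idt$p, 1)

  mono <- delongTest(s, exp(s), lab)
  expect_equal(mono$diff, 0)
  expect_equal(mono$p, 1)

  # small paired sample against a label-permutation oracle on the AUC
  # difference statistic
  set.seed(41)
  labp <- rep(c(TRUE, FALSE), each = 10)
  base <- rnorm(20) + 0.8 * labp
  sa <- base + rnorm(20, sd = 0.6)
  sb <- rnorm(20, sd = 1.2) + 0.4 * labp
  obs <- delongTest(sa, sb, labp)
  B <- 4000
  aucDiff <- function(a, b, l) bruteAUC(a[l], a[!l]) - bruteAUC(b[l], b[!l])
  d0 <- abs(aucDiff(sa, sb, labp))
  perm <- vapply(1:B, function(i) {
    swap <- runif(20) < 0.5   # exchange the paired scores per subject
    a2 <- ifelse(swap, sb, sa); b2 <- ifelse(swap, sa, sb)
    abs(aucDiff(a2, b2, labp))
  }, numeric(1))
  pPerm <- mean(perm >= d0 - 1e-12)
  se <- sqrt(pPerm * (1 - pPerm) / B)
  expect_lt(abs(obs$p - pPerm), 4 * se + 0.06)
})

test_that("DeLong test agrees with pROC's paired comparison", {
  skip_if_not_installed("pROC")
  set.seed(17)
  lab <- rep(c(TRUE, FALSE), c(40, 45))
  sa <- rnorm(85) + lab
  sb <- 0.5 * sa + rnorm(85, sd = 0.8)
  ours <- delongTest(sa, sb, lab)
  ra <- pROC::roc(lab, sa, direction = "<", quiet = TRUE)
  rb <- pROC::roc(lab, sb, direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("ROC sample size reproduces the binormal closed forms", {
  expect_equal(as.integer(aucSampleSize(0.70)), 40L)
  expect_equal(as.integer(aucSampleSize(0.65)), 73L)
  expect_equal(attr(aucSampleSize(0.70, ratio = 2), "nSecondGroup"), 80L)
  # monotone decreasing in the alternative AUC
  grid <- seq(0.55, 0.95, by = 0.05)
  ns <- vapply(grid, function(a) as.integer(aucSampleSize(a)), integer(1))
  expect_true(all(diff(ns) < 0))
  expect_error(aucSampleSize(0.5), "aucAlt")
  expect_error(aucSampleSize(0.7, alpha = 0), "alpha")
})
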