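.POSITIVE_CLASSES <- c("AEH", "EM_G1", "EM_G2", "EM_G3", "Others")

#' Dichotomize patient records for the diagnostic analyses
#'
#' The positive class pools atypical endometrial hyperplasia with the
#' carcinomas (AEH, EM G1-G3, Others); the negative class is Normal and
#' EH. Age is split at >= 55 years (postmenopausal proxy; the boundary is
#' inclusive) and cytology at positive-or-suspicious-positive versus
#' negative.
#'
#' @param x a [CytometryExperiment-class] or a data.frame with columns
#'   `histology`, `age`, `cytology`.
#' @return data.frame with logical columns `label` (positive class),
#'   `age55`, `cytologyPos`.
#' @export
dichotomize <- function(x) {
  if (is(x, "CytometryExperiment")) x <- as.data.frame(colData(x))
  hist <- as.character(x$histology)
  bad <- setdiff(unique(hist), .HISTOLOGY_LEVELS)
  if (length(bad)) stop("unknown histology class: ", paste(bad, collapse = ", "))
  data.frame(
    label = hist %in% .POSITIVE_CLASSES,
    age55 = x$age >= 55,
    cytologyPos = as.character(x$cytology) %in% c("positive", "suspicious_positive")
  )
}

#' Logistic association between outcome and a predictor
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' predictor, optionally adjusted for binary covariates; reports the odds
#' ratio with a Wald 95% CI on the log-odds scale. Complete separation is
#' detected and flagged (infinite OR) rather than silently diverging.
#'
#' @param outcome logical or 0/1 outcome.
#' @param predictor numeric predictor (continuous or binary).
#' @param covariates optional data.frame/matrix of adjusting covariates.
#' @param level confidence level (default 0.95).
#' @return list with `or`, `ci` (length 2), `p`, `logor`, `se`,
#'   `adjusted`, `separation`, `covariates` (names), and the coefficient
#'   `table` for all terms.
#' @examples
#' out <- rep(c(TRUE, FALSE), each = 10)
#' x <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
#' fitLogisticOR(out, x)$or   # (8*8)/(2*2) = 16
#' @export
fitLogisticOR <- function(outcome, predictor, covariates = NULL,
                          level = 0.95) {
  outcome <- as.integer(outcome)
  if (sum(outcome) == 0 || sum(outcome) == length(outcome)) {
    stop("need at least one event and one non-event")
  }
  df <- data.frame(.y = outcome, predictor = predictor)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  cf <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  separation <- !fit$converged || any(abs(cf) > 15) ||
    any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8) &&
    max(abs(cf)) > 10
  z <- qnorm(1 - (1 - level) / 2)
  tab <- data.frame(
    term = names(cf), logor = unname(cf), se = unname(se),
    or = exp(unname(cf)),
    ci_lo = exp(unname(cf - z * se)), ci_hi = exp(unname(cf + z * se)),
    p = 2 * pnorm(-abs(unname(cf / se)))
  )
  if (separation) {
    tab$or[abs(tab$logor) > 15] <- ifelse(tab$logor[abs(tab$logor) > 15] > 0,
                                          Inf, 0)
  }
  list(
    or = tab$or[1], ci = c(tab$ci_lo[1], tab$ci_hi[1]), p = tab$p[1],
    logor = tab$logor[1], se = tab$se[1],
    adjusted = !is.null(covariates), separation = separation,
    covariates = if (is.null(covariates)) character(0) else
      colnames(as.data.frame(covariates)),
    table = tab, fit = fit
  )
}

# placement values: for each positive, the fraction of negatives it beats
# (ties count 1/2), and vice versa; the basis of the DeLong variance
.placements <- function(score, label) {
  xs <- score[label]; ys <- score[!label]
  m <- length(xs); n <- length(ys)
  v10 <- vapply(xs, function(x) (sum(x > ys) + 0.5 * sum(x == ys)) / n, 0)
  v01 <- vapply(ys, function(y) (sum(xs > y) + 0.5 * sum(xs == y)) / m, 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Empirical ROC curve with DeLong confidence interval and Youden cutoff
#'
#' The ROC is evaluated at every observed threshold (rule: score >= t is
#' called positive); the AUC is the Mann-Whitney statistic with ties
#' counted 1/2, its variance the DeLong placement-value estimate. The
#' reported cutoff maximizes the Youden index J = sensitivity +
#' specificity - 1, ties broken toward higher specificity; cutoffs are
#' midpoints between consecutive distinct scores.
#'
#' @param score numeric score per patient.
#' @param label logical: TRUE = positive class.
#' @param direction `">"` if larger scores indicate the positive class,
#'   `"<"` for the reverse, or `"auto"` (default) to orient so that the
#'   AUC is >= 0.5 (the chosen orientation is reported).
#' @param level confidence level.
#' @return list of class `rocResult`: `points` (threshold, sensitivity,
#'   specificity), `auc`, `se`, `ci`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden`, `direction`, `n`.
#' @export
rocCurve <- function(score, label, direction = c("auto", ">", "<"),
                     level = 0.95) {
  direction <- match.arg(direction)
  label <- as.logical(label)
  if (length(unique(label)) < 2) stop("both classes must be present")
  if (direction == "auto") {
    direction <- if (mean(rank(score)[label]) >= mean(rank(score)[!label]))
      ">" else "<"
  }
  s <- if (direction == ">") score else -score
  pl <- .placements(s, label)
  m <- sum(label); n <- sum(!label)
  v <- (if (m > 1) var(pl$v10) / m else 0) + (if (n > 1) var(pl$v01) / n else 0)
  se <- sqrt(v)
  z <- qnorm(1 - (1 - level) / 2)
  uq <- sort(unique(s))
  thr <- c(uq[1] - 1, (uq[-length(uq)] + uq[-1]) / 2, uq[length(uq)] + 1)
  sens <- vapply(thr, function(t) mean(s[label] >= t), 0)
  spec <- vapply(thr, function(t) mean(s[!label] < t), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  pts <- data.frame(
    threshold = if (direction == ">") thr else -thr,
    sensitivity = sens, specificity = spec
  )
  structure(list(
    points = pts, auc = pl$auc, se = se,
    ci = pmin(pmax(c(pl$auc - z * se, pl$auc + z * se), 0), 1),
    cutoff = if (direction == ">") thr[best] else -thr[best],
    sensitivity = sens[best], specificity = spec[best],
    youden = j[best], direction = direction, n = c(pos = m, neg = n)
  ), class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), n+ = %d, n- = %d\n",
              x$auc, x$ci[1], x$ci[2], x$n["pos"], x$n["neg"]))
  cat(sprintf("Youden cutoff %.4g (direction %s): sens %.3f, spec %.3f\n",
              x$cutoff, x$direction, x$sensitivity, x$specificity))
  invisible(x)
}

#' In-sample combined score of cytology and a morphometric feature
#'
#' Fitted probability from the two-predictor logistic model (binary
#' cytology flag plus continuous feature), fitted and evaluated on the
#' same cohort, for comparing the combined ROC with cytology alone.
#'
#' @param label logical outcome (positive class).
#' @param cytologyPos logical cytology flag.
#' @param feature numeric morphometric feature.
#' @return list: `score` (fitted probabilities), `fit`, `separation`.
#' @export
combinedScore <- function(label, cytologyPos, feature) {
  fit <- suppressWarnings(glm(label ~ cytologyPos + feature,
                              family = binomial()))
  list(score = unname(fitted(fit)), fit = fit,
       separation = !fit$converged || any(abs(coef(fit)[-1]) > 15))
}

#' DeLong test comparing two paired AUCs
#'
#' Compares the AUCs of two scores measured on the same patients using the
#' DeLong placement-value covariance and a two-sided normal test.
#' Degenerate variance (e.g. identical scores) yields p = 1.
#'
#' @param scoreA,scoreB numeric scores on the same patients.
#' @param label logical: TRUE = positive class.
#' @return list: `aucA`, `aucB`, `diff`, `se`, `z`, `p`.
#' @export
delongTest <- function(scoreA, scoreB, label) {
  label <- as.logical(label)
  if (length(scoreA) != length(scoreB) || length(scoreA) != length(label)) {
    stop("scores and labels must cover the same patients")
  }
  if (length(unique(label)) < 2) stop("both classes must be present")
  pa <- .placements(scoreA, label)
  pb <- .placements(scoreB, label)
  m <- sum(label); n <- sum(!label)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (!is.finite(v) || v <= 1e-12) {
    return(list(aucA = pa$auc, aucB = pb$auc, diff = d, se = 0,
                z = 0, p = 1))
  }
  z <- d / sqrt(v)
  list(aucA = pa$auc, aucB = pb$auc, diff = d, se = sqrt(v), z = z,
       p = 2 * pnorm(-abs(z)))
}

#' ROC sample size by the binormal variance-function method
#'
#' Number of cases per group needed to distinguish an alternative AUC from
#' the null 0.5: with \eqn{a = \sqrt{2}\,\Phi^{-1}(\theta)} and variance
#' function \eqn{V(\theta) = 0.0099\,e^{-a^2/2}\,(6a^2 + 16)},
#' \deqn{n = \frac{\big(z_{1-\alpha/2}\sqrt{V(0.5)} +
#'   z_{power}\sqrt{V(\theta)}\big)^2}{(\theta - 0.5)^2},}
#' rounded to the nearest integer. At the defaults (two-sided 5%
#' significance, 90% power, 1:1 group ratio) an alternative AUC of 0.70
#' requires 40 cases per group and 0.65 requires 73.
#'
#' @param aucAlt alternative AUC in (0.5, 1).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param ratio size of the second group relative to the first.
#' @return cases in the first group (nearest integer), with attribute
#'   `nSecondGroup`.
#' @examples
#' aucSampleSize(0.70)  # 40
#' aucSampleSize(0.65)  # 73
#' @export
aucSampleSize <- function(aucAlt, alpha = 0.05, power = 0.90, ratio = 1) {
  if (aucAlt <= 0.5 || aucAlt >= 1) stop("aucAlt must lie in (0.5, 1)")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  vtheta <- function(theta) {
    a <- sqrt(2) * qnorm(theta)
    0.0099 * exp(-a^2 / 2) * (6 * a^2 + 16)
  }
  z1 <- qnorm(1 - alpha / 2)
  z2 <- qnorm(power)
  n <- (z1 * sqrt(vtheta(0.5)) + z2 * sqrt(vtheta(aucAlt)))^2 /
       (aucAlt - 0.5)^2
  structure(as.integer(round(n)), nSecondGroup = as.integer(round(n * ratio)))
}
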