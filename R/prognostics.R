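#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator with Greenwood standard errors, via
#' [survival::survfit()], returned as a tidy step table.
#'
#' @param time follow-up times (months, >= 0).
#' @param event logical/0-1 event indicator.
#' @param group optional grouping factor; NULL for a single curve.
#' @return data.frame: `group`, `time`, `n_risk`, `n_event`, `surv`,
#'   `se` (Greenwood), with the `survfit` object as attribute `fit`.
#' @export
kmEstimate <- function(time, event, group = NULL) {
  stopifnot(all(time >= 0))
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("empty group")
  df <- data.frame(time = time, event = as.integer(event), group = group)
  fit <- survfit(Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(group)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  structure(data.frame(
    group = grp, time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    surv = sm$surv, se = sm$std.err
  ), fit = fit)
}

#' Log-rank test between survival groups
#'
#' Standard (k-group) log-rank statistic via [survival::survdiff()],
#' referred to chi-square with k - 1 degrees of freedom.
#'
#' @inheritParams kmEstimate
#' @param group grouping factor with >= 2 non-empty levels.
#' @return list: `chisq`, `df`, `p`, `n` (per group), `obs`, `exp`.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) == 0)) stop("empty group")
  df <- data.frame(time = time, event = as.integer(event), group = group)
  sd <- survdiff(Surv(time, event) ~ group, data = df)
  k <- length(sd$n)
  list(chisq = unname(sd$chisq), df = k - 1,
       p = pchisq(sd$chisq, k - 1, lower.tail = FALSE),
       n = as.vector(sd$n), obs = as.vector(sd$obs),
       exp = as.vector(sd$exp))
}

# two-group log-rank chi-square for every candidate cutoff at once.
# cuts: vector of cutoffs; membership low = feature <= cut.
# Returns the vector of chi-square statistics.
.logrankScan <- function(feature, time, event, cuts) {
  o <- order(time)
  time <- time[o]; event <- as.logical(event)[o]; feature <- feature[o]
  et <- unique(time[event])
  if (!length(et)) return(rep(0, length(cuts)))
  n <- length(time)
  # at-risk indicator n x J and per-time event counts
  R <- outer(time, et, ">=")
  dj <- vapply(et, function(t) sum(event & time == t), 0)
  nj <- colSums(R)
  L <- outer(feature, cuts, "<=")            # n x C
  n1 <- crossprod(L, R)                      # C x J, at risk in low group
  d1 <- crossprod(L, outer(time, et, "==") & event)  # C x J events in low
  O1 <- rowSums(d1)
  E1 <- as.vector(n1 %*% (dj / nj))
  p1 <- sweep(n1, 2, nj, "/")
  hyp <- sweep(p1 * (1 - p1), 2, ifelse(nj > 1, dj * (nj - dj) / (nj - 1), 0), "*")
  V <- rowSums(hyp)
  chi <- ifelse(V > 1e-12, (O1 - E1)^2 / V, 0)
  as.vector(chi)
}

#' Outcome-based optimal cutpoint for a continuous marker
#'
#' Exhaustive scan of candidate cutoffs (midpoints between consecutive
#' distinct feature values) whose split leaves at least
#' `minGroupFrac` of patients on each side; the chosen cutoff maximizes
#' the two-group log-rank chi-square. The uncorrected p-value treats the
#' maximal statistic as a single chi-square(1) — anti-conservative by
#' construction; a min-p permutation correction (feature values permuted
#' against the survival outcomes, scan repeated, corrected p = rank of the
#' observed maximum) is computed when `correct = TRUE`.
#'
#' @param feature numeric marker per patient.
#' @param time,event survival outcome.
#' @param minGroupFrac minimum fraction of patients in each group
#'   (default 0.10).
#' @param orientation which side of the cutoff is reported as the risk
#'   group: `"low"` (low marker = risk, as for circularity/solidity) or
#'   `"high"` (as for fractal dimension).
#' @param correct compute the permutation min-p corrected p-value.
#' @param B number of permutations.
#' @param seed seed for the permutations.
#' @return list of class `cutpointResult`: `cutoff`, `chisq`, `p`
#'   (uncorrected), `pCorrected` (NA if not computed), `candidates`,
#'   `chisqAll`, `nLow`, `nHigh`, `riskGroup`, `orientation`.
#' @export
optimalCutpoint <- function(feature, time, event, minGroupFrac = 0.10,
                            orientation = c("low", "high"), correct = TRUE,
                            B = 200L, seed = 1L) {
  orientation <- match.arg(orientation)
  n <- length(feature)
  if (!any(event)) stop("no events: cutpoint scan undefined")
  uq <- sort(unique(feature))
  if (length(uq) < 2) stop("feature is constant: no admissible cutoff")
  cand <- (uq[-length(uq)] + uq[-1]) / 2
  nlow <- vapply(cand, function(c) sum(feature <= c), 0)
  minN <- ceiling(minGroupFrac * n)
  ok <- nlow >= minN & (n - nlow) >= minN
  if (!any(ok)) stop("no admissible cutoff under the group-size constraint")
  cand <- cand[ok]
  chi <- .logrankScan(feature, time, event, cand)
  best <- which.max(chi)
  obs <- chi[best]
  pCorr <- NA_real_
  if (correct) {
    pCorr <- .withSeed(seed, {
      exceed <- 0L
      for (b in seq_len(B)) {
        fp <- sample(feature)
        uqp <- sort(unique(fp))
        cp <- (uqp[-length(uqp)] + uqp[-1]) / 2
        nl <- vapply(cp, function(c) sum(fp <= c), 0)
        cp <- cp[nl >= minN & (n - nl) >= minN]
        mx <- if (length(cp)) max(.logrankScan(fp, time, event, cp)) else 0
        if (mx >= obs) exceed <- exceed + 1L
      }
      (1 + exceed) / (B + 1)
    })
  }
  structure(list(
    cutoff = cand[best], chisq = obs,
    p = pchisq(obs, 1, lower.tail = FALSE), pCorrected = pCorr,
    candidates = cand, chisqAll = chi,
    nLow = sum(feature <= cand[best]), nHigh = sum(feature > cand[best]),
    riskGroup = orientation, orientation = orientation
  ), class = "cutpointResult")
}

#' @export
print.cutpointResult <- function(x, ...) {
  cat(sprintf(
    "Optimal cutpoint %.4g (%d low / %d high, risk group = %s marker)\n",
    x$cutoff, x$nLow, x$nHigh, x$riskGroup))
  cat(sprintf("log-rank chi-square %.3f, uncorrected p %.4g", x$chisq, x$p))
  if (!is.na(x$pCorrected)) cat(sprintf(", min-p corrected p %.4g", x$pCorrected))
  cat("\n")
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Cox model via [survival::coxph()] with Efron
#' (default) or Breslow tie handling; hazard ratios with Wald confidence
#' intervals and p-values per covariate. A singular design (e.g. a
#' duplicated covariate) is an error; monotone likelihood (a covariate
#' perfectly ordering the events) is flagged.
#'
#' @param covariates data.frame or matrix of covariates.
#' @param time,event survival outcome.
#' @param ties `"efron"` or `"breslow"`.
#' @param level confidence level.
#' @return list of class `coxFit`: `table` (hr, ci, p per covariate),
#'   `nEvents`, `n`, `ties`, `monotone` flag, and the `coxph` fit.
#' @export
coxFit <- function(covariates, time, event, ties = c("efron", "breslow"),
                   level = 0.95) {
  ties <- match.arg(ties)
  df <- as.data.frame(covariates)
  nev <- sum(event)
  if (nev < ncol(df)) {
    warning("fewer events (", nev, ") than covariates (", ncol(df), ")")
  }
  df$.time <- time
  df$.event <- as.integer(event)
  fit <- suppressWarnings(
    coxph(Surv(.time, .event) ~ ., data = df, ties = ties,
          control = coxph.control(iter.max = 50))
  )
  cf <- coef(fit)
  if (any(is.na(cf))) stop("singular design: collinear covariates")
  se <- sqrt(diag(vcov(fit)))
  monotone <- any(abs(cf) > 15) || any(se > 50)
  z <- qnorm(1 - (1 - level) / 2)
  tab <- data.frame(
    term = names(cf), coef = unname(cf), se = unname(se),
    hr = exp(unname(cf)),
    ci_lo = exp(unname(cf - z * se)), ci_hi = exp(unname(cf + z * se)),
    p = 2 * pnorm(-abs(unname(cf / se)))
  )
  structure(list(table = tab, nEvents = nev, n = length(time), ties = ties,
                 monotone = monotone, fit = fit), class = "coxFit")
}

#' @export
print.coxFit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties), %d patients, %d events%s\n",
              x$ties, x$n, x$nEvents,
              if (x$monotone) " [monotone likelihood flagged]" else ""))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %s: HR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                tb$term[i], tb$hr[i], tb$ci_lo[i], tb$ci_hi[i], tb$p[i]))
  }
  invisible(x)
}

#' Histology subsets for the survival analyses
#'
#' Presets mirroring the reported survival panels: `"ec"` = all cancers
#' plus precursors entering the survival analysis (EM G1-G3 and Others),
#' `"em"` = endometrioid carcinoma G1-G3, `"em_g2_g3"` = endometrioid
#' G2-G3 only.
#'
#' @param x a [CytometryExperiment-class].
#' @param subset `"ec"`, `"em"`, or `"em_g2_g3"`.
#' @return logical vector selecting the patients of the subset.
#' @export
survivalSubset <- function(x, subset = c("ec", "em", "em_g2_g3")) {
  subset <- match.arg(subset)
  h <- as.character(histologyClass(x))
  keep <- switch(subset,
    ec = h %in% c("EM_G1", "EM_G2", "EM_G3", "Others"),
    em = h %in% c("EM_G1", "EM_G2", "EM_G3"),
    em_g2_g3 = h %in% c("EM_G2", "EM_G3")
  )
  keep
}
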