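#' Full-study configuration
#'
#' Bundles the synthetic-cohort configuration with every analysis default
#' in one place, so each choice the pipeline makes (threshold method,
#' minimum particle area, box sizes, tie handling, cutpoint settings) is
#' explicit and logged in the report.
#'
#' @param cohort a [cohortConfig()].
#' @param seed master seed; overrides the cohort config seed.
#' @param defaults named list overriding the analysis defaults:
#'   `threshold` ("isodata"), `minArea` (64), `boxSizes`, `features`
#'   (descriptors analyzed by the ROC stage), `survFeatures` (markers run
#'   through the survival stage with their risk orientation), `adjusters`,
#'   `subsets`, `minGroupFrac` (0.10), `ties` ("efron"), `cutpointB`
#'   (permutations for the min-p correction).
#' @return list of class `studyConfig`.
#' @export
studyConfig <- function(cohort = cohortConfig(), seed = NULL,
                        defaults = list()) {
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  base <- list(
    threshold = "isodata",
    minArea = 64,
    boxSizes = c(2, 3, 4, 6, 8, 12, 16, 32, 64),
    features = c("perimeter", "fit_ellipse_major", "fit_ellipse_minor",
                 "angle", "circularity", "feret_max", "feret_min",
                 "solidity", "fractal_dimension"),
    survFeatures = c(circularity = "low", solidity = "low",
                     fractal_dimension = "high"),
    adjusters = c("age55", "cytologyPos"),
    subsets = c("ec", "em", "em_g2_g3"),
    minGroupFrac = 0.10,
    ties = "efron",
    cutpointB = 200L
  )
  structure(list(cohort = cohort,
                 defaults = modifyList(base, defaults)),
            class = "studyConfig")
}

#' Diagnostic stage: logistic, ROC, and combined-score comparisons
#'
#' Runs, for each requested specimen feature: unadjusted and adjusted
#' (age >= 55, dichotomized cytology) logistic odds ratios; the ROC with
#' DeLong CI and Youden cutoff; and for circularity, solidity and fractal
#' dimension the paired DeLong comparison of cytology alone versus
#' cytology plus the feature (in-sample combined score).
#'
#' @param cohort a [CytometryExperiment-class].
#' @param features descriptor names to analyze.
#' @return list with `logistic` (rows per feature x adjustment), `roc`
#'   (list of [rocCurve()] results), `combined` (paired comparisons).
#' @export
diagnoseCohort <- function(cohort,
                           features = c("circularity", "solidity",
                                        "fractal_dimension")) {
  di <- dichotomize(cohort)
  if (length(unique(di$label)) < 2) {
    stop("diagnostic stage requires both diagnostic classes")
  }
  feats <- morphometry(cohort)
  features <- intersect(features, rownames(feats))
  logistic <- list(); roc <- list(); combined <- list()
  for (f in features) {
    x <- feats[f, ]
    un <- fitLogisticOR(di$label, x)
    ad <- fitLogisticOR(di$label, x,
                        covariates = di[, c("age55", "cytologyPos")])
    logistic[[f]] <- data.frame(
      feature = f,
      or_unadjusted = un$or, ci_lo_unadjusted = un$ci[1],
      ci_hi_unadjusted = un$ci[2], p_unadjusted = un$p,
      or_adjusted = ad$or, ci_lo_adjusted = ad$ci[1],
      ci_hi_adjusted = ad$ci[2], p_adjusted = ad$p
    )
    roc[[f]] <- rocCurve(x, di$label)
    if (f %in% c("circularity", "solidity", "fractal_dimension")) {
      cs <- combinedScore(di$label, di$cytologyPos, x)
      dl <- delongTest(cs$score, as.numeric(di$cytologyPos), di$label)
      combined[[f]] <- data.frame(
        feature = f, auc_combined = dl$aucA, auc_cytology = dl$aucB,
        p = dl$p
      )
    }
  }
  logistic <- do.call(rbind, logistic)
  combined <- do.call(rbind, combined)
  rownames(logistic) <- NULL
  rownames(combined) <- NULL
  list(logistic = logistic, roc = roc, combined = combined)
}

#' Prognostic stage: cutpoints, Kaplan-Meier, log-rank, Cox
#'
#' For each survival marker and histology subset: outcome-based optimal
#' cutpoint (with min-p corrected p), Kaplan-Meier step tables and
#' log-rank test of the resulting split, and univariable plus
#' multivariable Cox models. The multivariable model adjusts for
#' age >= 55, endometrioid histology, and the number of cell clusters.
#'
#' @param cohort a [CytometryExperiment-class].
#' @param features named character vector: marker name -> risk orientation
#'   (`"low"` or `"high"`).
#' @param subsets histology subset presets (see [survivalSubset()]).
#' @param minGroupFrac,ties,B cutpoint and Cox settings.
#' @param seed seed for the cutpoint permutations.
#' @return nested list `[[feature]][[subset]]` with `cutpoint`, `logrank`,
#'   `km`, `coxUni`, `coxMulti` (NULL where a stage is not estimable).
#' @export
prognoseCohort <- function(cohort,
                           features = c(circularity = "low",
                                        solidity = "low",
                                        fractal_dimension = "high"),
                           subsets = c("ec", "em", "em_g2_g3"),
                           minGroupFrac = 0.10, ties = "efron", B = 200L,
                           seed = 1L) {
  feats <- morphometry(cohort)
  cd <- as.data.frame(colData(cohort))
  out <- list()
  for (f in names(features)) {
    out[[f]] <- list()
    for (s in subsets) {
      keep <- survivalSubset(cohort, s)
      res <- NULL
      if (sum(keep) >= 10 && sum(cd$event[keep]) >= 2) {
        x <- feats[f, keep]
        tm <- cd$time_months[keep]; ev <- cd$event[keep]
        res <- tryCatch({
          cp <- optimalCutpoint(x, tm, ev, minGroupFrac = minGroupFrac,
                                orientation = features[[f]], B = B,
                                seed = deriveSeed(seed, f, s))
          grp <- ifelse(x <= cp$cutoff, "low", "high")
          lr <- logrankTest(tm, ev, grp)
          km <- kmEstimate(tm, ev, grp)
          hOther <- as.character(cd$histology[keep]) %in%
            c("EM_G1", "EM_G2", "EM_G3")
          uni <- coxFit(data.frame(marker = x), tm, ev, ties = ties)
          multi <- tryCatch(coxFit(data.frame(
            marker = x,
            age55 = cd$age[keep] >= 55,
            endometrioid = hOther,
            cluster_count = feats["cluster_count", keep]
          ), tm, ev, ties = ties), error = function(e) NULL)
          list(cutpoint = cp, logrank = lr, km = km, coxUni = uni,
               coxMulti = multi)
        }, error = function(e) list(error = conditionMessage(e)))
      }
      out[[f]][[s]] <- res
    }
  }
  out
}

#' Run the full synthetic study end to end
#'
#' simulate -> extract -> diagnose -> prognose, producing one report
#' bundle: the cohort characteristics table (class counts, ages, cytology
#' cross-tab), the logistic association table, per-descriptor ROC
#' summaries, the cytology-combination comparisons, and the survival
#' results, plus a log of every analysis default used. Deterministic for
#' a fixed config: the same config and seed give an identical report.
#'
#' @param config a [studyConfig()].
#' @param cohort optionally, a pre-generated [CytometryExperiment-class]
#'   (skips simulation; used to re-run analyses on cached output).
#' @param verbose print stage progress.
#' @return list of class `studyReport` with elements `characteristics`,
#'   `logistic`, `roc`, `combined`, `survival`, `defaults`, `seed`,
#'   and `cohort`.
#' @export
runFullStudy <- function(config = studyConfig(), cohort = NULL,
                         verbose = FALSE) {
  d <- config$defaults
  if (is.null(cohort)) {
    if (verbose) message("simulate + extract: ",
                         sum(config$cohort$counts), " patients")
    cohort <- generateCohort(config$cohort, verbose = verbose)
  }
  cd <- as.data.frame(colData(cohort))
  characteristics <- list(
    counts = table(cd$histology),
    age = do.call(rbind, lapply(split(cd$age, cd$histology), function(a) {
      data.frame(mean = mean(a), sd = sd(a), n = length(a))
    })),
    cytology = table(cd$cytology, cd$histology)
  )
  if (verbose) message("diagnose")
  diag <- diagnoseCohort(cohort, features = d$features)
  if (verbose) message("prognose")
  prog <- prognoseCohort(cohort, features = d$survFeatures,
                         subsets = d$subsets,
                         minGroupFrac = d$minGroupFrac, ties = d$ties,
                         B = d$cutpointB,
                         seed = deriveSeed(config$cohort$seed, "cutpoint"))
  structure(list(
    characteristics = characteristics,
    logistic = diag$logistic,
    roc = diag$roc,
    combined = diag$combined,
    survival = prog,
    defaults = d,
    seed = config$cohort$seed,
    cohort = cohort
  ), class = "studyReport")
}

#' Write a study report bundle to disk
#'
#' JSON report (tables, ROC summaries, survival results, defaults) plus
#' the cohort CSV.
#'
#' @param report a `studyReport` from [runFullStudy()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rocSummary <- lapply(report$roc, function(r) {
    list(auc = r$auc, ci = r$ci, cutoff = r$cutoff,
         sensitivity = r$sensitivity, specificity = r$specificity,
         direction = r$direction)
  })
  survSummary <- lapply(report$survival, function(bySub) {
    lapply(bySub, function(s) {
      if (is.null(s) || !is.null(s$error)) return(s)
      list(cutoff = s$cutpoint$cutoff, chisq = s$cutpoint$chisq,
           p = s$cutpoint$p, pCorrected = s$cutpoint$pCorrected,
           nLow = s$cutpoint$nLow, nHigh = s$cutpoint$nHigh,
           logrank_p = s$logrank$p,
           coxUni = s$coxUni$table,
           coxMulti = if (!is.null(s$coxMulti)) s$coxMulti$table)
    })
  })
  obj <- list(
    characteristics = list(
      counts = as.list(report$characteristics$counts),
      age = report$characteristics$age,
      cytology = as.data.frame.matrix(report$characteristics$cytology)
    ),
    logistic = report$logistic,
    roc = rocSummary,
    combined = report$combined,
    survival = survSummary,
    defaults = report$defaults,
    seed = report$seed
  )
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeCohortCSV(report$cohort, file.path(dir, "cohort.csv"))
  invisible(dir)
}

#' @export
print.studyReport <- function(x, ...) {
  cat("Synthetic cytology study report (seed", x$seed, ")\n")
  cat("patients:", ncol(x$cohort), " events:",
      sum(colData(x$cohort)$event), "\n")
  cat("ROC AUCs:\n")
  for (f in names(x$roc)) {
    cat(sprintf("  %-18s %.3f (%.3f-%.3f)\n", f, x$roc[[f]]$auc,
                x$roc[[f]]$ci[1], x$roc[[f]]$ci[2]))
  }
  invisible(x)
}
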