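# 3x3 binary dilation, used to keep a 1-px gap between placed clusters
.dilate1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  out <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  for (dr in -1:1) for (dc in -1:1) {
    out[(2 - dr):(nr + 1 - dr), (2 - dc):(nc + 1 - dc)] <-
      out[(2 - dr):(nr + 1 - dr), (2 - dc):(nc + 1 - dc)] | p[2:(nr + 1), 2:(nc + 1)]
  }
  out[2:(nr + 1L), 2:(nc + 1L)]
}

# run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline consumes a seed derived
#' deterministically from the master seed and a stage tag, so one master
#' seed reproduces the whole study.
#'
#' @param master integer master seed.
#' @param ... character or integer tags identifying the stage.
#' @return integer seed in 1 .. 2^31 - 2.
#' @export
deriveSeed <- function(master, ...) {
  s <- as.numeric(master) %% 2147483647
  for (tag in unlist(list(...))) {
    codes <- if (is.character(tag)) utf8ToInt(tag) else as.integer(tag)
    for (cd in codes) s <- (s * 31 + cd) %% 2147483647
  }
  as.integer(s %% 2147483645 + 1)
}

#' Rasterize a synthetic cell-cluster mask
#'
#' Draws the star-shaped boundary \eqn{r(\theta) = R_e(\theta)(1 + a \sum_k
#' k^{-\beta}(u_k \cos k\theta + v_k \sin k\theta))} defined by a
#' [ClusterShapeParams-class] and fills it on a square canvas. The harmonic
#' coefficients \eqn{u_k, v_k} are standard-normal draws fixed by the
#' params' seed, so the mask is fully deterministic. With zero roughness
#' the boundary is an exact ellipse.
#'
#' @param params a [ClusterShapeParams-class] (or [shapeParams()] call).
#' @param canvas canvas side length in pixels; by default just large
#'   enough to contain the shape.
#' @return logical matrix with attributes `center` (row, col) and
#'   `radiusRange`.
#' @section Errors: if the perturbation drives \eqn{r(\theta) \le 0}
#' anywhere (roughness too large for the base radius), an error is raised.
#' @examples
#' m <- generateClusterMask(shapeParams(baseRadius = 30, seed = 7))
#' sum(m) / (pi * 30^2)  # close to 1
#' @export
generateClusterMask <- function(params, canvas = NULL) {
  stopifnot(is(params, "ClusterShapeParams"))
  a <- params@baseRadius
  b <- a * sqrt(1 - params@eccentricity^2)
  K <- params@nHarmonics
  amp <- params@roughnessAmplitude
  if (K > 0) {
    uv <- .withSeed(params@seed, rnorm(2L * K))
    u <- uv[seq_len(K)]; v <- uv[K + seq_len(K)]
    w <- seq_len(K)^(-params@roughnessExponent)
  }
  radius <- function(theta) {
    base <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    if (amp == 0 || K == 0) return(base)
    ct <- cos(outer(theta, seq_len(K)))
    st <- sin(outer(theta, seq_len(K)))
    base * (1 + amp * as.vector(ct %*% (w * u) + st %*% (w * v)))
  }
  thetaGrid <- seq(0, 2 * pi, length.out = 2048L)
  rg <- radius(thetaGrid)
  if (min(rg) <= 0) {
    stop("roughness too large for base radius: boundary radius <= 0")
  }
  rmax <- max(rg)
  if (is.null(canvas)) canvas <- 2L * ceiling(rmax) + 3L
  if (canvas < 2 * rmax) {
    stop("canvas too small to contain the cluster boundary")
  }
  cx <- (canvas + 1) / 2
  rows <- matrix(seq_len(canvas), canvas, canvas)
  cols <- matrix(seq_len(canvas), canvas, canvas, byrow = TRUE)
  dy <- -(rows - cx); dx <- cols - cx
  d <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  inside <- matrix(FALSE, canvas, canvas)
  cand <- d <= rmax + 1
  inside[cand] <- d[cand] <= radius(th[cand])
  # star-shaped in the continuum; rasterization can pinch off slivers at
  # sharp spikes, so keep the component containing the center
  lab <- labelClusters(inside, connectivity = 8, minArea = 1)
  ctr <- lab[round(cx), round(cx)]
  if (ctr == 0L) ctr <- which.max(tabulate(lab[lab > 0L]))
  structure(lab == ctr, center = c(cx, cx), radiusRange = range(rg))
}

# class-conditional morphology: malignant specimens shed more, larger and
# more irregular clusters; benign clusters are smooth and near-elliptical
.CLASS_SHAPE_DEFAULTS <- list(
  Normal = list(radius = c(9, 16),    ecc = c(0.0, 0.40), amp = c(0.02, 0.08), beta = 2.0, lambda = 4.0),
  EH     = list(radius = c(9, 16),    ecc = c(0.0, 0.40), amp = c(0.02, 0.10), beta = 2.0, lambda = 4.0),
  AEH    = list(radius = c(9.6, 17.2),  ecc = c(0.2, 0.60), amp = c(0.10, 0.24), beta = 1.6, lambda = 4.8),
  EM_G1  = list(radius = c(10.2, 18.3), ecc = c(0.2, 0.65), amp = c(0.14, 0.30), beta = 1.6, lambda = 5.12),
  EM_G2  = list(radius = c(10.7, 19.5), ecc = c(0.2, 0.70), amp = c(0.18, 0.36), beta = 1.5, lambda = 5.49),
  EM_G3  = list(radius = c(11.2, 20.6), ecc = c(0.2, 0.70), amp = c(0.22, 0.42), beta = 1.5, lambda = 5.86),
  Others = list(radius = c(11.2, 20.6), ecc = c(0.2, 0.70), amp = c(0.22, 0.42), beta = 1.5, lambda = 5.86)
)

#' Synthetic cohort configuration
#'
#' Assembles the configuration of the synthetic cytology cohort generator.
#' Defaults are calibrated to the reported clinical cohort: per-class
#' patient counts 92/13/17/43/18/10/7 (Normal, EH, AEH, EM G1-G3, Others),
#' class-conditional age means (SD) of 49.9 (12.2), 45.9 (6.9), 46.2
#' (10.6), 59.2 (10.6), 63.1 (13.8), 60.3 (8.0), 63.4 (13.6) years, and the
#' class-conditional three-tier cytology frequencies of the same cohort.
#' Cluster morphology is class-conditional: benign classes draw smooth,
#' nearly elliptical clusters (low roughness amplitude), malignant classes
#' increasingly irregular, protruding boundaries (higher amplitude, slower
#' harmonic decay).
#'
#' @param counts named integer vector of patients per histology class.
#' @param ageMean,ageSD named numeric vectors per class (years).
#' @param cytologyProbs class x category matrix of cytology probabilities
#'   (rows sum to 1).
#' @param shape per-class list of morphology ranges (`radius`, `ecc`,
#'   `amp` as c(lo, hi); scalars `beta` and `lambda`, the class's Poisson
#'   mean clusters per field).
#' @param clustersPerField fallback Poisson mean of the clusters-per-field
#'   count for classes without their own `lambda`.
#' @param fieldSize field side length in pixels.
#' @param gray foreground/background gray levels: list(fgMean, fgSD,
#'   bgMean, bgSD); clusters are dark objects on a bright background.
#' @param survival list: `beta` named log-hazard coefficients per standardized
#'   specimen feature, `baselineRate` events/month, `censorRate`
#'   censoring hazard/month, `adminTime` administrative censoring horizon
#'   (months).
#' @param nHarmonics harmonics in the boundary perturbation.
#' @param patientSD standard deviation of the patient-level roughness
#'   offset (between-patient heterogeneity within a histology class).
#' @param seed master seed.
#' @return list of class `cohortConfig`.
#' @export
cohortConfig <- function(counts = c(Normal = 92L, EH = 13L, AEH = 17L,
                                    EM_G1 = 43L, EM_G2 = 18L, EM_G3 = 10L,
                                    Others = 7L),
                         ageMean = c(Normal = 49.9, EH = 45.9, AEH = 46.2,
                                     EM_G1 = 59.2, EM_G2 = 63.1,
                                     EM_G3 = 60.3, Others = 63.4),
                         ageSD = c(Normal = 12.2, EH = 6.9, AEH = 10.6,
                                   EM_G1 = 10.6, EM_G2 = 13.8, EM_G3 = 8.0,
                                   Others = 13.6),
                         cytologyProbs = NULL,
                         shape = .CLASS_SHAPE_DEFAULTS,
                         clustersPerField = 5,
                         fieldSize = 256L,
                         gray = list(fgMean = 80, fgSD = 8,
                                     bgMean = 215, bgSD = 6),
                         survival = list(
                           beta = c(circularity = -0.8, solidity = -0.5,
                                    fractal_dimension = 0.6),
                           baselineRate = 0.004, censorRate = 0.008,
                           adminTime = 120),
                         nHarmonics = 24L,
                         patientSD = 0.05,
                         seed = 20260923L) {
  if (is.null(cytologyProbs)) {
    # class-conditional cytology cross-tabulation of the reference cohort
    tab <- rbind(
      Normal = c(25, 57, 10), EH = c(1, 9, 3), AEH = c(0, 11, 6),
      EM_G1 = c(0, 11, 32), EM_G2 = c(0, 3, 15), EM_G3 = c(0, 0, 10),
      Others = c(0, 0, 7)
    )
    cytologyProbs <- tab / rowSums(tab)
    colnames(cytologyProbs) <- .CYTOLOGY_LEVELS
  }
  stopifnot(all(counts >= 0), all(abs(rowSums(cytologyProbs) - 1) < 1e-8))
  structure(list(
    counts = counts, ageMean = ageMean, ageSD = ageSD,
    cytologyProbs = cytologyProbs, shape = shape,
    clustersPerField = clustersPerField, fieldSize = as.integer(fieldSize),
    gray = gray, survival = survival, nHarmonics = as.integer(nHarmonics),
    patientSD = patientSD, seed = as.integer(seed)
  ), class = "cohortConfig")
}

#' Generate one synthetic microscope field
#'
#' Draws the number of clusters from the configured Poisson distribution,
#' samples class-conditional shape parameters, rasterizes each cluster and
#' places them without overlap (bounded retries), then renders dark
#' clusters on a bright noisy background as an 8-bit grayscale image. The
#' ground-truth cluster masks are kept in the field's `info` for testing.
#'
#' @param config a [cohortConfig()].
#' @param class histology class name (one of the seven levels).
#' @param fieldIndex 1..5.
#' @param seed integer seed for this field.
#' @param nClusters override the drawn cluster count (e.g. 0 for an empty
#'   field).
#' @param specimenId specimen identifier.
#' @param ampShift patient-level offset added to the class roughness
#'   amplitude range (biological heterogeneity between patients of the
#'   same class; shared by all fields of one specimen).
#' @return a [CytoField-class]; `info$truth` holds one logical mask per
#'   placed cluster, `info$shapeParams` the sampled parameters.
#' @export
generateField <- function(config, class, fieldIndex = 1L, seed = 1L,
                          nClusters = NULL, specimenId = "specimen",
                          ampShift = 0) {
  stopifnot(class %in% names(config$shape))
  sh <- config$shape[[class]]
  sh$amp <- pmax(sh$amp + ampShift, 0.005)
  sz <- config$fieldSize
  lambda <- if (!is.null(sh$lambda)) sh$lambda else config$clustersPerField
  .withSeed(seed, {
    n <- if (is.null(nClusters)) rpois(1, lambda) else nClusters
    placed <- list()
    params <- list()
    occupied <- matrix(FALSE, sz, sz)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:60) {
        p <- shapeParams(
          baseRadius = runif(1, sh$radius[1], sh$radius[2]),
          eccentricity = runif(1, sh$ecc[1], sh$ecc[2]),
          roughnessAmplitude = runif(1, sh$amp[1], sh$amp[2]),
          roughnessExponent = sh$beta,
          nHarmonics = config$nHarmonics,
          seed = sample.int(2147483646L, 1)
        )
        m <- tryCatch(generateClusterMask(p), error = function(e) NULL)
        if (is.null(m)) next
        mr <- nrow(m)
        if (mr >= sz - 2) next
        r0 <- sample.int(sz - mr + 1L, 1)
        c0 <- sample.int(sz - mr + 1L, 1)
        region <- occupied[r0:(r0 + mr - 1L), c0:(c0 + mr - 1L)]
        if (!any(region & .dilate1(m))) {
          full <- matrix(FALSE, sz, sz)
          full[r0:(r0 + mr - 1L), c0:(c0 + mr - 1L)] <- m
          occupied <- occupied | full
          placed[[length(placed) + 1L]] <- full
          params[[length(params) + 1L]] <- p
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place cluster ", i, " without overlap")
    }
    g <- config$gray
    gray <- matrix(rnorm(sz * sz, g$bgMean, g$bgSD), sz, sz)
    if (length(placed)) {
      fg <- which(occupied)
      gray[fg] <- rnorm(length(fg), g$fgMean, g$fgSD)
    }
    gray <- pmin(pmax(round(gray), 0), 255)
    CytoField(gray, fieldIndex = fieldIndex, specimenId = specimenId,
              info = list(truth = placed, shapeParams = params,
                          class = class, seed = seed))
  })
}

#' Simulate overall survival from a linear predictor
#'
#' Exponential event times with hazard `baselineRate * exp(lp)`,
#' independent exponential censoring at `censorRate`, and administrative
#' censoring at `adminTime` months.
#'
#' @param lp numeric linear predictor (log relative hazard) per patient.
#' @param baselineRate baseline hazard, events per month.
#' @param censorRate censoring hazard per month.
#' @param adminTime administrative censoring horizon in months.
#' @param seed integer seed.
#' @return data.frame with `time_months` and logical `event`.
#' @export
simulateSurvival <- function(lp, baselineRate = 0.004, censorRate = 0.008,
                             adminTime = 120, seed = 1L) {
  n <- length(lp)
  .withSeed(seed, {
    tEvent <- rexp(n, rate = baselineRate * exp(lp))
    tCens <- pmin(rexp(n, rate = censorRate), adminTime)
    data.frame(time_months = pmin(tEvent, tCens), event = tEvent <= tCens)
  })
}

# class-conditional specimen-feature distributions for the feature-level
# generator; FD separation between pooled benign and pooled malignant+AEH
# classes is designed binormal (see generateFeatureCohort)
.FEATURE_LEVEL_DEFAULTS <- list(
  #             circ.mean circ.sd  sol.mean sol.sd  fd.mean fd.sd
  Normal = list(circ = c(0.86, 0.05), sol = c(0.92, 0.03), fd = c(1.300, 0.080)),
  EH     = list(circ = c(0.84, 0.05), sol = c(0.91, 0.03), fd = c(1.300, 0.080)),
  AEH    = list(circ = c(0.72, 0.08), sol = c(0.84, 0.05), fd = c(1.4172, 0.080)),
  EM_G1  = list(circ = c(0.68, 0.08), sol = c(0.82, 0.05), fd = c(1.4172, 0.080)),
  EM_G2  = list(circ = c(0.62, 0.09), sol = c(0.79, 0.06), fd = c(1.4172, 0.080)),
  EM_G3  = list(circ = c(0.56, 0.09), sol = c(0.76, 0.06), fd = c(1.4172, 0.080)),
  Others = list(circ = c(0.56, 0.09), sol = c(0.76, 0.06), fd = c(1.4172, 0.080))
)

#' Generate a feature-level synthetic cohort (no images)
#'
#' Draws specimen-level morphometric features directly from class-conditional
#' normal distributions instead of rendering and measuring field images.
#' This is the fast generator used for statistical calibration: the fractal
#' dimension of every benign patient (Normal, EH) is N(1.300, 0.080) and of
#' every positive-class patient (AEH and carcinomas) N(1.4172, 0.080), so
#' the design AUC separating the diagnostic classes is the binormal value
#' \eqn{\Phi(\Delta/\sqrt{\sigma_0^2+\sigma_1^2})} = 0.85 exactly.
#' Ages, cytology and survival follow the same model as [generateCohort()].
#'
#' @param config a [cohortConfig()]; counts, ages, cytology and survival
#'   settings are honored (shape/image settings are not used).
#' @param featureParams per-class feature distributions (mean, sd) for
#'   `circ`, `sol`, `fd`.
#' @return a [CytometryExperiment-class] whose morphometry assay has rows
#'   circularity, solidity, fractal_dimension.
#' @export
generateFeatureCohort <- function(config = cohortConfig(),
                                  featureParams = .FEATURE_LEVEL_DEFAULTS) {
  meta <- .drawClinical(config)
  n <- nrow(meta)
  fp <- featureParams
  draw <- function(which) {
    mus <- vapply(as.character(meta$histology), function(cl) fp[[cl]][[which]][1], 0)
    sds <- vapply(as.character(meta$histology), function(cl) fp[[cl]][[which]][2], 0)
    rnorm(n, mus, sds)
  }
  feats <- .withSeed(deriveSeed(config$seed, "features"), {
    circ <- pmin(pmax(draw("circ"), 0.05), 1)
    sol <- pmin(pmax(draw("sol"), 0.05), 1)
    fd <- pmin(pmax(draw("fd"), 0.3), 2)
    rbind(circularity = circ, solidity = sol, fractal_dimension = fd)
  })
  colnames(feats) <- meta$patient_id
  surv <- .survFromFeatures(feats, config)
  meta$time_months <- surv$time_months
  meta$event <- surv$event
  CytometryExperiment(feats, meta[, c("age", "cytology", "histology",
                                      "time_months", "event")],
                      metadata = list(config = config, generator = "feature"))
}

# shared clinical draw: class, age (truncated normal >= 18), cytology
.drawClinical <- function(config) {
  cls <- rep(names(config$counts), times = config$counts)
  n <- length(cls)
  .withSeed(deriveSeed(config$seed, "clinical"), {
    age <- vapply(cls, function(cl) {
      repeat {
        a <- rnorm(1, config$ageMean[[cl]], config$ageSD[[cl]])
        if (a >= 18) return(a)
      }
    }, numeric(1))
    cyt <- vapply(cls, function(cl) {
      sample(.CYTOLOGY_LEVELS, 1, prob = config$cytologyProbs[cl, ])
    }, character(1))
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = age, cytology = cyt, histology = cls,
      time_months = NA_real_, event = NA,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
}

# survival times from standardized (circularity, solidity, fd) rows
.survFromFeatures <- function(feats, config) {
  sv <- config$survival
  zrow <- function(r) {
    v <- feats[r, ]
    s <- sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  lp <- rep(0, ncol(feats))
  for (nm in names(sv$beta)) {
    if (nm %in% rownames(feats)) lp <- lp + sv$beta[[nm]] * zrow(nm)
  }
  simulateSurvival(lp, baselineRate = sv$baselineRate,
                   censorRate = sv$censorRate, adminTime = sv$adminTime,
                   seed = deriveSeed(config$seed, "survival"))
}

#' Generate a full synthetic cytology cohort with field images
#'
#' For each patient: histology class from the configured counts, age from
#' the class-conditional truncated normal (>= 18 years), cytology from the
#' class-conditional three-tier distribution; five field images rendered
#' with [generateField()]; specimen features measured by the package's own
#' extraction pipeline ([extractFeatures()]); and overall survival times
#' from an exponential model whose log-hazard is linear in the
#' standardized measured circularity, solidity and fractal dimension.
#' Fully seeded: the same config yields the identical cohort.
#'
#' @param config a [cohortConfig()].
#' @param imageDir optional directory; when given, field images and
#'   ground-truth masks are written there as PNG.
#' @param keepImages keep the [CytoField-class] objects in the result
#'   metadata (memory-heavy; default FALSE).
#' @param verbose print progress every 25 patients.
#' @return a [CytometryExperiment-class] (11 morphometry rows x patients).
#' @export
generateCohort <- function(config = cohortConfig(), imageDir = NULL,
                           keepImages = FALSE, verbose = FALSE) {
  meta <- .drawClinical(config)
  n <- nrow(meta)
  featRows <- c(.FEATURE_NAMES)
  feats <- matrix(NA_real_, length(featRows), n,
                  dimnames = list(featRows, meta$patient_id))
  fieldsKept <- if (keepImages) vector("list", n) else NULL
  if (!is.null(imageDir)) dir.create(imageDir, showWarnings = FALSE,
                                     recursive = TRUE)
  patientSD <- if (is.null(config$patientSD)) 0.05 else config$patientSD
  for (i in seq_len(n)) {
    pid <- meta$patient_id[i]
    shift <- .withSeed(deriveSeed(config$seed, "patient", pid),
                       rnorm(1, 0, patientSD))
    flds <- lapply(1:5, function(f) {
      generateField(config, class = meta$histology[i], fieldIndex = f,
                    seed = deriveSeed(config$seed, "field", pid, f),
                    specimenId = pid, ampShift = shift)
    })
    ex <- extractFeatures(flds)
    feats[, i] <- unlist(ex$specimen[1, featRows])
    if (!is.null(imageDir)) {
      for (f in flds) writeFieldImage(f, file.path(
        imageDir, sprintf("%s_field%d.png", pid, f@fieldIndex)))
    }
    if (keepImages) fieldsKept[[i]] <- flds
    if (verbose && i %% 25 == 0) message("  patient ", i, "/", n)
  }
  surv <- .survFromFeatures(feats, config)
  meta$time_months <- surv$time_months
  meta$event <- surv$event
  md <- list(config = config, generator = "image")
  if (keepImages) md$fields <- fieldsKept
  CytometryExperiment(feats, meta[, c("age", "cytology", "histology",
                                      "time_months", "event")],
                      metadata = md)
}
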