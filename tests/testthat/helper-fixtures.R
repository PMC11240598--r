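# in-code fixtures and independent oracles shared across tests

rasterDisk <- function(r, size = 2 * r + 11) {
  cx <- (size + 1) / 2
  outer(seq_len(size), seq_len(size),
        function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
}

# square of continuum side s rotated by `deg`, rasterized on pixel centers
rasterRotSquare <- function(s, deg, size = ceiling(s * 2) + 11) {
  cx <- (size + 1) / 2
  th <- deg * pi / 180
  outer(seq_len(size), seq_len(size), function(i, j) {
    x <- j - cx; y <- i - cx
    xr <- cos(th) * x + sin(th) * y
    yr <- -sin(th) * x + cos(th) * y
    abs(xr) <= s / 2 & abs(yr) <= s / 2
  })
}

# irregular but reproducible blob
randomBlob <- function(seed, r = 20, amp = 0.25) {
  generateClusterMask(shapeParams(baseRadius = r, roughnessAmplitude = amp,
                                  roughnessExponent = 1.5, seed = seed))
}

# two-level test image: objects at `lo`, background at `hi`
twoLevelImage <- function(lo = 40, hi = 220, size = 64) {
  g <- matrix(hi, size, size)
  g[10:20, 10:20] <- lo
  g[40:55, 30:50] <- lo
  g
}

# drop the provenance attributes binarize() attaches, keeping the mask
justMask <- function(m) matrix(as.vector(m), nrow(m))

# 4-neighborhood erosion; m & !erode4(m) is the inner boundary
.erode4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  p[1:nr, 2:(nc + 1)] & p[3:(nr + 2), 2:(nc + 1)] &
    p[2:(nr + 1), 1:nc] & p[2:(nr + 1), 3:(nc + 2)] & m
}

# brute-force pairwise AUC (Mann-Whitney with half ties)
bruteAUC <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# brute-force minimum projection width over a fine angle sweep
bruteMinWidth <- function(pts, stepDeg = 1) {
  angles <- seq(0, 180 - stepDeg, by = stepDeg) * pi / 180
  widths <- vapply(angles, function(a) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  min(widths)
}

# exhaustive isodata oracle: scan all 256 thresholds and return the
# intermeans fixed points (thresholds where t crosses the class-mean
# midpoint from below)
.intermeansMid <- function(h, t) {
  v <- 0:255
  lo <- v <= t
  if (sum(h[lo]) == 0 || sum(h[!lo]) == 0) return(Inf)
  (sum(h[lo] * v[lo]) / sum(h[lo]) + sum(h[!lo] * v[!lo]) / sum(h[!lo])) / 2
}

isodataFixedPoints <- function(gray) {
  h <- tabulate(as.integer(round(gray)) + 1L, nbins = 256L)
  sat <- vapply(0:254, function(t) t >= .intermeansMid(h, t), logical(1))
  which(sat & !c(FALSE, sat[-255])) - 1L
}

# per-cutpoint log-rank oracle using survival::survdiff
survdiffScan <- function(feature, time, event, cuts) {
  vapply(cuts, function(cc) {
    g <- factor(feature <= cc, levels = c(FALSE, TRUE))
    if (length(unique(g)) < 2) return(0)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    unname(sd$chisq)
  }, numeric(1))
}

# Cox partial log-likelihood for one covariate, no ties assumed
coxPartialLik <- function(beta, x, time, event) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- as.logical(event)[ord]
  n <- length(x)
  ll <- 0
  for (i in which(event)) {
    atRisk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[atRisk])))
  }
  ll
}

# small survival dataset with a binary covariate effect
toySurvival <- function(n, betaTrue = 0, seed = 1, censorRate = 0.3) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = 0.1 * exp(betaTrue * x))
  c0 <- rexp(n, rate = 0.1 * censorRate / (1 - censorRate))
  list(x = x, time = pmin(t, c0), event = t <= c0)
}

tinyCohortConfig <- function(seed = 11) {
  cohortConfig(counts = c(Normal = 7L, EH = 1L, AEH = 2L, EM_G1 = 3L,
                          EM_G2 = 2L, EM_G3 = 1L, Others = 1L),
               seed = seed)
}
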