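#' Trace the boundary of a connected component
#'
#' Moore-neighbor tracing with Jacob's stopping criterion, clockwise in
#' image coordinates (rows increase downward), starting at the
#' topmost-then-leftmost foreground pixel. Returns the ordered boundary
#' pixel coordinates and the 8-direction chain code (0 = east, codes
#' increase clockwise; even codes are axial moves, odd codes diagonal).
#'
#' A single-pixel component has an empty chain (degenerate, flagged via the
#' `degenerate` attribute).
#'
#' @param mask logical matrix containing exactly one connected component.
#' @return integer matrix of boundary pixels (columns `row`, `col`) in
#'   traversal order, with attributes `chain` (integer vector of direction
#'   codes) and `degenerate`.
#' @export
traceBoundary <- function(mask) {
  if (!any(mask)) stop("empty component")
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # topmost-then-leftmost foreground pixel
  idx <- which(t(m))  # raster order scan
  first <- idx[1]
  srow <- (first - 1L) %/% (nc + 2L) + 1L
  scol <- first - (srow - 1L) * (nc + 2L)
  start <- c(srow, scol)
  # directions clockwise from east, image coords (row down)
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  path <- matrix(0L, 4L * sum(m) + 8L, 2L)
  chain <- integer(nrow(path))
  path[1L, ] <- start
  np <- 1L
  cur <- start
  d <- 0L          # pretend we arrived at start moving east
  firstMove <- -1L
  repeat {
    s <- (d + 6L) %% 8L
    nd <- -1L
    for (k in 0:7) {
      cand <- (s + k) %% 8L
      if (m[cur[1] + dr[cand + 1L], cur[2] + dc[cand + 1L]]) { nd <- cand; break }
    }
    if (nd < 0L) break  # isolated pixel
    if (firstMove < 0L) {
      firstMove <- nd
    } else if (cur[1] == start[1] && cur[2] == start[2] && nd == firstMove) {
      break  # re-entered the initial cycle (Jacob's criterion)
    }
    cur <- c(cur[1] + dr[nd + 1L], cur[2] + dc[nd + 1L])
    np <- np + 1L
    path[np, ] <- cur
    chain[np - 1L] <- nd
    d <- nd
  }
  nchain <- np - 1L
  # drop the final duplicate of the start pixel (closed chain)
  if (np > 1L) np <- np - 1L
  out <- path[seq_len(np), , drop = FALSE] - 1L  # unpad
  colnames(out) <- c("row", "col")
  structure(out, chain = chain[seq_len(max(nchain, 0L))],
            degenerate = nchain == 0L)
}

#' Perimeter of a closed chain code
#'
#' Chain-code length with sqrt(2) weighting: axial (even-code) steps count
#' 1, diagonal (odd-code) steps sqrt(2). Degenerate components fall back to
#' their unit-cell boundary: a single pixel has perimeter 4, a two-pixel
#' domino 6 (a diagonal pair 8), which keeps circularity finite.
#'
#' @param chain integer vector of 8-direction codes (attribute of
#'   [traceBoundary()]), or the traced boundary itself.
#' @param nPixels component area in pixels, used for the degenerate
#'   fallbacks; required when `chain` is empty or has < 3 steps.
#' @param axialAdjacent for the two-pixel fallback: TRUE if the pixels
#'   share an edge.
#' @return perimeter in pixels.
#' @export
chainPerimeter <- function(chain, nPixels = NULL, axialAdjacent = TRUE) {
  if (is.matrix(chain)) chain <- attr(chain, "chain")
  if (is.null(nPixels)) nPixels <- Inf
  if (nPixels == 1 || length(chain) == 0) return(4)
  if (nPixels == 2) return(if (axialAdjacent) 6 else 8)
  diag <- sum(chain %% 2L == 1L)
  (length(chain) - diag) + diag * sqrt(2)
}

#' Circularity of a particle
#'
#' `4 * pi * area / perimeter^2`, capped at 1 (digitization can push the
#' raw ratio slightly above 1 for near-circular particles).
#' @param area particle area (> 0).
#' @param perimeter particle perimeter (> 0).
#' @return circularity in (0, 1\].
#' @examples
#' circularity(pi * 50^2, 2 * pi * 50)   # continuum disk -> 1
#' circularity(20^2, 4 * 20)             # continuum square -> pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0)) stop("area and perimeter must be > 0")
  pmin(1, 4 * pi * area / perimeter^2)
}

# convex hull of the pixel-corner point set; columns x, y in pixel units
# (x = col, y = row). Vertices in traversal order.
.pixelHull <- function(px) {
  x <- c(px[, "col"] - 0.5, px[, "col"] + 0.5, px[, "col"] - 0.5, px[, "col"] + 0.5)
  y <- c(px[, "row"] - 0.5, px[, "row"] - 0.5, px[, "row"] + 0.5, px[, "row"] + 0.5)
  pts <- unique(cbind(x = x, y = y))
  h <- chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]
}

.polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Convex hull and solidity of a component
#'
#' The hull is taken over the pixel-corner point set (each pixel
#' contributes its four unit-square corners), so a convex digital shape
#' has solidity exactly its pixel area over the hull polygon (shoelace)
#' area. Solidity is capped at 1.
#'
#' @param px integer matrix of component pixels (columns `row`, `col`), or
#'   a logical mask of one component.
#' @return list with `hull` (vertex matrix, columns x, y), `hullArea`, and
#'   `solidity`; `degenerate` is TRUE when the hull is collinear.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2:4, 3] <- TRUE; m[3, 2:4] <- TRUE  # plus sign
#' convexSolidity(m)$solidity  # 5/7
#' @export
convexSolidity <- function(px) {
  if (is.logical(px)) px <- which(px, arr.ind = TRUE)
  colnames(px) <- c("row", "col")
  if (nrow(px) == 0) stop("empty component")
  hull <- .pixelHull(px)
  ha <- .polygonArea(hull)
  degenerate <- nrow(hull) < 3 || ha <= 0
  list(hull = hull, hullArea = ha,
       solidity = if (degenerate) NA_real_ else min(1, nrow(px) / ha),
       degenerate = degenerate)
}

#' Moment-based ellipse fit of a component
#'
#' Fits the ellipse with the same second central moments as the pixel set
#' (each pixel treated as a unit square, adding 1/12 to both axial
#' moments), then rescales the axes so the ellipse area equals the pixel
#' area: for eigenvalues `l1 >= l2` of the moment matrix the unscaled
#' semi-axes are `2*sqrt(l1)` and `2*sqrt(l2)`, multiplied by
#' `sqrt(A / (pi * 4 * sqrt(l1 * l2)))`. The angle is the orientation of
#' the major axis in degrees, measured counterclockwise from the x axis
#' (image rows pointing down are flipped so angles follow the usual
#' mathematical convention), in \[0, 180).
#'
#' @inheritParams convexSolidity
#' @return list with `major`, `minor` (full axis lengths, px), `angle`
#'   (degrees in \[0, 180)), and `degenerate` (TRUE for collinear pixels).
#' @export
fitEllipse <- function(px) {
  if (is.logical(px)) px <- which(px, arr.ind = TRUE)
  colnames(px) <- c("row", "col")
  n <- nrow(px)
  if (n < 2) {
    return(list(major = 2 / sqrt(pi), minor = 2 / sqrt(pi), angle = 0,
                degenerate = TRUE))
  }
  x <- px[, "col"]
  y <- -px[, "row"]  # y up for counterclockwise angles
  mx <- mean(x); my <- mean(y)
  uxx <- mean((x - mx)^2) + 1 / 12
  uyy <- mean((y - my)^2) + 1 / 12
  uxy <- mean((x - mx) * (y - my))
  degenerate <- (uxx - 1 / 12) * (uyy - 1 / 12) - uxy^2 < 1e-10
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  a0 <- 2 * sqrt(l1)
  b0 <- 2 * sqrt(max(l2, 0))
  scl <- if (b0 > 0) sqrt(n / (pi * a0 * b0)) else 1
  angle <- if (common < 1e-12) 0 else 0.5 * atan2(2 * uxy, uxx - uyy) * 180 / pi
  angle <- angle %% 180
  list(major = 2 * a0 * scl, minor = 2 * b0 * scl, angle = angle,
       degenerate = degenerate)
}

#' Feret (caliper) diameters of a convex hull
#'
#' Maximum Feret diameter is the largest pairwise distance between hull
#' vertices; minimum Feret diameter is the smallest projection width over
#' all hull edge directions (rotating calipers: the minimum width of a
#' convex polygon is attained perpendicular to one of its edges).
#'
#' @param hull vertex matrix (columns x, y) from [convexSolidity()], or a
#'   logical component mask / pixel matrix, in which case the pixel-corner
#'   hull is computed first.
#' @return named vector `c(feret_max, feret_min)` in pixels.
#' @examples
#' m <- matrix(TRUE, 10, 30)   # 30 x 10 rectangle
#' feretDiameters(m)           # c(sqrt(1000), 10)
#' @export
feretDiameters <- function(hull) {
  if (is.logical(hull) || (is.numeric(hull) && !is.null(colnames(hull)) &&
                           all(c("row", "col") %in% colnames(hull)))) {
    hull <- convexSolidity(hull)$hull
  }
  v <- nrow(hull)
  if (v < 2) stop("hull must have at least 2 vertices")
  dmax <- max(dist(hull))
  if (v == 2) {
    return(c(feret_max = dmax, feret_min = 0))
  }
  wmin <- Inf
  for (i in seq_len(v)) {
    j <- if (i == v) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    proj <- hull %*% nrm
    wmin <- min(wmin, max(proj) - min(proj))
  }
  c(feret_max = dmax, feret_min = wmin)
}

#' Box-counting fractal dimension of a binary field
#'
#' For each box size `e` the field is partitioned into an `e x e` grid and
#' the number `N(e)` of boxes containing at least one foreground pixel is
#' counted; when `offsets > 1`, that many grid origins per axis are tried
#' and the minimum count kept. The dimension is the negative slope of the
#' ordinary least-squares fit of `log N(e)` against `log e`. Default box
#' sizes are 2, 3, 4, 6, 8, 12, 16, 32, 64 with a single origin-anchored
#' grid, the usual defaults of particle-analysis tools.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @param boxSizes integer vector (>= 2 values, each >= 2) of box edge
#'   lengths in pixels.
#' @param offsets number of grid origins tried per axis (default 1).
#' @return the fractal dimension, with attributes `boxSizes` and `counts`.
#' @examples
#' sq <- matrix(TRUE, 128, 128)
#' boxCountFD(sq)  # ~2
#' @export
boxCountFD <- function(mask, boxSizes = c(2, 3, 4, 6, 8, 12, 16, 32, 64),
                       offsets = 1) {
  if (!any(mask)) stop("empty mask: fractal dimension undefined")
  boxSizes <- sort(unique(as.integer(boxSizes)))
  if (any(boxSizes < 2)) stop("box sizes must be >= 2")
  boxSizes <- boxSizes[boxSizes <= max(dim(mask))]
  if (length(boxSizes) < 2) stop("fewer than 2 usable box sizes")
  px <- which(mask, arr.ind = TRUE)
  r <- px[, 1] - 1L; c <- px[, 2] - 1L
  counts <- vapply(boxSizes, function(e) {
    offs <- unique(as.integer(seq(0, e - 1, length.out = max(1, offsets))))
    best <- Inf
    for (or in offs) for (oc in offs) {
      br <- (r + or) %/% e
      bc <- (c + oc) %/% e
      n <- length(unique(br * (max(bc) + 1L) + bc))
      if (n < best) best <- n
    }
    best
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(boxSizes)), log(counts))
  structure(-unname(fit$coefficients[2]), boxSizes = boxSizes, counts = counts)
}

#' Shape descriptors for every labeled cluster
#'
#' Computes the particle-analysis descriptor set for each labeled
#' component: area (px^2), perimeter (sqrt(2)-weighted boundary chain, px),
#' circularity, fitted-ellipse major/minor axes and angle, solidity, and
#' maximum/minimum Feret diameters.
#'
#' @param labels integer label matrix from [labelClusters()], or a
#'   [CytoField-class] with labels set.
#' @return data.frame with one row per cluster (column `cluster` plus the
#'   nine descriptors); zero rows when there are no clusters.
#' @export
clusterFeatures <- function(labels) {
  if (is(labels, "CytoField")) {
    if (!length(labels@labels)) stop("field has no labels; call labelClusters()")
    labels <- labels@labels
  }
  k <- max(labels, 0L)
  cols <- c("cluster", "area", "perimeter", "circularity",
            "fit_ellipse_major", "fit_ellipse_minor", "angle", "solidity",
            "feret_max", "feret_min")
  if (k == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  allpx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    px <- allpx[lab == i, , drop = FALSE]
    colnames(px) <- c("row", "col")
    n <- nrow(px)
    # local mask for boundary tracing
    r0 <- min(px[, 1]); c0 <- min(px[, 2])
    sub <- matrix(FALSE, max(px[, 1]) - r0 + 1L, max(px[, 2]) - c0 + 1L)
    sub[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- TRUE
    bnd <- traceBoundary(sub)
    axial <- n == 2 && sum(abs(px[1, ] - px[2, ])) == 1
    per <- chainPerimeter(attr(bnd, "chain"), nPixels = n, axialAdjacent = axial)
    hs <- convexSolidity(px)
    el <- fitEllipse(px)
    fer <- if (nrow(hs$hull) >= 2) feretDiameters(hs$hull) else c(1, 1)
    rows[[i]] <- data.frame(
      cluster = i, area = n, perimeter = per,
      circularity = circularity(n, per),
      fit_ellipse_major = el$major, fit_ellipse_minor = el$minor,
      angle = el$angle,
      solidity = if (is.na(hs$solidity)) 1 else hs$solidity,
      feret_max = fer[["feret_max"]], feret_min = fer[["feret_min"]]
    )
  }
  do.call(rbind, rows)
}

# circular mean of axial data (angles mod 180): mean on doubled angles
.axialMean <- function(deg) {
  th <- deg * pi / 90  # 2 * theta in radians
  (atan2(mean(sin(th)), mean(cos(th))) * 90 / pi) %% 180
}

#' Aggregate cluster descriptors to field level
#'
#' Unweighted mean of each descriptor over the clusters of one field, plus
#' the cluster count and the field's box-counting fractal dimension. The
#' angle is averaged as axial data (circular mean on doubled angles) by
#' default. A field with zero clusters has undefined descriptor means
#' (NA, `defined = FALSE`).
#'
#' @param clusters data.frame from [clusterFeatures()].
#' @param fractalDimension the field's [boxCountFD()] value (NA if the
#'   mask is empty).
#' @param angleMean `"axial"` (circular mean on 2*theta, default) or
#'   `"arithmetic"`.
#' @return one-row data.frame of field features with columns `cluster_count`,
#'   `fractal_dimension`, the nine descriptor means, and `defined`.
#' @export
summarizeField <- function(clusters, fractalDimension = NA_real_,
                           angleMean = c("axial", "arithmetic")) {
  angleMean <- match.arg(angleMean)
  n <- nrow(clusters)
  descr <- c("area", "perimeter", "circularity", "fit_ellipse_major",
             "fit_ellipse_minor", "angle", "solidity", "feret_max", "feret_min")
  if (n == 0) {
    means <- setNames(rep(NA_real_, length(descr)), descr)
  } else {
    means <- vapply(descr, function(d) {
      if (d == "angle" && angleMean == "axial") .axialMean(clusters$angle)
      else mean(clusters[[d]])
    }, numeric(1))
  }
  out <- as.data.frame(as.list(means))
  out$cluster_count <- n
  out$fractal_dimension <- as.numeric(fractalDimension)
  out$defined <- n > 0
  out
}

#' Aggregate field features to specimen level
#'
#' Unweighted mean of each field-level entry over the (up to five) fields.
#' Descriptor means use only fields with at least one cluster; the fractal
#' dimension uses every field where it is defined (any foreground). The
#' specimen is flagged when fewer than five fields contribute.
#'
#' @param fields data.frame of field rows from [summarizeField()].
#' @return one-row data.frame with the averaged features, `n_fields_used`,
#'   and `flagged`.
#' @export
summarizeSpecimen <- function(fields) {
  if (nrow(fields) < 1 || nrow(fields) > 5) stop("expected 1-5 fields")
  ok <- fields$defined
  if (!any(ok) && all(is.na(fields$fractal_dimension))) {
    stop("all fields undefined: no clusters and no foreground")
  }
  descr <- c("area", "perimeter", "circularity", "fit_ellipse_major",
             "fit_ellipse_minor", "angle", "solidity", "feret_max", "feret_min")
  means <- vapply(descr, function(d) {
    v <- fields[[d]][ok]
    if (d == "angle" && length(v)) .axialMean(v) else mean(v)
  }, numeric(1))
  out <- as.data.frame(as.list(means))
  out$cluster_count <- mean(fields$cluster_count)
  out$fractal_dimension <- mean(fields$fractal_dimension, na.rm = TRUE)
  out$n_fields_used <- sum(ok)
  out$flagged <- sum(ok) < 5
  out
}

#' Extract all features from a field or a specimen's fields
#'
#' Convenience wrapper running binarization (if needed), labeling,
#' per-cluster descriptors, the field fractal dimension and the field
#' summary; for a list of fields, also the specimen summary.
#'
#' @param x a [CytoField-class] or a list of them (one specimen).
#' @param minArea minimum cluster area in pixels passed to
#'   [labelClusters()].
#' @param boxSizes box sizes for [boxCountFD()].
#' @param ... passed to [binarize()].
#' @return list with `clusters` (per-cluster data.frame), `field`
#'   (per-field rows) and, for a list input, `specimen` (one row).
#' @export
extractFeatures <- function(x, minArea = 64,
                            boxSizes = c(2, 3, 4, 6, 8, 12, 16, 32, 64), ...) {
  if (is(x, "CytoField")) x <- list(x)
  clus <- list(); flds <- list()
  for (i in seq_along(x)) {
    fld <- x[[i]]
    if (!length(fld@mask)) fld <- binarize(fld, ...)
    if (!length(fld@labels)) fld <- labelClusters(fld, minArea = minArea)
    cf <- clusterFeatures(fld)
    # box counting on the retained clusters: debris below minArea is
    # suppressed before the dimension is measured, like the descriptors
    fdMask <- fld@labels > 0L
    fd <- if (any(fdMask)) boxCountFD(fdMask, boxSizes = boxSizes) else NA_real_
    fr <- summarizeField(cf, as.numeric(fd))
    fr$field <- fld@fieldIndex
    fr$specimen <- fld@specimenId
    if (nrow(cf)) {
      cf$field <- fld@fieldIndex
      cf$specimen <- fld@specimenId
    }
    clus[[i]] <- cf
    flds[[i]] <- fr
  }
  fields <- do.call(rbind, flds)
  out <- list(clusters = do.call(rbind, clus), field = fields)
  # a specimen whose every field is empty has no summary (NULL)
  out$specimen <- tryCatch(summarizeSpecimen(fields),
                           error = function(e) NULL)
  out
}
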