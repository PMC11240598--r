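#' Convert an image to 8-bit grayscale
#'
#' RGB input is collapsed by Rec. 601 luminance (0.299 R + 0.587 G +
#' 0.114 B); inputs of higher bit depth (or unit-range arrays from image
#' readers) are rescaled linearly to \[0, 255\]. Rounding is half away from
#' zero. An already-8-bit grayscale matrix is returned unchanged.
#'
#' @param image numeric matrix (grayscale) or 3-d array (height x width x
#'   channel, RGB or RGBA). Values may be 8-bit (0-255), higher depth, or
#'   unit range (0-1).
#' @param maxValue full-scale value of the input; by default inferred:
#'   1 for unit-range input, 255 for values <= 255, 65535 otherwise.
#' @return numeric matrix with values in \[0, 255\].
#' @examples
#' toGray8(matrix(c(0, 128, 255), 1))
#' @export
toGray8 <- function(image, maxValue = NULL) {
  if (length(image) == 0) stop("empty image")
  if (is.array(image) && length(dim(image)) == 3) {
    nch <- dim(image)[3]
    if (nch >= 3) {
      image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    } else {
      image <- image[, , 1]
    }
  }
  image <- as.matrix(image)
  if (is.null(maxValue)) {
    mx <- max(image)
    maxValue <- if (mx <= 1) 1 else if (mx <= 255) 255 else 65535
  }
  if (maxValue != 255) image <- image / maxValue * 255
  # round half away from zero (not banker's rounding)
  out <- floor(abs(image) + 0.5) * sign(image)
  pmin(pmax(out, 0), 255)
}

.histogram256 <- function(gray) {
  tabulate(as.integer(round(gray)) + 1L, nbins = 256L)
}

#' Isodata (iterative intermeans) threshold of an 8-bit histogram
#'
#' Finds the lowest fixed point of the intermeans iteration: the smallest
#' threshold t with t >= (mean of pixels <= t + mean of pixels > t) / 2,
#' scanning candidate thresholds from below. Scanning upward selects the
#' fixed point between the histogram modes even when the foreground class
#' is small, which is the behavior of the classic particle-analysis
#' default threshold. Pixels <= t are one side, > t the other.
#' @param gray numeric matrix of 8-bit gray values.
#' @return integer threshold in 0..254, or NA for a constant image.
#' @export
isodataThreshold <- function(gray) {
  h <- .histogram256(gray)
  v <- 0:255
  if (sum(h > 0) < 2) return(NA_integer_)
  cs <- cumsum(h)
  cm <- cumsum(h * v)
  tot <- cs[256]; mtot <- cm[256]
  for (t in 0:254) {
    n1 <- cs[t + 1]
    if (n1 == 0 || n1 == tot) next
    m1 <- cm[t + 1] / n1
    m2 <- (mtot - cm[t + 1]) / (tot - n1)
    if (t >= (m1 + m2) / 2) return(as.integer(t))
  }
  254L
}

#' Otsu threshold of an 8-bit histogram
#'
#' Maximizes between-class variance over all 256 candidate thresholds.
#' @inheritParams isodataThreshold
#' @return integer threshold in 0..254, or NA for a constant image.
#' @export
otsuThreshold <- function(gray) {
  h <- .histogram256(gray)
  if (sum(h > 0) < 2) return(NA_integer_)
  v <- 0:255
  w1 <- cumsum(h)
  mu1 <- cumsum(h * v)
  tot <- w1[256]
  mtot <- mu1[256]
  w2 <- tot - w1
  between <- ifelse(w1 > 0 & w2 > 0,
                    (mu1 / w1 - (mtot - mu1) / w2)^2 * w1 * w2, -Inf)
  # candidates t = 0..254 split at "<= t"
  which.max(between[1:255]) - 1L
}

#' Binarize an 8-bit grayscale field
#'
#' Computes a global threshold and returns the foreground mask according to
#' the stated polarity: with `dark_foreground` (stained clusters on a bright
#' background) pixels `<= t` are foreground; with `light_foreground` pixels
#' `> t` are. A constant image is degenerate: the mask is all background and
#' the attribute `degenerate` is set (with a warning).
#'
#' For the automatic methods, a minimum-contrast guard treats effectively
#' unimodal images (class means closer than `minContrast` gray levels, as
#' in an empty field containing only background noise) as degenerate too:
#' all background, flagged, threshold still logged.
#'
#' @param gray numeric matrix of 8-bit gray values, or a [CytoField-class].
#' @param method `"isodata"` (default, iterative intermeans), `"otsu"`, or
#'   `"fixed"` with threshold `t`.
#' @param polarity `"dark_foreground"` (default) or `"light_foreground"`.
#' @param t fixed threshold when `method = "fixed"`.
#' @param minContrast minimum separation of the two class means (gray
#'   levels) for an automatic threshold to be accepted; stained clusters
#'   on a bright background separate by >100 levels.
#' @return For a matrix: logical mask with attributes `threshold`, `method`,
#'   `degenerate`. For a `CytoField`: the field with `mask` and `info` filled.
#' @examples
#' g <- matrix(220, 20, 20); g[5:10, 5:10] <- 40
#' m <- binarize(g)
#' attr(m, "threshold")
#' @export
binarize <- function(gray, method = c("isodata", "otsu", "fixed"),
                     polarity = c("dark_foreground", "light_foreground"),
                     t = NULL, minContrast = 20) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  if (is(gray, "CytoField")) {
    m <- binarize(gray@gray, method = method, polarity = polarity, t = t,
                  minContrast = minContrast)
    gray@mask <- matrix(as.vector(m), nrow(m), ncol(m))
    gray@info$method <- attr(m, "method")
    gray@info$threshold <- attr(m, "threshold")
    gray@info$degenerate <- attr(m, "degenerate")
    gray@info$polarity <- polarity
    validObject(gray)
    return(gray)
  }
  if (!length(gray)) stop("empty image")
  thr <- switch(method,
    isodata = isodataThreshold(gray),
    otsu = otsuThreshold(gray),
    fixed = {
      if (is.null(t)) stop("method 'fixed' requires a threshold t")
      as.numeric(t)
    }
  )
  degenerate <- is.na(thr)
  if (!degenerate && method != "fixed") {
    lo <- gray <= thr
    if (mean(gray[!lo]) - mean(gray[lo]) < minContrast) degenerate <- TRUE
  }
  if (is.na(thr)) {
    warning("constant image: threshold undefined, returning all-background")
  }
  if (degenerate) {
    mask <- matrix(FALSE, nrow(gray), ncol(gray))
  } else if (polarity == "dark_foreground") {
    mask <- gray <= thr
  } else {
    mask <- gray > thr
  }
  structure(mask, threshold = as.numeric(thr), method = method,
            degenerate = degenerate)
}

#' Label connected cell clusters in a binary mask
#'
#' Run-based two-pass connected-component labeling with union-find.
#' Components smaller than `minArea` pixels are removed (debris
#' suppression). Labels are assigned 1..K in raster-scan order (by row,
#' then column) of each component's first pixel.
#'
#' @param mask logical matrix (TRUE = foreground), or a [CytoField-class]
#'   that has been [binarize()]d.
#' @param connectivity 8 (default) or 4.
#' @param minArea minimum component area in pixels (default 64, sized to
#'   suppress sub-cluster debris at 4x magnification).
#' @param excludeEdges drop components touching the image border
#'   (default FALSE, matching common particle-analyzer defaults).
#' @return For a mask: integer label matrix (0 = background) with attribute
#'   `nComponents`. For a `CytoField`: the field with `labels` filled.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[2:4, 2:4] <- TRUE; m[7:9, 7:9] <- TRUE
#' lab <- labelClusters(m, minArea = 1)
#' attr(lab, "nComponents")
#' @export
labelClusters <- function(mask, connectivity = 8, minArea = 64,
                          excludeEdges = FALSE) {
  if (is(mask, "CytoField")) {
    fld <- mask
    if (!length(fld@mask)) stop("field has no mask; call binarize() first")
    lab <- labelClusters(fld@mask, connectivity = connectivity,
                         minArea = minArea, excludeEdges = excludeEdges)
    fld@labels <- matrix(as.integer(lab), nrow(lab), ncol(lab))
    fld@info$nComponents <- attr(lab, "nComponents")
    fld@info$minArea <- minArea
    fld@info$connectivity <- connectivity
    return(fld)
  }
  stopifnot(is.logical(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(structure(lab, nComponents = 0L))

  # run-length encode each row; union runs adjacent across rows
  runs <- vector("list", nr)
  nrun <- 0L
  for (r in seq_len(nr)) {
    row <- mask[r, ]
    if (!any(row)) next
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    runs[[r]] <- cbind(start = starts[keep], end = ends[keep],
                       id = nrun + seq_len(sum(keep)))
    nrun <- nrun + sum(keep)
  }
  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  reach <- if (connectivity == 8) 1L else 0L
  for (r in 2:nr) {
    a <- runs[[r - 1]]; b <- runs[[r]]
    if (is.null(a) || is.null(b)) next
    for (j in seq_len(nrow(b))) {
      ov <- which(a[, "start"] <= b[j, "end"] + reach &
                  a[, "end"] >= b[j, "start"] - reach)
      for (k in ov) {
        ra <- find(a[k, "id"]); rb <- find(b[j, "id"])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(nrun), find, integer(1))
  # paint provisional labels
  for (r in seq_len(nr)) {
    b <- runs[[r]]
    if (is.null(b)) next
    for (j in seq_len(nrow(b))) {
      lab[r, b[j, "start"]:b[j, "end"]] <- root[b[j, "id"]]
    }
  }
  # relabel in raster order of first pixel, drop small / edge components
  labT <- t(lab)  # column-major over t() = raster (row-major) order
  firstSeen <- unique(labT[labT > 0L])
  sizes <- tabulate(lab[lab > 0L])
  keepLab <- firstSeen[sizes[firstSeen] >= minArea]
  if (excludeEdges && length(keepLab)) {
    edgeLabs <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    keepLab <- setdiff(keepLab, edgeLabs)
  }
  remap <- integer(max(lab))
  remap[keepLab] <- seq_along(keepLab)
  out <- matrix(0L, nr, nc)
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]
  structure(out, nComponents = length(keepLab))
}
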