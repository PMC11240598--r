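#' Analytic reference shapes for validating the box-counting estimator
#'
#' Deterministic binary masks with known box-counting dimension, used as
#' fixtures for [boxCountFD()]:
#'
#' | name                  | construction                           | dimension        |
#' |-----------------------|----------------------------------------|------------------|
#' | `line`                | 1-px horizontal segment                | 1                |
#' | `disk`                | filled disk                            | 2                |
#' | `square`              | filled square                          | 2                |
#' | `sierpinski_carpet`   | IFS on a 3^depth grid                  | log 8 / log 3    |
#' | `sierpinski_triangle` | Pascal-parity IFS on a 2^depth grid    | log 3 / log 2    |
#' | `koch_island`         | rasterized Koch snowflake boundary     | log 4 / log 3    |
#'
#' For the carpet, `size` must be a multiple of `3^depth`; for the
#' triangle, of `2^depth`. The exact number of occupied unit cells of the
#' carpet is `8^depth`, of the triangle `3^depth`.
#'
#' @param name one of the shapes above.
#' @param depth recursion depth (>= 1; ignored for line/disk/square).
#' @param size mask side length in pixels.
#' @return logical `size x size` matrix with attribute `analyticDimension`.
#' @examples
#' m <- referenceShape("sierpinski_carpet", depth = 3, size = 27)
#' sum(m)  # 8^3 = 512
#' @export
referenceShape <- function(name = c("line", "disk", "square",
                                    "sierpinski_carpet",
                                    "sierpinski_triangle", "koch_island"),
                           depth = 1L, size = 243L) {
  name <- match.arg(name)
  size <- as.integer(size)
  depth <- as.integer(depth)
  if (depth < 1 && name %in% c("sierpinski_carpet", "sierpinski_triangle",
                               "koch_island")) {
    stop("depth must be >= 1")
  }
  m <- matrix(FALSE, size, size)
  dimval <- switch(name,
    line = {
      m[(size + 1L) %/% 2L, ] <- TRUE
      1
    },
    disk = {
      cx <- (size + 1) / 2
      r <- (size - 1) / 2
      m <- outer(seq_len(size), seq_len(size),
                 function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
      2
    },
    square = {
      m[] <- TRUE
      2
    },
    sierpinski_carpet = {
      cells <- 3L^depth
      if (size %% cells != 0L) stop("size must be a multiple of 3^depth")
      f <- size %/% cells
      ci <- (seq_len(size) - 1L) %/% f
      keep1 <- rep(TRUE, cells)
      # cell (a, b) kept iff no base-3 digit position has both digits == 1
      dig <- function(v, l) (v %/% 3L^l) %% 3L
      filled <- outer(ci, ci, function(a, b) {
        ok <- rep(TRUE, length(a))
        for (l in 0:(depth - 1L)) ok <- ok & !(dig(a, l) == 1L & dig(b, l) == 1L)
        ok
      })
      m <- filled
      log(8) / log(3)
    },
    sierpinski_triangle = {
      cells <- 2L^depth
      if (size %% cells != 0L) stop("size must be a multiple of 2^depth")
      f <- size %/% cells
      ci <- (seq_len(size) - 1L) %/% f
      m <- outer(ci, ci, function(a, b) bitwAnd(a, b) == 0L)
      log(3) / log(2)
    },
    koch_island = {
      m <- .kochBoundary(depth, size)
      log(4) / log(3)
    }
  )
  structure(m, analyticDimension = dimval)
}

# rasterized boundary of the Koch snowflake at the given iteration depth
.kochBoundary <- function(depth, size) {
  # equilateral triangle, counterclockwise, inscribed with margin for bumps
  s <- size * 0.62
  cx <- size / 2
  cy <- size / 2 + size * 0.07
  h <- s * sqrt(3) / 2
  pts <- rbind(
    c(cx - s / 2, cy - h / 3),
    c(cx + s / 2, cy - h / 3),
    c(cx, cy + 2 * h / 3)
  )
  for (it in seq_len(depth)) {
    n <- nrow(pts)
    out <- matrix(0, 4L * n, 2L)
    for (i in seq_len(n)) {
      p <- pts[i, ]; q <- pts[if (i == n) 1L else i + 1L, ]
      v <- (q - p) / 3
      a <- p + v
      b <- p + 2 * v
      # outward bump for a counterclockwise polygon: rotate v by -60 deg
      rot <- c(v[1] * cos(-pi / 3) - v[2] * sin(-pi / 3),
               v[1] * sin(-pi / 3) + v[2] * cos(-pi / 3))
      cpt <- a + rot
      out[(4L * (i - 1L) + 1L):(4L * i), ] <- rbind(p, a, cpt, b)
    }
    pts <- out
  }
  m <- matrix(FALSE, size, size)
  n <- nrow(pts)
  for (i in seq_len(n)) {
    p <- pts[i, ]; q <- pts[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((q - p)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.3)))
    xs <- round(p[1] + t * (q[1] - p[1]))
    ys <- round(p[2] + t * (q[2] - p[2]))
    ok <- xs >= 1 & xs <= size & ys >= 1 & ys <= size
    m[cbind(size + 1L - ys[ok], xs[ok])] <- TRUE  # y up -> row down
  }
  m
}
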