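test_that("boundary tracing visits exactly the morphological boundary", {
  # 3x3 filled square: 8 boundary pixels
  s3 <- matrix(TRUE, 3, 3)
  b <- traceBoundary(s3)
  expect_equal(nrow(b), 8)
  expect_false(attr(b, "degenerate"))

  # single pixel: degenerate, empty chain
  p1 <- matrix(TRUE, 1, 1)
  b1 <- traceBoundary(p1)
  expect_true(attr(b1, "degenerate"))
  expect_length(attr(b1, "chain"), 0)

  # random blobs: traced set equals the morphological (inner) boundary
  for (seed in 1:5) {
    m <- randomBlob(seed)
    b <- traceBoundary(m)
    traced <- unique(paste(b[, "row"], b[, "col"]))
    er <- m & !(.erode4(m))
    ref <- which(er, arr.ind = TRUE)
    refSet <- paste(ref[, 1], ref[, 2])
    expect_setequal(traced, refSet)
  }
})

test_that("chain perimeter matches closed forms and degenerate fallbacks", {
  # axis-aligned s x s square: 4 (s - 1), exactly
  for (s in c(3, 8, 20)) {
    sq <- matrix(TRUE, s, s)
    expect_equal(chainPerimeter(traceBoundary(sq), s^2), 4 * (s - 1))
  }
  # degenerate fallbacks keep circularity finite
  expect_equal(chainPerimeter(integer(0), nPixels = 1), 4)
  dom <- matrix(TRUE, 1, 2)
  expect_equal(chainPerimeter(traceBoundary(dom), 2, axialAdjacent = TRUE), 6)

  # 45-degree rotated square: the chain is (almost) all diagonal steps
  rs <- rasterRotSquare(30, 45)
  ch <- attr(traceBoundary(rs), "chain")
  expect_gt(mean(ch %% 2 == 1), 0.95)
  diagCount <- sum(ch %% 2 == 1); axCount <- sum(ch %% 2 == 0)
  expect_equal(chainPerimeter(traceBoundary(rs), sum(rs)),
               axCount + diagCount * sqrt(2))

  # digitized disk: the sqrt(2)-weighted chain overestimates the continuum
  # circumference by the known digitization factor ~ 8 (sqrt(2) - 1) / pi
  d <- rasterDisk(50)
  per <- chainPerimeter(traceBoundary(d), sum(d))
  expect_gt(per / (2 * pi * 50), 1.00)
  expect_lt(per / (2 * pi * 50), 1.07)
})

test_that("circularity closed forms and cap", {
  expect_equal(circularity(pi * 50^2, 2 * pi * 50), 1)          # disk
  expect_equal(circularity(20^2, 4 * 20), pi / 4)               # square
  expect_equal(circularity(100, 10), 1)                         # capped
  expect_error(circularity(0, 10))
  expect_error(circularity(10, -1))
})

test_that("solidity: convex identity, plus-sign 5/7, rotation invariance", {
  rect <- matrix(TRUE, 20, 30)
  expect_gte(convexSolidity(rect)$solidity, 0.98)

  plus <- matrix(FALSE, 5, 5); plus[2:4, 3] <- TRUE; plus[3, 2:4] <- TRUE
  cs <- convexSolidity(plus)
  expect_equal(cs$hullArea, 7)
  expect_equal(cs$solidity, 5 / 7)

  for (seed in 1:3) {
    m <- randomBlob(seed)
    s0 <- convexSolidity(m)$solidity
    s90 <- convexSolidity(t(m[nrow(m):1, ]))$solidity  # 90 deg rotation
    expect_equal(s0, s90, tolerance = 1e-12)
  }
})

test_that("moment ellipse recovers constructed axes and orientation", {
  sz <- 121; cx <- 61
  el <- outer(1:sz, 1:sz, function(i, j) ((j - cx) / 40)^2 + ((i - cx) / 20)^2 <= 1)
  fe <- fitEllipse(el)
  expect_equal(fe$major, 80, tolerance = 0.02)
  expect_equal(fe$minor, 40, tolerance = 0.02)
  expect_true(fe$angle < 2 || fe$angle > 178)

  th <- 30 * pi / 180
  elr <- outer(1:sz, 1:sz, function(i, j) {
    x <- j - cx; y <- -(i - cx)
    xr <- cos(th) * x + sin(th) * y; yr <- -sin(th) * x + cos(th) * y
    (xr / 40)^2 + (yr / 20)^2 <= 1
  })
  fer <- fitEllipse(elr)
  expect_equal(fer$angle, 30, tolerance = 2 / 30)  # within +/- 2 degrees
  expect_equal(fer$major, 80, tolerance = 0.02)

  d <- rasterDisk(30)
  fd <- fitEllipse(d)
  expect_equal(fd$major / fd$minor, 1, tolerance = 0.01)

  lin <- matrix(TRUE, 1, 30)
  expect_true(fitEllipse(lin)$degenerate)
})

test_that("Feret diameters: closed forms and brute-force calipers oracle", {
  rect <- matrix(TRUE, 10, 30)
  fr <- feretDiameters(rect)
  expect_equal(unname(fr["feret_max"]), sqrt(30^2 + 10^2), tolerance = 1e-10)
  expect_equal(unname(fr["feret_min"]), 10, tolerance = 1e-10)

  # equilateral triangle side s (continuum polygon input)
  s <- 50
  tri <- cbind(x = c(0, s, s / 2), y = c(0, 0, s * sqrt(3) / 2))
  ft <- feretDiameters(tri)
  expect_equal(unname(ft["feret_max"]), s)
  expect_equal(unname(ft["feret_min"]), s * sqrt(3) / 2)

  # rotating calipers against a fine brute-force angle sweep; the sweep
  # has a linear kink error of about width * step / 2, so a 0.1-degree
  # step bounds the discrepancy by ~0.1%
  set.seed(99)
  for (rep in 1:100) {
    pts <- cbind(x = runif(12, 0, 100), y = runif(12, 0, 100))
    hull <- pts[chull(pts), , drop = FALSE]
    fm <- feretDiameters(hull)
    expect_equal(unname(fm["feret_max"]), max(dist(pts)), tolerance = 1e-10)
    bw <- bruteMinWidth(pts, stepDeg = 0.1)
    expect_lte(unname(fm["feret_min"]), bw + 1e-9)   # calipers is exact
    expect_equal(unname(fm["feret_min"]), bw, tolerance = 0.001)
  }
})

test_that("box-counting dimension matches analytic fixture values", {
  line <- referenceShape("line", size = 512)
  expect_equal(as.numeric(boxCountFD(line)), 1, tolerance = 0.05)

  sq <- referenceShape("square", size = 512)
  expect_equal(as.numeric(boxCountFD(sq)), 2, tolerance = 0.05 / 2)

  carpet <- referenceShape("sierpinski_carpet", depth = 5, size = 243)
  expect_equal(sum(carpet), 8^5)
  fdc <- boxCountFD(carpet, boxSizes = c(3, 9, 27, 81))
  # grid-aligned counts are exactly 8^(5-k)
  expect_equal(unname(attr(fdc, "counts")), 8^(4:1))
  expect_equal(as.numeric(fdc), log(8) / log(3), tolerance = 0.03 / 1.89)

  tri <- referenceShape("sierpinski_triangle", depth = 7, size = 256)
  expect_equal(as.numeric(boxCountFD(tri, c(2, 4, 8, 16, 32, 64))),
               log(3) / log(2), tolerance = 0.05 / 1.58)

  koch <- referenceShape("koch_island", depth = 5, size = 512)
  expect_equal(as.numeric(boxCountFD(koch, c(6, 9, 18, 27, 54, 81))),
               log(4) / log(3), tolerance = 0.05 / 1.26)

  expect_error(boxCountFD(matrix(FALSE, 8, 8)), "empty")
  expect_error(boxCountFD(matrix(TRUE, 8, 8), boxSizes = c(4)), "2 usable")
  expect_error(referenceShape("sierpinski_carpet", depth = 3, size = 100),
               "multiple")
})

test_that("descriptors are translation, rotation, and scale consistent", {
  base <- randomBlob(4, r = 18, amp = 0.15)
  pad <- function(m, nr, nc, r0, c0) {
    out <- matrix(FALSE, nr, nc)
    out[r0 + seq_len(nrow(m)) - 1, c0 + seq_len(ncol(m)) - 1] <- m
    out
  }
  feat <- function(m) {
    lab <- labelClusters(m, minArea = 1)
    clusterFeatures(lab)[1, ]
  }
  f1 <- feat(pad(base, 120, 120, 5, 5))
  f2 <- feat(pad(base, 120, 120, 60, 70))
  for (col in c("area", "perimeter", "circularity", "solidity",
                "feret_max", "feret_min", "fit_ellipse_major")) {
    expect_equal(f1[[col]], f2[[col]], info = col)   # translation: exact
  }

  # 90-degree rotation: exact for area/perimeter/solidity/feret
  rot <- t(base[nrow(base):1, ])
  f3 <- feat(pad(rot, 120, 120, 5, 5))
  expect_equal(f1$area, f3$area)
  expect_equal(f1$perimeter, f3$perimeter)
  expect_equal(f1$circularity, f3$circularity)
  expect_equal(f1$feret_max, f3$feret_max, tolerance = 1e-10)

  # doubling a smooth mask: area x4, lengths x2, shape ratios stable
  disk1 <- rasterDisk(25); disk2 <- rasterDisk(50)
  g1 <- feat(disk1); g2 <- feat(disk2)
  expect_equal(g2$area / g1$area, 4, tolerance = 0.03)
  expect_equal(g2$perimeter / g1$perimeter, 2, tolerance = 0.03)
  expect_equal(g2$feret_max / g1$feret_max, 2, tolerance = 0.03)
  expect_equal(g2$fit_ellipse_major / g1$fit_ellipse_major, 2, tolerance = 0.03)
  expect_equal(g2$circularity, g1$circularity, tolerance = 0.02)
  expect_equal(g2$solidity, g1$solidity, tolerance = 0.02)
  fdr <- abs(as.numeric(boxCountFD(disk2)) - as.numeric(boxCountFD(disk1)))
  expect_lt(fdr, 0.05)
})

test_that("field and specimen summaries follow the averaging rules", {
  mk <- function(circ) {
    data.frame(cluster = 1, area = 100, perimeter = 40, circularity = circ,
               fit_ellipse_major = 12, fit_ellipse_minor = 10, angle = 10,
               solidity = 0.9, feret_max = 13, feret_min = 9)
  }
  one <- summarizeField(mk(0.5), 1.3)
  expect_equal(one$circularity, 0.5)
  expect_equal(one$cluster_count, 1)

  two <- summarizeField(rbind(mk(0.4), mk(0.8)), 1.3)
  expect_equal(two$circularity, 0.6)

  empty <- summarizeField(mk(0.5)[0, ], NA_real_)
  expect_equal(empty$cluster_count, 0)
  expect_false(empty$defined)
  expect_true(is.na(empty$circularity))

  # five identical fields: specimen equals any field (fixed point)
  f5 <- do.call(rbind, replicate(5, summarizeField(mk(0.5), 1.3),
                                 simplify = FALSE))
  sp <- summarizeSpecimen(f5)
  expect_equal(sp$circularity, 0.5)
  expect_equal(sp$n_fields_used, 5)
  expect_false(sp$flagged)

  fds <- c(1.2, 1.3, 1.4, 1.3, 1.3)
  fmix <- do.call(rbind, lapply(fds, function(fd) summarizeField(mk(0.5), fd)))
  expect_equal(summarizeSpecimen(fmix)$fractal_dimension, 1.3)

  # an empty field among five: descriptors use 4 fields, fd all defined ones
  fmix2 <- rbind(fmix[1:4, ], summarizeField(mk(0.5)[0, ], 1.5))
  sp2 <- summarizeSpecimen(fmix2)
  expect_equal(sp2$n_fields_used, 4)
  expect_true(sp2$flagged)
  expect_equal(sp2$circularity, 0.5)
  expect_equal(sp2$fractal_dimension, mean(c(1.2, 1.3, 1.4, 1.3, 1.5)))

  expect_error(summarizeSpecimen(fmix[0, ]), "1-5")
})

test_that("axial angle averaging wraps around 180", {
  a <- summarizeField(data.frame(cluster = 1:2, area = 1, perimeter = 1,
                                 circularity = 1, fit_ellipse_major = 1,
                                 fit_ellipse_minor = 1, angle = c(178, 2),
                                 solidity = 1, feret_max = 1, feret_min = 1),
                      1)$angle
  expect_true(min(abs(c(a - 0, a - 180))) < 1e-6)
})
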