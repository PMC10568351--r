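## Gaussian shape similarity, plane distances and screening semantics.

## A one-group TwnGroups object with prescribed centroids and planes.
twnFixture <- function(centroids, planes = NULL, nRings = 1L,
                       totalFrames = 1L) {
  if (is.null(planes)) {
    p <- ringPlane(centroids)
    planes <- data.frame(group = 1L, ring = 1L,
                         nx = p$normal[1], ny = p$normal[2],
                         nz = p$normal[3], px = p$point[1],
                         py = p$point[2], pz = p$point[3])
  }
  ox <- data.frame(group = 1L, ring = rep(seq_len(nRings), each = 4L),
                   slot = rep(1:4, nRings),
                   x = rep(centroids[, 1], nRings),
                   y = rep(centroids[, 2], nRings),
                   z = rep(centroids[, 3], nRings))
  new("TwnGroups",
      groups = data.frame(group = 1L, nRings = nRings,
                          occupancy = nRings / totalFrames,
                          c1x = centroids[1,1], c1y = centroids[1,2],
                          c1z = centroids[1,3],
                          c2x = centroids[2,1], c2y = centroids[2,2],
                          c2z = centroids[2,3],
                          c3x = centroids[3,1], c3y = centroids[3,2],
                          c3z = centroids[3,3],
                          c4x = centroids[4,1], c4y = centroids[4,2],
                          c4z = centroids[4,3]),
      oxygens = ox, planes = planes, totalFrames = as.integer(totalFrames))
}

sq <- rbind(c(1.98, 0, 0), c(0, 1.98, 0), c(-1.98, 0, 0), c(0, -1.98, 0))

test_that("shape similarity is exactly 1 for a coincident oxygen set and
           vanishes at long range", {
  expect_lt(abs(shapeSimilarity(sq, sq, fragElements = "O") - 1), 1e-9)
  far <- sweep(sq, 2, c(100, 0, 0), "+")
  expect_lt(shapeSimilarity(sq, far, fragElements = "O"), 1e-6)
})

test_that("single-atom overlap matches a numerical quadrature of the
           defining shape-density integrals", {
  params <- shapeParameters()
  aO <- alphaFromRadius(params@radii[["O"]], params@p)
  ## 1 A offset pair of oxygen Gaussians: the product integral
  ## factorises over axes, each factor integrated by midpoint rule
  offs <- 1.0
  oAB <- params@p^2 *
    quad1d(aO, aO, 0, offs, -12, 13) *
    quad1d(aO, aO, 0, 0, -12, 12) *
    quad1d(aO, aO, 0, 0, -12, 12)
  oAA <- params@p^2 * quad1d(aO, aO, 0, 0, -12, 12)^3
  want <- 2 * oAB / (oAA + oAA)
  got <- shapeSimilarity(matrix(c(0, 0, 0), 1),
                         matrix(c(offs, 0, 0), 1), fragElements = "O")
  expect_lt(abs(got - want), 1e-6)
})

test_that("shape similarity is bounded, symmetric and rigid-transform
           invariant", {
  set.seed(71)
  for (k in 1:100) {
    a <- matrix(rnorm(12, sd = 2), 4, 3)
    b <- matrix(rnorm(15, sd = 2), 5, 3)
    s <- shapeSimilarity(a, b, fragElements = "O")
    expect_gte(s, 0); expect_lte(s, 1)
    ## symmetry (both sets as oxygens, roles swapped)
    sSwap <- shapeSimilarity(b, a, fragElements = "O")
    expect_lt(abs(s - sSwap), 1e-12)
    ## joint rigid transform
    R <- randomRotation(); t3 <- runif(3, -5, 5)
    tr <- function(m) sweep(m %*% t(R), 2, t3, "+")
    expect_lt(abs(shapeSimilarity(tr(a), tr(b), fragElements = "O") - s),
              1e-9)
  }
})

test_that("mixed-element fragments and the min/max normalization behave", {
  fr <- fragmentSet(data.frame(frag = "f", element = c("C", "N", "O"),
                               x = c(0, 1.4, 2.8), y = 0, z = 0))
  s <- shapeSimilarity(sq, fr)
  expect_gte(s, 0); expect_lte(s, 1)
  pm <- shapeParameters(normalization = "minmax")
  sm <- shapeSimilarity(sq, fr, params = pm)
  expect_gte(sm, 0); expect_lte(sm, 1)
  ## hydrogens are excluded from shape and centroid
  frH <- fragmentSet(data.frame(frag = "f",
                                element = c("C", "N", "O", "H", "H"),
                                x = c(0, 1.4, 2.8, 50, -50), y = 0, z = 0))
  expect_equal(shapeSimilarity(sq, frH), s)
  expect_equal(fragmentCentroid(frH), fragmentCentroid(fr))
})

test_that("fragment centroid is the unweighted heavy-atom mean", {
  one <- fragmentSet(data.frame(frag = "a", element = "C",
                                x = 1, y = 1, z = 1))
  expect_equal(fragmentCentroid(one), c(1, 1, 1), ignore_attr = TRUE)
  two <- fragmentSet(data.frame(frag = "a", element = "C",
                                x = c(0, 2), y = 0, z = 0))
  expect_equal(fragmentCentroid(two), c(1, 0, 0), ignore_attr = TRUE)
  ## benzene ring: centroid at the ring center
  ang <- (0:5) * pi / 3
  benz <- fragmentSet(data.frame(frag = "benzene", element = "C",
                                 x = 1.397 * cos(ang) + 2,
                                 y = 1.397 * sin(ang) - 1, z = 0.5))
  expect_lt(max(abs(fragmentCentroid(benz) - c(2, -1, 0.5))), 1e-9)
})

test_that("average plane distance averages hand-computed orthogonal
           distances", {
  ## centroid on every plane -> 0
  tg <- twnFixture(sq)
  expect_equal(avgPlaneDistance(tg, c(0, 0, 0)), 0)
  ## single plane z = 0, centroid at z = 0.7 -> 0.7
  expect_equal(avgPlaneDistance(tg, c(0.3, -0.2, 0.7)), 0.7)
  ## three hand-built planes
  n1 <- c(0, 0, 1); n2 <- c(0, 1, 0); n3 <- c(1, 1, 1) / sqrt(3)
  planes <- data.frame(group = 1L, ring = 1:3,
                       nx = c(n1[1], n2[1], n3[1]),
                       ny = c(n1[2], n2[2], n3[2]),
                       nz = c(n1[3], n2[3], n3[3]),
                       px = c(0, 0, 1), py = c(0, 2, 0), pz = c(1, 0, 0))
  tg3 <- twnFixture(sq, planes = planes, nRings = 3L)
  ctr <- c(1, 1, 1)
  want <- mean(c(abs(sum(n1 * (ctr - c(0, 0, 1)))),
                 abs(sum(n2 * (ctr - c(0, 2, 0)))),
                 abs(sum(n3 * (ctr - c(1, 0, 0))))))
  expect_lt(abs(avgPlaneDistance(tg3, ctr) - want), 1e-9)
  ## invariance under a joint rigid transform
  set.seed(73)
  R <- randomRotation(); t3 <- runif(3, -4, 4)
  planesT <- planes
  nrm <- as.matrix(planes[, c("nx", "ny", "nz")]) %*% t(R)
  pts <- sweep(as.matrix(planes[, c("px", "py", "pz")]) %*% t(R), 2,
               t3, "+")
  planesT[, c("nx", "ny", "nz")] <- nrm
  planesT[, c("px", "py", "pz")] <- pts
  tgT <- twnFixture(sweep(sq %*% t(R), 2, t3, "+"), planes = planesT,
                    nRings = 3L)
  expect_lt(abs(avgPlaneDistance(tgT, as.numeric(R %*% ctr + t3)) - want),
            1e-9)
})

test_that("screening passes exactly at the inclusive thresholds", {
  tg <- twnFixture(sq)
  fr <- fragmentSet(data.frame(frag = "id", element = "O",
                               x = sq[, 1], y = sq[, 2], z = sq[, 3]))
  ## identity construction: S = 1, D = 0, passes the defaults
  res <- screenFragments(fr, tg)
  expect_true(all(screenRecords(res)$passed))
  expect_lt(abs(screenRecords(res)$shape_similarity - 1), 1e-9)
  expect_lt(screenRecords(res)$avg_distance, 1e-12)

  ## far fragment fails on both criteria
  farA <- sweep(sq, 2, c(10, 0, 4), "+")
  frFar <- fragmentSet(data.frame(frag = "far", element = "O",
                                  x = farA[, 1], y = farA[, 2],
                                  z = farA[, 3]))
  recFar <- screenRecords(suppressWarnings(screenFragments(frFar, tg)))
  expect_false(recFar$passed)
  expect_lt(recFar$shape_similarity, 0.6)
  expect_gt(recFar$avg_distance, 0.5)

  ## thresholds set to the exact computed scores: still a pass
  off <- sweep(sq, 2, c(0.8, 0, 0.3), "+")
  frOff <- fragmentSet(data.frame(frag = "off", element = "O",
                                  x = off[, 1], y = off[, 2],
                                  z = off[, 3]))
  s <- shapeSimilarity(tg, frOff)
  d <- avgPlaneDistance(tg, fragmentCentroid(frOff))
  atBoundary <- screenFragments(frOff, tg, sMin = s, dMax = d)
  expect_true(screenRecords(atBoundary)$passed)
  justOver <- screenFragments(frOff, tg, sMin = s + 1e-12,
                              dMax = d - 1e-12)
  expect_false(screenRecords(justOver)$passed)
})

test_that("threshold sweep counts match a by-hand tally and nest
           monotonically", {
  ## constructed scores for 10 fragments x 1 group
  sv <- c(0.45, 0.55, 0.58, 0.62, 0.65, 0.68, 0.72, 0.75, 0.80, 0.95)
  dv <- c(0.2, 0.4, 0.9, 0.25, 0.55, 1.2, 0.45, 0.05, 0.8, 0.31)
  rec <- data.frame(frag = paste0("f", 1:10), group = 1L,
                    shape_similarity = sv, avg_distance = dv,
                    passed = sv >= 0.6 & dv <= 0.5)
  res <- new("ScreenResult", records = rec, sMin = 0.6, dMax = 0.5)
  sw <- thresholdSweep(res)
  for (k in seq_len(nrow(sw))) {
    want <- sum(sv >= sw$sMin[k] & dv <= sw$dMax[k])
    expect_equal(sw$nScreened[k], want)
    expect_equal(sw$pctScreened[k], 100 * want / 10)
  }
  ## nesting: tighter thresholds never screen more
  for (s0 in unique(sw$sMin)) {
    sub <- sw[sw$sMin == s0, ]
    expect_true(all(diff(sub$nScreened[order(sub$dMax)]) >= 0))
  }
  for (d0 in unique(sw$dMax)) {
    sub <- sw[sw$dMax == d0, ]
    expect_true(all(diff(sub$nScreened[order(sub$sMin)]) <= 0))
  }
  ## all-fail records give zero counts
  recBad <- transform(rec, shape_similarity = 0.1, avg_distance = 50,
                      passed = FALSE)
  swBad <- thresholdSweep(new("ScreenResult", records = recBad,
                              sMin = 0.6, dMax = 0.5))
  expect_true(all(swBad$nScreened == 0L))
})

test_that("screen summary marks fragments screened against any group", {
  rec <- data.frame(frag = rep(c("a", "b"), each = 2),
                    group = rep(1:2, 2),
                    shape_similarity = c(0.9, 0.1, 0.2, 0.3),
                    avg_distance = c(0.1, 3, 2, 4))
  rec$passed <- rec$shape_similarity >= 0.6 & rec$avg_distance <= 0.5
  res <- new("ScreenResult", records = rec, sMin = 0.6, dMax = 0.5)
  s <- screenSummary(res)
  expect_equal(s$screened, c(TRUE, FALSE))
  expect_equal(s$nPassed, c(1L, 0L))
  expect_equal(s$bestShape, c(0.9, 0.3))
  expect_equal(s$bestDistance, c(0.1, 2))
})
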