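# Orientation metrics: density, qualifying masks, parallelism/radiality,
# aspect ratio, angular histograms, and group statistics.

# PeakField built directly from an axis matrix (bypasses peak search)
manual_peaks <- function(axes, dims, spacingNm = 130) {
  ax <- array(NA_real_, c(dims, 3L))
  ax[, , , 1] <- array(axes[, 1], dims)
  ax[, , , 2] <- array(axes[, 2], dims)
  ax[, , , 3] <- array(axes[, 3], dims)
  new("PeakField", axes = ax, peakValue = array(1, dims),
      degenerate = array(FALSE, dims), spacingNm = spacingNm)
}

test_that("density equals the spherical integral of the ODF", {
  g <- sphereGrid()
  set.seed(13)
  cf <- array(rnorm(2 * 2 * 2 * 15), c(2, 2, 2, 15))
  fld <- odfField(cf, 130)
  dens <- densityMap(fld)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    quad <- sum(gridWeights(g) * shEvaluate(cf[i, j, k, ], g))
    expect_equal(dens[i, j, k], quad, tolerance = 1e-8)
  }
  expect_equal(densityMap(odfField(2 * cf, 130)), 2 * dens,
               tolerance = 1e-12)
  # unit-mass Watson ODF -> density 1
  one <- odfField(array(watsonODF(c(0, 0, 1), 5), c(1, 1, 1, 15)), 130)
  expect_equal(as.numeric(densityMap(one)), 1, tolerance = 1e-9)
})

test_that("qualifying mask: strict count threshold and wire distance", {
  dims <- c(6L, 6L, 4L)
  sch <- makeScheme("custom",
                    specs = data.frame(illumView = "A", psi = 0, tau = 0))
  mk <- function(v) new("IrradianceStack", volumes = list(v), scheme = sch,
                        spacingNm = 130, countsPerUnit = 1,
                        noiseModel = "none", seed = NA_real_)
  expect_false(any(qualifyingMask(mk(array(0, dims)), 5000)))
  v <- array(0, dims); v[2, 3, 1] <- 5000; v[4, 4, 2] <- 5001
  m <- qualifyingMask(mk(v), 5000)
  expect_false(m[2, 3, 1])            # exactly at threshold: excluded
  expect_true(m[4, 4, 2])
  # wire distance against the brute-force oracle
  wires <- data.frame(x1 = 0, y1 = 0, z1 = 0, x2 = 650, y2 = 390,
                      z2 = 130, label = 1L, diameter_nm = 200)
  big <- mk(array(6000, dims))
  mw <- qualifyingMask(big, 5000, wires = wires, maxDistNm = 400)
  a <- as.numeric(wires[1, 1:3]); b <- as.numeric(wires[1, 4:6])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    for (k in seq_len(dims[3])) {
      p <- (c(i, j, k) - 1) * 130
      expect_equal(mw[i, j, k],
                   oracle_point_segment_dist(p, a, b) < 400)
    }
  }
})

test_that("parallelism: aligned, orthogonal, and uniform-axis means", {
  dims <- c(20L, 20L, 5L)
  n <- prod(dims)
  wires <- data.frame(x1 = 0, y1 = 1300, z1 = 260, x2 = 2470, y2 = 1300,
                      z2 = 260, label = 1L, diameter_nm = 200)
  mask <- array(TRUE, dims)
  alongX <- manual_peaks(matrix(rep(c(1, 0, 0), each = n), n), dims)
  p1 <- parallelism(alongX, wires, mask)
  expect_equal(p1$mean, 1, tolerance = 1e-12)
  expect_equal(p1$sd, 0, tolerance = 1e-12)
  alongZ <- manual_peaks(matrix(rep(c(0, 0, 1), each = n), n), dims)
  expect_equal(parallelism(alongZ, wires, mask)$mean, 0,
               tolerance = 1e-12)
  # uniform random axes: E|cos theta| = 1/2 (mean of |u.t| for u uniform
  # on the sphere), Monte Carlo tolerance ~4 / sqrt(12 n)
  set.seed(99)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pu <- parallelism(manual_peaks(u, dims), wires, mask)
  expect_equal(pu$mean, 0.5, tolerance = 4 / sqrt(12 * n))
  expect_error(parallelism(alongX, wires, array(FALSE, dims)), "empty")
})

test_that("radiality: radial peaks score 1, tangent peaks 0, on-axis voxels
           are excluded, crossed > single on tangent-aligned fields", {
  dims <- c(12L, 12L, 5L)
  n <- prod(dims)
  # wire along x at the grid center plane
  wires <- data.frame(x1 = 0, y1 = 650, z1 = 260, x2 = 1430, y2 = 650,
                      z2 = 260, label = 1L, diameter_nm = 200)
  mask <- array(TRUE, dims)
  # peaks pointing along the perpendicular offset from the wire axis
  co <- odfscope:::.voxel_coords(dims, 130)
  P <- cbind(rep(co$x, times = dims[2] * dims[3]),
             rep(rep(co$y, each = dims[1]), times = dims[3]),
             rep(co$z, each = dims[1] * dims[2]))
  off <- cbind(0, P[, 2] - 650, P[, 3] - 260)
  nrm <- sqrt(rowSums(off^2)); nrm[nrm == 0] <- 1
  r1 <- radiality(manual_peaks(off / nrm, dims), wires, mask)
  expect_equal(r1$mean, 1, tolerance = 1e-9)
  expect_gt(r1$nExcludedOnWire, 0)   # voxels on the wire axis dropped
  alongX <- manual_peaks(matrix(rep(c(1, 0, 0), each = n), n), dims)
  expect_equal(radiality(alongX, wires, mask)$mean, 0, tolerance = 1e-12)
  # tangent-aligned fiber fields: radiality rises from single to crossed
  fs <- wireFixture("single", dims = c(24L, 24L, 12L))
  fc <- wireFixture("crossed", dims = c(24L, 24L, 12L))
  ps <- peakField(fs$field, mask = fs$tubeMask)
  pc <- peakField(fc$field, mask = fc$tubeMask)
  rs <- radiality(ps, fs$wires, fs$tubeMask)$mean
  rc <- radiality(pc, fc$wires, fc$tubeMask)$mean
  expect_gt(rc, rs)
})

test_that("aspect ratio: ball, cuboid oracle, mass-scale invariance", {
  # uniform ball
  dims <- c(25L, 25L, 25L)
  co <- (seq_len(25) - 13)
  R2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  ball <- array(as.numeric(R2 <= 10^2), dims)
  ar <- aspectRatio(ball, spacingNm = 130)
  expect_equal(ar$ratio, 1, tolerance = 0.02)
  # 40 x 10 x 10 voxel cuboid: eigenvalues follow the exact discrete
  # variances V(n) = (n^2 - 1)/12, ratio = (V40 + V10) / (V10 + V10)
  cub <- array(1, c(40L, 10L, 10L))
  arc <- aspectRatio(cub, spacingNm = 1)
  v40 <- (40^2 - 1) / 12; v10 <- (10^2 - 1) / 12
  expect_equal(arc$ratio, (v40 + v10) / (v10 + v10), tolerance = 1e-10)
  expect_equal(aspectRatio(5 * cub, spacingNm = 1)$ratio, arc$ratio,
               tolerance = 1e-12)
  # a line of mass has zero inertia about its own axis -> degenerate
  line <- array(0, dims); line[, 13, 13] <- 1
  ar1 <- aspectRatio(line, spacingNm = 1)
  expect_true(is.infinite(ar1$ratio) && ar1$degenerate)
})

test_that("angular histogram: center/edge binning and count conservation", {
  dims <- c(8L, 8L, 4L)
  n <- prod(dims)
  mask <- array(TRUE, dims)
  alongView <- manual_peaks(matrix(rep(c(0, 0, 1), each = n), n), dims)
  h <- angularHistogram(alongView, mask)
  expect_equal(h$counts[[1]][1], n)          # all in the central bin
  expect_equal(h$total, n)
  inPlane <- manual_peaks(matrix(rep(c(1, 0, 0), each = n), n), dims)
  h2 <- angularHistogram(inPlane, mask)
  expect_equal(sum(h2$counts[[length(h2$counts)]]), n)  # all on the edge
  set.seed(4)
  u <- matrix(rnorm(3 * n), n, 3); u <- u / sqrt(rowSums(u^2))
  h3 <- angularHistogram(manual_peaks(u, dims), mask)
  expect_equal(h3$total, n)                  # conservation
})

test_that("group statistics match closed forms", {
  rows <- data.frame(
    id = paste0("c", 1:9),
    arrangement = rep(c("single", "paired", "crossed"), each = 3),
    parallelism = c(0.88, 0.87, 0.89, 0.89, 0.90, 0.88, 0.70, 0.72, 0.68),
    radiality = c(0.17, 0.18, 0.16, 0.20, 0.19, 0.21, 0.51, 0.49, 0.53),
    aspectRatio = c(8, 7.5, 8.5, 7, 7.2, 6.8, 3, 3.2, 2.8))
  gc <- groupCompare(rows)
  # hand-computed pooled two-sample t on the single-vs-crossed parallelism
  x <- rows$parallelism[1:3]; y <- rows$parallelism[7:9]
  sp <- sqrt(((2) * var(x) + (2) * var(y)) / 4)
  tref <- (mean(x) - mean(y)) / (sp * sqrt(1 / 3 + 1 / 3))
  got <- gc$tTests[gc$tTests$metric == "parallelism" &
                   gc$tTests$group1 == "single" &
                   gc$tTests$group2 == "crossed", ]
  expect_equal(got$t, tref, tolerance = 1e-10)
  expect_equal(got$df, 4)
  # identical groups: t = 0, p = 1
  same <- rows; same$parallelism <- rep(c(0.8, 0.9, 0.85), 3)
  gs <- groupCompare(same, metrics = "parallelism")
  expect_true(all(abs(gs$tTests$t) < 1e-12))
  expect_true(all(gs$tTests$p > 0.999))
  # perfectly linear metric vs aspect ratio: |r| = 1
  lin <- rows; lin$radiality <- 1 - 0.1 * lin$aspectRatio
  gl <- groupCompare(lin, metrics = "radiality")
  expect_equal(abs(gl$correlations$r), 1, tolerance = 1e-12)
  expect_error(groupCompare(rows[c(1, 4, 7), ]), ">= 2 rows")
})
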