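# Phantom generators: Watson ODFs, shell (GUV), fibers, wire fixtures.

test_that("Watson ODFs: isotropy, polar and girdle shapes, unit mass", {
  g <- sphereGrid()
  iso <- watsonODF(c(0, 0, 1), 0, g)
  expect_equal(gfa(iso), 0, tolerance = 1e-10)
  expect_equal(iso[1] * sqrt(4 * pi), 1, tolerance = 1e-10)  # unit mass
  polar <- watsonODF(c(0, 0, 1), 5, g)
  expect_equal(polar[1] * sqrt(4 * pi), 1, tolerance = 1e-10)
  pk <- peakOrientation(polar)
  expect_lt(axis_angle_deg(pk$axis, c(0, 0, 1)), 2)
  girdle <- watsonODF(c(0, 0, 1), -5, g)
  expect_gt(gfa(girdle), 0)
  # girdle maximum lies in the xy-plane: equatorial value > polar value
  eq <- shEvaluate(girdle, matrix(c(1, 0, 0), 1))
  pole <- shEvaluate(girdle, matrix(c(0, 0, 1), 1))
  expect_gt(eq, pole)
  expect_warning(watsonODF(c(0, 0, 1), 20, g), "band limit")
})

test_that("GUV phantom: radial truth, spherical symmetry, documented scale", {
  ph <- guvPhantom(dims = c(33L, 33L, 33L), radiusNm = 1500,
                   widthNm = 260, kappa = 5)
  expect_s4_class(ph$field, "ODFField")
  expect_gt(sum(ph$shellMask), 0)
  # ground truth is exactly radial by construction
  ctr <- (dim(ph$field)[1:3] - 1) / 2 * voxelSpacingNm(ph$field)
  idx <- which(ph$shellMask, arr.ind = TRUE)
  for (r in sample(nrow(idx), 25)) {
    v <- (idx[r, ] - 1) * voxelSpacingNm(ph$field) - ctr
    tru <- ph$truthAxes[idx[r, 1], idx[r, 2], idx[r, 3], ]
    expect_lt(axis_angle_deg(v, tru), 1e-6)
  }
  # density is mirror-symmetric about the central voxel plane
  dens <- densityMap(ph$field)
  expect_equal(dens, dens[33:1, , ], tolerance = 1e-10)
  expect_equal(dens, dens[, , 33:1], tolerance = 1e-10)
  # default shell radius matches the ~6 um vesicle diameter
  expect_equal(formals(guvPhantom)$radiusNm, 3000)
  expect_error(guvPhantom(dims = c(16L, 16L, 16L), radiusNm = 3000),
               "exceeds")
})

test_that("fiber phantom: straight tangents, additive crossings, helix", {
  sp <- 130
  straight <- fiberPhantom(rbind(c(0, 1560, 1560), c(3120, 1560, 1560)),
                           dims = c(25L, 25L, 25L), spacingNm = sp,
                           radiusNm = 200, kappa = 5)
  expect_gt(sum(straight$tubeMask), 0)
  tr <- matrix(straight$truthAxes, ncol = 3)[as.vector(straight$tubeMask), ]
  expect_true(all(abs(tr[, 1]) > 1 - 1e-9))
  # crossing voxel = sum of the two Watson lobes (linearity)
  cross <- fiberPhantom(rbind(c(1560, 0, 1560), c(1560, 3120, 1560)),
                        dims = c(25L, 25L, 25L), spacingNm = sp,
                        radiusNm = 200, kappa = 5,
                        field = straight$field)
  mid <- c(13L, 13L, 13L)
  g <- sphereGrid()
  expected <- watsonODF(c(1, 0, 0), 5, g) + watsonODF(c(0, 1, 0), 5, g)
  expect_equal(cross$field@coefficients[mid[1], mid[2], mid[3], ],
               expected, tolerance = 1e-8)
  # gentle helix: phantom ODF peaks track the local tangent within 5 deg
  t <- seq(0, 2 * pi, length.out = 60)
  helix <- cbind(2000 + 1200 * cos(t), 2000 + 1200 * sin(t),
                 500 + 3000 * t / (2 * pi))
  hph <- fiberPhantom(helix, dims = c(32L, 32L, 32L), spacingNm = sp,
                      radiusNm = 150, kappa = 8)
  pk <- peakField(hph$field, mask = hph$tubeMask)
  ax <- matrix(pk@axes, ncol = 3)
  tru <- matrix(hph$truthAxes, ncol = 3)
  sel <- which(as.vector(hph$tubeMask))
  ang <- acos(pmin(1, abs(rowSums(ax[sel, ] * tru[sel, ])))) * 180 / pi
  expect_lt(stats::quantile(ang, 0.9), 5)
})

test_that("wire fixtures: arrangement geometry and ground truth", {
  single <- wireFixture("single", dims = c(24L, 24L, 12L))
  expect_equal(nrow(single$wires), 1L)
  paired <- wireFixture("paired", dims = c(24L, 24L, 12L))
  expect_equal(nrow(paired$wires), 2L)
  # parallel wires: identical direction vectors
  d1 <- unlist(paired$wires[1, 4:6]) - unlist(paired$wires[1, 1:3])
  d2 <- unlist(paired$wires[2, 4:6]) - unlist(paired$wires[2, 1:3])
  expect_equal(abs(sum(d1 * d2)) / sqrt(sum(d1^2) * sum(d2^2)), 1,
               tolerance = 1e-12)
  crossed <- wireFixture("crossed", dims = c(24L, 24L, 12L))
  d1 <- unlist(crossed$wires[1, 4:6]) - unlist(crossed$wires[1, 1:3])
  d2 <- unlist(crossed$wires[2, 4:6]) - unlist(crossed$wires[2, 1:3])
  expect_equal(sum(d1 * d2), 0)
  expect_true(all(single$wires$diameter_nm == 200))
  # zero disorder: every in-tube ODF peaks along its wire tangent
  pk <- peakField(single$field, mask = single$tubeMask)
  m <- parallelism(pk, single$wires, single$tubeMask)
  expect_gte(m$mean, 0.999)
  # a disordered fraction lowers parallelism, deterministically per seed
  dis1 <- wireFixture("single", dims = c(24L, 24L, 12L),
                      disorderedFraction = 0.5, seed = 9L)
  dis2 <- wireFixture("single", dims = c(24L, 24L, 12L),
                      disorderedFraction = 0.5, seed = 9L)
  expect_equal(dis1$field@coefficients, dis2$field@coefficients)
  pkd <- peakField(dis1$field, mask = dis1$tubeMask)
  expect_lt(parallelism(pkd, dis1$wires, dis1$tubeMask)$mean, m$mean)
})
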