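# Forward model: linearity, shift invariance, DC equivalence with direct
# sphere quadrature, and the noise models.

# single-voxel field helper
point_field <- function(coeffs, dims = c(9L, 9L, 9L), spacingNm = 130) {
  cf <- array(0, c(dims, 15L))
  mid <- (dims + 1L) %/% 2L
  cf[mid[1], mid[2], mid[3], ] <- coeffs
  odfField(cf, spacingNm)
}

test_that("zero fields map to zero volumes; doubling doubles", {
  sch <- makeScheme("six_no_tilt")
  z <- point_field(rep(0, 15))
  st <- quiet_fp(z, sch, pad = 4L)
  expect_true(all(vapply(stackVolumes(st), function(v) all(v == 0),
                         logical(1))))
  f1 <- point_field(watsonODF(c(0, 0, 1), 4))
  f2 <- odfField(2 * f1@coefficients, f1@spacingNm)
  s1 <- quiet_fp(f1, sch, pad = 4L)
  s2 <- quiet_fp(f2, sch, pad = 4L)
  for (p in 1:6) {
    expect_equal(s2@volumes[[p]], 2 * s1@volumes[[p]], tolerance = 1e-12)
  }
})

test_that("DC totals equal direct angular quadrature of the weighted ODF", {
  # independent oracle: total signal = sum_j wq_j w_p(s_j) f(s_j) with the
  # weights computed from raw geometry, bypassing the transfer function
  g <- sphereGrid()
  cfg <- opticsConfig()
  sch <- makeScheme("six_with_tilt")
  gain <- odfscope:::.optics_gain(cfg, g)
  for (coeffs in list(watsonODF(c(0, 0, 1), 5),
                      watsonODF(c(1, 0, 0), 5))) {
    # circular boundaries (pad = 0) keep the volume total exactly G(0)
    fld <- point_field(coeffs)
    st <- quiet_fp(fld, sch, cfg, pad = 0L)
    fvals <- shEvaluate(coeffs, g)
    for (p in 1:6) {
      sp <- sch@specs[p, ]
      geo <- measurementGeometry(sp$illumView, sp$psi, sp$tau, cfg)
      dc <- detectionConstants(geo$naDet, cfg@n)
      w <- gain * drop((gridDirections(g) %*% geo$p)^2) *
        (dc["C1"] + dc["C2"] * (1 - drop(gridDirections(g) %*%
                                         geo$detAxis)^2))
      expect_equal(sum(st@volumes[[p]]), sum(gridWeights(g) * w * fvals),
                   tolerance = 1e-6)
    }
  }
  # polarization contrast differs between z- and x-oriented dipoles
  stz <- quiet_fp(point_field(watsonODF(c(0, 0, 1), 5)), sch, pad = 0L)
  stx <- quiet_fp(point_field(watsonODF(c(1, 0, 0), 5)), sch, pad = 0L)
  tz <- vapply(stz@volumes, sum, numeric(1))
  tx <- vapply(stx@volumes, sum, numeric(1))
  expect_gt(max(abs(tz / sum(tz) - tx / sum(tx))), 0.01)
})

test_that("isotropic point sources: same-view untilted volumes coincide only
           in the NA = n limit", {
  iso <- point_field(watsonODF(c(0, 0, 1), 0))
  # full-aperture detection (NA = n): C2 = 0, so polarization rotation
  # within a view cannot change an isotropic signal
  cfgFull <- opticsConfig(naA = 1.33, naB = 1.33)
  sch <- makeScheme("six_no_tilt")
  st <- quiet_fp(iso, sch, cfgFull, pad = 0L)
  expect_equal(st@volumes[[1]], st@volumes[[2]], tolerance = 1e-9)
  expect_equal(st@volumes[[2]], st@volumes[[3]], tolerance = 1e-9)
  # finite NA: the excited lobe's angle to the detection axis varies with
  # psi, so same-view totals genuinely differ
  stF <- quiet_fp(iso, sch, opticsConfig(), pad = 0L)
  expect_gt(abs(sum(stF@volumes[[1]]) - sum(stF@volumes[[2]])),
            1e-4 * sum(stF@volumes[[1]]))
})

test_that("circular shift of the field shifts every volume identically", {
  set.seed(8)
  dims <- c(12L, 12L, 12L)
  cf <- array(rnorm(prod(dims) * 15, sd = 0.05), c(dims, 15L))
  cf[, , , 1] <- abs(cf[, , , 1])
  fld <- odfField(cf, 130)
  sh <- c(3L, 5L, 2L)
  cfs <- cf[c((dims[1] - sh[1] + 1):dims[1], 1:(dims[1] - sh[1])), , , ,
            drop = FALSE]
  cfs <- cfs[, c((dims[2] - sh[2] + 1):dims[2], 1:(dims[2] - sh[2])), , ,
             drop = FALSE]
  cfs <- cfs[, , c((dims[3] - sh[3] + 1):dims[3], 1:(dims[3] - sh[3])), ,
             drop = FALSE]
  sch <- makeScheme("six_with_tilt")
  s0 <- quiet_fp(fld, sch, pad = 0L)
  s1 <- quiet_fp(odfField(cfs, 130), sch, pad = 0L)
  for (p in 1:6) {
    v <- s0@volumes[[p]]
    vs <- v[c((dims[1] - sh[1] + 1):dims[1], 1:(dims[1] - sh[1])), , ]
    vs <- vs[, c((dims[2] - sh[2] + 1):dims[2], 1:(dims[2] - sh[2])), ]
    vs <- vs[, , c((dims[3] - sh[3] + 1):dims[3], 1:(dims[3] - sh[3]))]
    expect_equal(s1@volumes[[p]], vs, tolerance = 1e-6)
  }
})

test_that("noise models: reproducibility, mean preservation, Poisson
           variance, and guards", {
  dims <- c(50L, 50L, 50L)
  v <- array(5, dims)
  st <- new("IrradianceStack", volumes = list(v),
            scheme = makeScheme("custom", specs = data.frame(
              illumView = "A", psi = 0, tau = 0)),
            spacingNm = 130, countsPerUnit = 1, noiseModel = "none",
            seed = NA_real_)
  n1 <- addNoise(st, "poisson", countsPerUnit = 1, seed = 42L)
  n2 <- addNoise(st, "poisson", countsPerUnit = 1, seed = 42L)
  expect_identical(n1@volumes[[1]], n2@volumes[[1]])
  # Poisson: sample variance matches the mean within 5% at 1.25e5 voxels
  counts <- n1@volumes[[1]]
  expect_equal(stats::var(as.vector(counts)) / mean(counts), 1,
               tolerance = 0.05)
  # large photon budgets recover the noiseless stack
  hi <- addNoise(st, "poisson", countsPerUnit = 1e6, seed = 1L)
  expect_lt(max(abs(hi@volumes[[1]] - v)) / 5, 0.01)
  neg <- st; neg@volumes[[1]][1] <- -1
  expect_error(addNoise(neg, "poisson"), "nonnegative")
})
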