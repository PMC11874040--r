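# Tikhonov reconstruction: inverse-operator algebra, round trips on the
# recoverable subspace, the untilted (2,1) failure, and estimator
# properties.

test_that("inverse operators match an independent ridge oracle and behave
           in the eta limits", {
  sch <- makeScheme("six_with_tilt")
  tf <- quiet_tf(sch, dims = c(8L, 8L, 8L), spacingNm = 130)
  idx <- list(c(1L, 1L, 1L), c(2L, 3L, 1L), c(4L, 2L, 5L))
  for (eta in c(0.5, 0.01)) {
    Ws <- buildInverseOperators(tf, idx, eta = eta)
    for (i in seq_along(idx)) {
      H <- transferMatrixAt(tf, idx[[i]])
      # oracle: ridge via QR of the augmented system [H; sqrt(eta) I]
      Aug <- rbind(H, sqrt(eta) * diag(15L))
      Wq <- t(vapply(1:6, function(j) {
        qr.solve(Aug, c(diag(6L)[, j], rep(0, 15L)))
      }, numeric(15L)))
      expect_equal(Ws[[i]], t(Wq), tolerance = 1e-10)
    }
  }
  # eta -> infinity drives W to zero
  Wbig <- buildInverseOperators(tf, idx[1], eta = 1e12)[[1]]
  expect_lt(max(abs(Wbig)), 1e-9)
  # eta = 0: W H is the orthogonal projector onto the recoverable
  # subspace (idempotent, symmetric, trace = rank 6)
  expect_warning(W0 <- buildInverseOperators(tf, idx[1], eta = 0)[[1]],
                 "pseudo-inverse")
  H <- transferMatrixAt(tf, idx[[1]])
  P <- W0 %*% H
  expect_equal(P %*% P, P, tolerance = 1e-8)
  expect_equal(P, t(P), tolerance = 1e-8)
  expect_equal(sum(diag(P)), 6, tolerance = 1e-8)
})

test_that("noiseless round trip recovers the projected truth within the
           common frequency support; the untilted scheme drops (2,1)", {
  ph <- guvPhantom(dims = c(32L, 32L, 32L), radiusNm = 1600,
                   widthNm = 260, kappa = 5)
  spectra <- function(field) {
    sapply(1:15, function(k) as.vector(stats::fft(
      field@coefficients[, , , k])))
  }
  subspace_projector <- function(tf) {
    sv <- svd(tf@a)
    keep <- sv$d > 1e-8 * sv$d[1]
    sv$v[, keep, drop = FALSE] %*% t(sv$v[, keep, drop = FALSE])
  }
  run <- function(scheme) {
    tf <- quiet_tf(scheme, dims = c(32L, 32L, 32L), spacingNm = 130)
    st <- quiet_fp(ph$field, scheme, pad = 0L, tf = tf)
    rc <- quiet_rec(st, rcfg = reconConfig(eta = 1e-6), pad = 0L, tf = tf)
    # well-transmitted common support: both views' OTFs above threshold
    # so that b^2 dominates eta
    m <- as.vector(tf@otfA > 0.02 & tf@otfB > 0.02)
    list(Fr = spectra(rc), Ft = spectra(ph$field) %*%
           t(subspace_projector(tf)), m = m, rc = rc)
  }
  rt <- run(makeScheme("six_with_tilt"))
  for (k in 1:6) {     # all l = 0 and l = 2 channels
    cc <- stats::cor(c(Re(rt$Ft[rt$m, k]), Im(rt$Ft[rt$m, k])),
                     c(Re(rt$Fr[rt$m, k]), Im(rt$Fr[rt$m, k])))
    expect_gt(cc, 0.99)
  }
  # untilted: the projected truth is still matched on the transmitted
  # channels, but the (2,1) channel of the raw truth is not recovered
  rt0 <- run(makeScheme("six_no_tilt"))
  for (k in c(2, 3, 4, 6)) {
    cc <- stats::cor(c(Re(rt0$Ft[rt0$m, k]), Im(rt0$Ft[rt0$m, k])),
                     c(Re(rt0$Fr[rt0$m, k]), Im(rt0$Fr[rt0$m, k])))
    expect_gt(cc, 0.95)
  }
  c21 <- stats::cor(as.vector(rt0$rc@coefficients[, , , 5]),
                    as.vector(ph$field@coefficients[, , , 5]))
  expect_lt(abs(c21), 0.2)
})

test_that("zero stacks give zero fields; the estimator is linear", {
  sch <- makeScheme("six_with_tilt")
  dims <- c(12L, 12L, 12L)
  tf <- quiet_tf(sch, dims = dims + 8L, spacingNm = 130)
  zero <- new("IrradianceStack",
              volumes = replicate(6, array(0, dims), simplify = FALSE),
              scheme = sch, spacingNm = 130, countsPerUnit = 1,
              noiseModel = "none", seed = NA_real_)
  rc0 <- quiet_rec(zero, rcfg = reconConfig(), pad = 4L, tf = tf)
  expect_equal(max(abs(rc0@coefficients)), 0)
  set.seed(21)
  vols <- replicate(6, array(abs(rnorm(prod(dims))), dims),
                    simplify = FALSE)
  st <- zero; st@volumes <- vols
  st3 <- zero; st3@volumes <- lapply(vols, function(v) 3 * v)
  r1 <- quiet_rec(st, rcfg = reconConfig(), pad = 4L, tf = tf)
  r3 <- quiet_rec(st3, rcfg = reconConfig(), pad = 4L, tf = tf)
  expect_equal(r3@coefficients, 3 * r1@coefficients, tolerance = 1e-9)
})

test_that("increasing eta monotonically shrinks the output energy", {
  ph <- guvPhantom(dims = c(16L, 16L, 16L), radiusNm = 700,
                   widthNm = 260, kappa = 5)
  sch <- makeScheme("six_with_tilt")
  tf <- quiet_tf(sch, dims = c(24L, 24L, 24L), spacingNm = 130)
  st <- quiet_fp(ph$field, sch, pad = 4L, tf = tf)
  energies <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1, 1), function(eta) {
    rc <- quiet_rec(st, rcfg = reconConfig(eta = eta), pad = 4L, tf = tf)
    sum(rc@coefficients^2)
  }, numeric(1))
  expect_true(all(diff(energies) < 0))
})

test_that("coupled-mode reconstruction round-trips a small phantom", {
  ph <- guvPhantom(dims = c(16L, 16L, 16L), radiusNm = 700,
                   widthNm = 260, kappa = 5)
  sch <- makeScheme("six_with_tilt")
  tfc <- quiet_tf(sch, dims = c(16L, 16L, 16L), spacingNm = 130,
                  mode = "coupled")
  st <- quiet_fp(ph$field, sch, mode = "coupled", pad = 0L, tf = tfc)
  expect_equal(length(st@volumes), 6L)
  rc <- quiet_rec(st, rcfg = reconConfig(eta = 1e-4, mode = "coupled"),
                  pad = 0L, tf = tfc)
  # density recovered up to blur: strong spatial correlation on the shell
  cc <- stats::cor(as.vector(densityMap(rc)),
                   as.vector(densityMap(ph$field)))
  expect_gt(cc, 0.7)
})
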