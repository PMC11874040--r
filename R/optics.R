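# Physics kernels: polarized excitation, dipole emission, finite-NA
# detection, and the per-measurement angular response on the sphere.

#' Construct the optical configuration of the dual-view instrument
#'
#' Defaults follow the instrument modeled throughout the package: a
#' water-immersion dual-view pair with detection NAs 1.1 (view A, axis z)
#' and 0.67 (view B, axis x), 488 nm excitation, 500 nm emission.  Axial
#' blur scales: the light-sheet sigma defaults to 500 nm (a ~1.2 um FWHM
#' sheet) and each view's detection axial sigma to the diffraction scale
#' n * lambda / (2 NA^2).
#'
#' @param naA,naB detection numerical apertures (view A / view B).
#' @param n immersion refractive index.
#' @param lambdaExNm,lambdaEmNm wavelengths in nm.
#' @param sigmaLsNm light-sheet Gaussian sigma (nm).
#' @param sigmaDetANm,sigmaDetBNm detection axial Gaussian sigmas (nm).
#' @return an \linkS4class{OpticsConfig}.
#' @export
opticsConfig <- function(naA = 1.1, naB = 0.67, n = 1.33,
                         lambdaExNm = 488, lambdaEmNm = 500,
                         sigmaLsNm = 500,
                         sigmaDetANm = n * lambdaEmNm / (2 * naA^2),
                         sigmaDetBNm = n * lambdaEmNm / (2 * naB^2)) {
  new("OpticsConfig", naA = naA, naB = naB, n = n,
      lambdaExNm = lambdaExNm, lambdaEmNm = lambdaEmNm,
      sigmaLsNm = sigmaLsNm, sigmaDetANm = sigmaDetANm,
      sigmaDetBNm = sigmaDetBNm,
      detAxisA = c(0, 0, 1), detAxisB = c(1, 0, 0))
}

setMethod("show", "OpticsConfig", function(object) {
  cat("OpticsConfig: NA_A =", object@naA, "(det axis z), NA_B =",
      object@naB, "(det axis x), n =", object@n, "\n",
      " lambda_ex/em =", object@lambdaExNm, "/", object@lambdaEmNm, "nm;",
      "sigma_ls =", object@sigmaLsNm, "nm\n")
})

#' Transverse diffraction-limited resolution
#'
#' lambda / (2 NA) at the emission wavelength; 227 nm for the default
#' high-NA view (500 nm / 2.2).
#'
#' @param cfg an \linkS4class{OpticsConfig}.
#' @param view "A" or "B".
#' @return resolution in nm.
#' @export
transverseResolutionNm <- function(cfg = opticsConfig(), view = "A") {
  na <- if (view == "A") cfg@naA else cfg@naB
  cfg@lambdaEmNm / (2 * na)
}

#' Polarized excitation efficiency of a dipole
#'
#' cos^2(theta) selection: the probability of exciting a dipole is the
#' squared cosine of the angle between its axis and the illumination
#' polarization.
#'
#' @param dipole unit 3-vector (or n x 3 matrix) of dipole axes.
#' @param polarization unit 3-vector.
#' @return scalar (or vector) in [0, 1].
#' @export
excitationWeight <- function(dipole, polarization) {
  d <- if (is.null(dim(dipole))) matrix(dipole, nrow = 1L) else dipole
  stopifnot(abs(sum(polarization^2) - 1) < 1e-9,
            all(abs(rowSums(d^2) - 1) < 1e-9))
  drop((d %*% polarization)^2)
}

#' Orientation-dependent collection efficiency constants
#'
#' A dipole radiates a sin^2(phi) intensity pattern (phi measured from its
#' axis; total power normalized to 1 over the full sphere).  Integrating
#' that pattern over the collection cone of half-angle asin(NA/n) gives a
#' collected power of the form C1 + C2 sin^2(phi_d), where phi_d is the
#' angle between the dipole axis and the detection optical axis.  The
#' constants are computed by Gauss--Legendre quadrature of the cone
#' integral for an axial and a transverse dipole.
#'
#' @param na numerical aperture (0 < na <= n).
#' @param n refractive index.
#' @param nQuad quadrature points over the cone polar angle.
#' @return named numeric c(C1, C2).
#' @export
detectionConstants <- function(na, n = 1.33, nQuad = 64L) {
  if (na <= 0) stop("NA must be positive")
  if (na > n) stop("NA cannot exceed the refractive index")
  a <- cos(asin(na / n))            # cos of cone half-angle
  gl <- .gauss_legendre(nQuad)
  ct <- (gl$nodes + 1) / 2 * (1 - a) + a      # cos(theta) in [a, 1]
  wt <- gl$weights * (1 - a) / 2
  st2 <- 1 - ct^2
  # azimuthal integral of (mu . r)^2 done analytically:
  #   axial dipole (mu = z):      2*pi * ct^2
  #   transverse dipole (mu = x): pi * st^2
  pref <- 3 / (8 * pi)
  pAx <- pref * sum(wt * (2 * pi - 2 * pi * ct^2))
  pTr <- pref * sum(wt * (2 * pi - pi * st2))
  c(C1 = pAx, C2 = pTr - pAx)
}

#' Geometry of one polarized light-sheet measurement
#'
#' Resolves a (illumination view, polarization angle, tilt) triple into
#' world-frame vectors.  The untilted sheet propagates along the
#' illuminating objective's axis; tilt rotates the propagation direction
#' within the sheet plane, about the detection axis of the measurement
#' (the other objective), making new polarization orientations accessible.
#' psi is measured in the plane perpendicular to the tilted propagation
#' axis, with psi = 0 along the detection axis.
#'
#' @param illumView "A" or "B".
#' @param psi transverse polarization angle (rad).
#' @param tau light-sheet tilt (rad).
#' @param cfg an \linkS4class{OpticsConfig}.
#' @return list with \code{k} (propagation), \code{p} (polarization),
#'   \code{detAxis}, \code{detView}, \code{naDet}, \code{sigmaDetNm}.
#' @export
measurementGeometry <- function(illumView, psi, tau, cfg = opticsConfig()) {
  if (illumView == "A") {
    k0 <- cfg@detAxisA; e1 <- cfg@detAxisB
    detView <- "B"; naDet <- cfg@naB; sDet <- cfg@sigmaDetBNm
    detAxis <- cfg@detAxisB
  } else if (illumView == "B") {
    k0 <- cfg@detAxisB; e1 <- cfg@detAxisA
    detView <- "A"; naDet <- cfg@naA; sDet <- cfg@sigmaDetANm
    detAxis <- cfg@detAxisA
  } else stop("illumView must be 'A' or 'B'")
  e2 <- c(k0[2] * e1[3] - k0[3] * e1[2],
          k0[3] * e1[1] - k0[1] * e1[3],
          k0[1] * e1[2] - k0[2] * e1[1])
  kv <- cos(tau) * k0 + sin(tau) * e2
  e2t <- cos(tau) * e2 - sin(tau) * k0
  p <- cos(psi) * e1 + sin(psi) * e2t
  list(k = kv, p = p, detAxis = detAxis, detView = detView,
       naDet = naDet, sigmaDetNm = sDet)
}

# Normalization gain: scales all responses so that an isotropic
# unit-density ODF yields signal 1.0 in the brightest untilted measurement
# (fixes the arbitrary photometric gain of the model).
.optics_gain <- function(cfg, grid = sphereGrid()) {
  best <- 0
  for (v in c("A", "B")) {
    for (psi in c(0, pi / 4, pi / 2, 3 * pi / 4)) {
      w <- .raw_angular_weight(v, psi, 0, cfg, grid)
      best <- max(best, sum(grid@weights * w) / (4 * pi))
    }
  }
  1 / best
}

.raw_angular_weight <- function(illumView, psi, tau, cfg, grid) {
  geo <- measurementGeometry(illumView, psi, tau, cfg)
  dc <- detectionConstants(geo$naDet, cfg@n)
  d <- grid@directions
  ex <- drop((d %*% geo$p)^2)
  cd <- drop(d %*% geo$detAxis)
  ex * (dc["C1"] + dc["C2"] * (1 - cd^2))
}

#' Angular response of one measurement
#'
#' w(s) = |s . p|^2 * (C1 + C2 (1 - (s . d_det)^2)): the product of the
#' cos^2 excitation selectivity and the finite-NA detection efficiency.
#' The product of two quadratics in s is exactly band-limited to l <= 4,
#' so its 15 even-band coefficients capture it without truncation error.
#'
#' @param illumView "A" or "B"; @param psi polarization angle (rad);
#' @param tau tilt (rad).
#' @param cfg an \linkS4class{OpticsConfig}.
#' @param grid quadrature \linkS4class{SphereGrid}.
#' @param gain photometric gain; default normalizes the brightest untilted
#'   isotropic-ODF signal to 1.
#' @return list with \code{coefficients} (length-15), \code{values}
#'   (weights at grid directions) and the geometry.
#' @export
angularResponse <- function(illumView, psi, tau = 0, cfg = opticsConfig(),
                            grid = sphereGrid(), gain = NULL) {
  if (is.null(gain)) gain <- .optics_gain(cfg, grid)
  w <- gain * .raw_angular_weight(illumView, psi, tau, cfg, grid)
  list(coefficients = shProject(w, grid), values = w,
       geometry = measurementGeometry(illumView, psi, tau, cfg))
}

#' Zero-frequency angular system matrix of a scheme
#'
#' Rows are the 15 spherical-harmonic coefficients of each measurement's
#' angular response, expressed in the detection-axis-aligned frame (z along
#' the view-A axis, x along the view-B axis).  This is the matrix whose
#' column structure reveals angular holes.
#'
#' @param scheme a \linkS4class{MeasurementScheme}.
#' @param cfg an \linkS4class{OpticsConfig}.
#' @param grid quadrature grid.
#' @return n_meas x 15 numeric matrix.
#' @export
angularSystemMatrix <- function(scheme, cfg = opticsConfig(),
                                grid = sphereGrid()) {
  gain <- .optics_gain(cfg, grid)
  sp <- scheme@specs
  t(vapply(seq_len(nrow(sp)), function(i) {
    angularResponse(sp$illumView[i], sp$psi[i], sp$tau[i], cfg, grid,
                    gain = gain)$coefficients
  }, numeric(15L)))
}
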