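# Orientation-dependent point spread functions from a scalar-pupil
# vectorial approximation: the pupil field is the transverse part of the
# dipole far-field radiation pattern inside the aperture, apodized by the
# aplanatic sqrt(1/cos(theta)) factor; Fourier transforming to the image
# plane and summing component intensities reproduces the Airy-like pattern
# of a transverse dipole and the donut of an axial dipole.

#' Dipole point spread function (transverse image plane)
#'
#' @param dipole unit 3-vector giving the emitter's axis (world frame).
#' @param cfg an \linkS4class{OpticsConfig}.
#' @param view detecting view, "A" (axis z) or "B" (axis x).
#' @param nPupil samples across the pupil diameter.
#' @param pad zero-padding factor (image pixel = lambda/(2 NA pad)).
#' @return list with \code{intensity} (matrix), \code{pixelNm}, and
#'   \code{energy} (integral over the image plane; equals the collection
#'   efficiency C1 + C2 sin^2(phi_d) of \code{\link{detectionConstants}}
#'   up to pupil discretization).
#' @export
dipolePsf <- function(dipole, cfg = opticsConfig(), view = "A",
                      nPupil = 64L, pad = 4L) {
  stopifnot(abs(sum(dipole^2) - 1) < 1e-9)
  na <- if (view == "A") cfg@naA else cfg@naB
  # rotate world coords into the detection frame: view A keeps (x, y, z);
  # view B maps (x', y', z') = (y, z, x) so the image axes are (y, z)
  mu <- if (view == "A") dipole else c(dipole[2], dipole[3], dipole[1])
  n <- nPupil * pad
  u <- (seq_len(n) - 1 - n %/% 2) * (2 / nPupil)   # pupil coords, |u|<=pad
  U <- matrix(u, n, n); V <- t(U)
  rho2 <- U^2 + V^2
  inA <- rho2 <= 1
  s <- na / cfg@n
  st <- sqrt(pmax(0, rho2)) * s
  ct <- sqrt(pmax(0, 1 - st^2))
  phi <- atan2(V, U)
  # far-field (theta, phi) components of the dipole radiation pattern;
  # collimation maps theta-hat -> rho-hat and phi-hat -> phi-hat, so the
  # pupil field is purely transverse
  cphi <- cos(phi); sphi <- sin(phi)
  eTheta <- mu[1] * ct * cphi + mu[2] * ct * sphi - mu[3] * st
  ePhi <- -mu[1] * sphi + mu[2] * cphi
  apod <- sqrt(3 / (8 * pi)) * s / sqrt(pmax(ct, 1e-6))
  Ex <- ifelse(inA, apod * (eTheta * cphi - ePhi * sphi), 0)
  Ey <- ifelse(inA, apod * (eTheta * sphi + ePhi * cphi), 0)
  dA <- (2 / nPupil)^2
  I <- (Mod(stats::fft(Ex))^2 + Mod(stats::fft(Ey))^2) * dA / n^2
  # center the origin
  shift <- function(m) {
    i <- c((n %/% 2 + 1):n, 1:(n %/% 2)); m[i, i]
  }
  I <- shift(I)
  list(intensity = I, pixelNm = cfg@lambdaEmNm / (2 * na * pad),
       energy = sum(I))
}

# Dipole PSF sampled directly on a voxel grid (n x n, spacing nm), energy
# renormalized to the exact collection efficiency; used by the coupled
# transfer-function mode.  Returns the centered PSF matrix.
.dipole_psf_on_grid <- function(dipole, cfg, view, n, spacingNm) {
  na <- if (view == "A") cfg@naA else cfg@naB
  mu <- if (view == "A") dipole else c(dipole[2], dipole[3], dipole[1])
  dnu <- 1 / (n * spacingNm)                 # cycles / nm
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * dnu
  NU <- matrix(k, n, n); NV <- t(NU)
  st <- sqrt(NU^2 + NV^2) * cfg@lambdaEmNm / cfg@n
  inA <- st <= na / cfg@n
  st <- pmin(st, 1)
  ct <- sqrt(pmax(0, 1 - st^2))
  phi <- atan2(NV, NU)
  cphi <- cos(phi); sphi <- sin(phi)
  eTheta <- mu[1] * ct * cphi + mu[2] * ct * sphi - mu[3] * st
  ePhi <- -mu[1] * sphi + mu[2] * cphi
  apod <- 1 / sqrt(pmax(ct, 1e-6))
  Ex <- ifelse(inA, apod * (eTheta * cphi - ePhi * sphi), 0)
  Ey <- ifelse(inA, apod * (eTheta * sphi + ePhi * cphi), 0)
  I <- Mod(stats::fft(Ex))^2 + Mod(stats::fft(Ey))^2
  dc <- detectionConstants(na, cfg@n)
  cphi <- sum(mu * c(0, 0, 1))
  eff <- unname(dc["C1"] + dc["C2"] * (1 - cphi^2))
  I * (eff / sum(I))
}
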