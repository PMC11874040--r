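# Spatio-angular transfer functions H_pv,lm(nu): for each measurement and
# 3D spatial frequency, the 15 coefficients mapping the object's
# spherical-harmonic spectrum to the measured irradiance spectrum.
# Only even-l columns exist (antipodal symmetry) and per-view transverse
# frequencies beyond 2 NA_v / lambda are not detected.

#' Spatio-angular transfer function of a scheme on a voxel grid
#'
#' Two fidelity modes.  "factored": H(nu) = B_v(nu) * a_lm with a the
#' angular-response coefficients and B_v a scalar OTF -- the product of
#' the detection transverse OTF (circular-aperture autocorrelation, strict
#' cutoff 2 NA_v / lambda) and a Gaussian axial OTF combining light-sheet
#' thickness and detection axial response.  "coupled": per-(l,m) transverse
#' kernels obtained by projecting the orientation dependence of the dipole
#' PSF onto the spherical harmonics, so the spatial shape varies with the
#' angular index (the point response does not factor into spatial x
#' angular parts); both modes agree at nu = 0 and share the band limits.
#'
#' @slot mode "factored" or "coupled".
#' @slot a n_meas x 15 zero-frequency angular matrix (photometric gain
#'   applied).
#' @slot detView character vector: detecting view per measurement.
#' @slot otfA,otfB 3D arrays of the per-view scalar OTF (factored mode).
#' @slot kernels coupled mode: list per view of complex (n1*n2) x 15
#'   transverse kernel spectra.
#' @slot dims integer grid dimensions (nx, ny, nz).
#' @slot spacingNm voxel spacing.
#' @export
setClass("TransferFunction",
  representation(mode = "character", a = "matrix", detView = "character",
                 otfA = "array", otfB = "array", kernels = "list",
                 dims = "integer", spacingNm = "numeric",
                 cfg = "OpticsConfig")
)

setMethod("show", "TransferFunction", function(object) {
  cat("TransferFunction (", object@mode, "): ", length(object@detView),
      " measurements on a ", paste(object@dims, collapse = "x"),
      " grid @ ", object@spacingNm, " nm\n", sep = "")
})

# fft frequencies (cycles/nm) for n samples at `spacing` nm
.fft_freq <- function(n, spacingNm) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  if (n == 1L) k <- 0L
  k / (n * spacingNm)
}

# circular-aperture incoherent OTF ("chat" function), cutoff nuc
.chat_otf <- function(nu, nuc) {
  r <- pmin(abs(nu) / nuc, 1)
  ifelse(abs(nu) < nuc, (2 / pi) * (acos(r) - r * sqrt(1 - r^2)), 0)
}

# scalar OTF of one detection view on the full 3D frequency grid
.view_otf <- function(view, cfg, dims, spacingNm) {
  fx <- .fft_freq(dims[1], spacingNm)
  fy <- .fft_freq(dims[2], spacingNm)
  fz <- .fft_freq(dims[3], spacingNm)
  na <- if (view == "A") cfg@naA else cfg@naB
  sdet <- if (view == "A") cfg@sigmaDetANm else cfg@sigmaDetBNm
  sAx <- sqrt(cfg@sigmaLsNm^2 + sdet^2)
  nuc <- 2 * na / cfg@lambdaEmNm
  if (view == "A") {
    # detection axis z: transverse = (x, y), axial = z
    tr <- outer(fx, fy, function(a, b) .chat_otf(sqrt(a^2 + b^2), nuc))
    ax <- exp(-2 * pi^2 * sAx^2 * fz^2)
    array(outer(tr, ax), dims)
  } else {
    # detection axis x: transverse = (y, z), axial = x
    tr <- outer(fy, fz, function(a, b) .chat_otf(sqrt(a^2 + b^2), nuc))
    ax <- exp(-2 * pi^2 * sAx^2 * fx^2)
    aperm(array(outer(tr, ax), c(dims[2], dims[3], dims[1])), c(3, 1, 2))
  }
}

#' @rdname TransferFunction-class
#' @param scheme a \linkS4class{MeasurementScheme}.
#' @param cfg an \linkS4class{OpticsConfig}.
#' @param dims integer length-3 voxel grid dimensions.
#' @param spacingNm voxel spacing (nm).
#' @param mode "factored" (default) or "coupled".
#' @param grid quadrature \linkS4class{SphereGrid} (coupled mode projects
#'   the PSF orientation dependence over it).
#' @param maxTiltRad largest tilt magnitude the model accepts (rad).
#' @return a \linkS4class{TransferFunction}.
#' @export
transferFunction <- function(scheme, cfg = opticsConfig(),
                             dims = c(48L, 48L, 48L), spacingNm = 130,
                             mode = c("factored", "coupled"),
                             grid = sphereGrid(), maxTiltRad = 35 * pi / 180) {
  mode <- match.arg(mode)
  dims <- as.integer(dims)
  sp <- scheme@specs
  if (nrow(sp) < 1L) stop("scheme must be nonempty")
  if (any(abs(sp$tau) > maxTiltRad)) {
    stop("tilt beyond configured maximum (", round(maxTiltRad * 180 / pi),
         " deg)")
  }
  nyq <- 1 / (2 * spacingNm)
  for (v in c("A", "B")) {
    na <- if (v == "A") cfg@naA else cfg@naB
    if (nyq < 2 * na / cfg@lambdaEmNm) {
      warning("frequency grid coarser than the 2NA/lambda cutoff of view ",
              v, " (transverse undersampling)", call. = FALSE)
    }
  }
  A <- angularSystemMatrix(scheme, cfg, grid)
  detView <- ifelse(sp$illumView == "A", "B", "A")
  if (mode == "factored") {
    new("TransferFunction", mode = "factored", a = A, detView = detView,
        otfA = .view_otf("A", cfg, dims, spacingNm),
        otfB = .view_otf("B", cfg, dims, spacingNm),
        kernels = list(), dims = dims, spacingNm = spacingNm, cfg = cfg)
  } else {
    raw <- list()
    for (v in unique(detView)) {
      raw[[v]] <- .coupled_kernels(v, cfg, dims, spacingNm, grid)
    }
    gain <- .optics_gain(cfg, grid)
    Y <- shBasisMatrix(grid@directions)
    kernels <- lapply(seq_len(nrow(sp)), function(i) {
      geo <- measurementGeometry(sp$illumView[i], sp$psi[i], sp$tau[i], cfg)
      ex <- gain * drop((grid@directions %*% geo$p)^2)
      # (n^2 x ndir) %*% (ndir x 15): fold excitation, quadrature, basis
      raw[[geo$detView]] %*% (Y * (grid@weights * ex))
    })
    new("TransferFunction", mode = "coupled", a = A, detView = detView,
        otfA = .view_otf("A", cfg, dims, spacingNm),
        otfB = .view_otf("B", cfg, dims, spacingNm),
        kernels = kernels, dims = dims, spacingNm = spacingNm, cfg = cfg)
  }
}

# Coupled-mode building block: for one detection view, the complex
# transverse OTF of the (energy-exact) dipole PSF for every quadrature
# direction, i.e. a (n1*n2) x ndir matrix; contracted against
# Y_lm * quadrature weights at use time.
.coupled_kernels <- function(view, cfg, dims, spacingNm, grid) {
  nt <- if (view == "A") dims[c(1, 2)] else dims[c(2, 3)]
  if (nt[1] != nt[2]) {
    stop("coupled mode requires equal transverse dimensions per view")
  }
  n <- nt[1]
  D <- grid@directions
  otfs <- matrix(0 + 0i, n * n, nrow(D))
  for (j in seq_len(nrow(D))) {
    psf <- .dipole_psf_on_grid(D[j, ], cfg, view, n, spacingNm)
    otfs[, j] <- as.vector(stats::fft(psf))
  }
  # strict transverse cutoff (clear floating dust beyond 2 NA / lambda)
  na <- if (view == "A") cfg@naA else cfg@naB
  f <- .fft_freq(n, spacingNm)
  rr <- sqrt(outer(f^2, f^2, "+"))
  otfs[as.vector(rr) >= 2 * na / cfg@lambdaEmNm, ] <- 0
  otfs
}

#' Evaluate a transfer function at explicit frequencies
#'
#' Returns the n_meas x 15 complex matrix H(nu) for each requested
#' frequency index (factored mode).  Mostly a test/audit surface; the
#' pipeline operates on whole grids.
#'
#' @param tf a \linkS4class{TransferFunction} (factored).
#' @param index integer length-3 voxel index (1-based) into the frequency
#'   grid.
#' @return n_meas x 15 numeric matrix.
#' @export
transferMatrixAt <- function(tf, index = c(1L, 1L, 1L)) {
  stopifnot(tf@mode == "factored")
  b <- ifelse(tf@detView == "A",
              tf@otfA[index[1], index[2], index[3]],
              tf@otfB[index[1], index[2], index[3]])
  tf@a * b
}

# axial-only Gaussian OTF of one detection view on the 3D frequency grid
# (used by the coupled mode, whose transverse response lives in the
# per-(l,m) kernels)
.axial_otf <- function(view, cfg, dims, spacingNm) {
  sdet <- if (view == "A") cfg@sigmaDetANm else cfg@sigmaDetBNm
  sAx <- sqrt(cfg@sigmaLsNm^2 + sdet^2)
  ax <- function(n) exp(-2 * pi^2 * sAx^2 * .fft_freq(n, spacingNm)^2)
  if (view == "A") {
    array(rep(ax(dims[3]), each = dims[1] * dims[2]), dims)
  } else {
    array(rep(ax(dims[1]), times = dims[2] * dims[3]), dims)
  }
}
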