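#' @import methods
NULL

#' Quadrature grid on the unit sphere
#'
#' An antipodally symmetric set of unit directions with quadrature weights
#' (steradians).  The default constructor builds a Gauss--Legendre x uniform
#' azimuth product grid that integrates polynomial integrands far beyond the
#' degree-8 products produced by degree-4 band-limited physics.
#'
#' @slot directions numeric matrix, n x 3, unit rows.
#' @slot weights numeric vector of length n, summing to 4*pi.
#' @export
setClass("SphereGrid",
  representation(directions = "matrix", weights = "numeric"),
  validity = function(object) {
    d <- object@directions
    if (ncol(d) != 3L) return("directions must be an n x 3 matrix")
    if (nrow(d) != length(object@weights)) return("weights length mismatch")
    nrm <- sqrt(rowSums(d^2))
    if (any(abs(nrm - 1) > 1e-9)) return("directions must be unit vectors")
    if (abs(sum(object@weights) - 4 * pi) > 1e-6) {
      return("weights must sum to 4*pi")
    }
    TRUE
  }
)

#' Optical configuration of the dual-view instrument
#'
#' Detection numerical apertures of the two orthogonal views, immersion
#' index, wavelengths and axial blur scales.  View A is the high-NA arm
#' (detection axis along z), view B the low-NA arm (detection axis along x).
#'
#' @slot naA,naB detection numerical apertures of views A and B.
#' @slot n refractive index of the immersion medium.
#' @slot lambdaExNm,lambdaEmNm excitation and emission wavelengths (nm).
#' @slot sigmaLsNm Gaussian sigma of the light-sheet axial profile (nm).
#' @slot sigmaDetANm,sigmaDetBNm Gaussian sigma of the detection axial
#'   response of each view (nm).
#' @slot detAxisA,detAxisB orthonormal detection axes (unit 3-vectors).
#' @export
setClass("OpticsConfig",
  representation(
    naA = "numeric", naB = "numeric", n = "numeric",
    lambdaExNm = "numeric", lambdaEmNm = "numeric",
    sigmaLsNm = "numeric", sigmaDetANm = "numeric", sigmaDetBNm = "numeric",
    detAxisA = "numeric", detAxisB = "numeric"
  ),
  validity = function(object) {
    # NA = n is allowed as the idealized full-hemisphere limit (C2 = 0)
    if (object@naA <= 0 || object@naA > object@n) {
      return("need 0 < naA <= n")
    }
    if (object@naB <= 0 || object@naB > object@n) {
      return("need 0 < naB <= n")
    }
    if (object@sigmaLsNm <= 0 || object@sigmaDetANm <= 0 ||
        object@sigmaDetBNm <= 0) {
      return("axial sigmas must be positive")
    }
    if (abs(sum(object@detAxisA * object@detAxisB)) > 1e-9) {
      return("detection axes must be orthogonal (dual-view geometry)")
    }
    TRUE
  }
)

#' An ordered set of polarized light-sheet measurements
#'
#' Each row of \code{specs} is one acquisition: the illuminating view
#' (detection happens through the other view), the transverse polarization
#' angle psi (rad, measured in the plane perpendicular to the tilted
#' propagation axis) and the light-sheet tilt tau (rad).
#'
#' @slot name character scheme name.
#' @slot specs data.frame with columns \code{illumView} ("A"/"B"),
#'   \code{psi} (rad), \code{tau} (rad).
#' @export
setClass("MeasurementScheme",
  representation(name = "character", specs = "data.frame"),
  validity = function(object) {
    s <- object@specs
    need <- c("illumView", "psi", "tau")
    if (!all(need %in% names(s))) {
      return("specs needs columns illumView, psi, tau")
    }
    if (nrow(s) < 1L) return("scheme must contain at least one measurement")
    if (!all(s$illumView %in% c("A", "B"))) {
      return("illumView must be 'A' or 'B'")
    }
    TRUE
  }
)

#' Voxel field of spherical-harmonic ODF coefficients
#'
#' The object f(r, s): a 3D grid of 15-coefficient real spherical-harmonic
#' expansions (even bands l = 0, 2, 4) with physical voxel spacing.
#'
#' @slot coefficients 4D numeric array (nx, ny, nz, 15).
#' @slot spacingNm voxel spacing in nm (isotropic).
#' @slot originNm world coordinate (nm) of voxel (1,1,1) center.
#' @export
setClass("ODFField",
  representation(coefficients = "array", spacingNm = "numeric",
                 originNm = "numeric"),
  validity = function(object) {
    d <- dim(object@coefficients)
    if (length(d) != 4L || d[4] != 15L) {
      return("coefficients must be an (nx, ny, nz, 15) array")
    }
    if (object@spacingNm <= 0) return("spacingNm must be positive")
    if (length(object@originNm) != 3L) return("originNm must be length 3")
    if (!all(is.finite(object@coefficients))) {
      return("coefficients must be finite")
    }
    TRUE
  }
)

#' Registered irradiance volumes for one acquisition scheme
#'
#' One 3D volume per measurement, on a common registered voxel grid, plus
#' noise metadata.  Values are in irradiance units; \code{countsPerUnit}
#' converts them to expected photon counts.
#'
#' @slot volumes list of 3D numeric arrays, one per measurement.
#' @slot scheme the \linkS4class{MeasurementScheme} that produced them.
#' @slot spacingNm voxel spacing (nm).
#' @slot countsPerUnit photon counts per irradiance unit (noise gain).
#' @slot noiseModel "none", "poisson" or "gaussian".
#' @slot seed integer seed used by the noise stage (NA if noiseless).
#' @export
setClass("IrradianceStack",
  representation(volumes = "list", scheme = "MeasurementScheme",
                 spacingNm = "numeric", countsPerUnit = "numeric",
                 noiseModel = "character", seed = "numeric"),
  validity = function(object) {
    if (length(object@volumes) != nrow(object@scheme@specs)) {
      return("number of volumes must match scheme length")
    }
    dims <- lapply(object@volumes, dim)
    if (length(unique(lapply(dims, as.integer))) != 1L) {
      return("all volumes must share one registered grid")
    }
    TRUE
  }
)

#' Null-space / angular-hole audit of a measurement scheme
#'
#' Holds the zero-frequency angular system matrix (rows = measurements,
#' columns = the 15 spherical-harmonic coefficients in the
#' detection-axis-aligned frame), its SVD, per-coefficient transmitted
#' amplitudes (column norms), the structural angular holes and the
#' condition number restricted to a band set.
#'
#' @slot A numeric matrix n_meas x 15.
#' @slot singularValues numeric vector.
#' @slot nullFunctions numeric matrix 15 x k, orthonormal columns spanning
#'   the (thresholded) null space.
#' @slot columnNorms numeric length-15 transmitted amplitude per coefficient.
#' @slot holes integer vector of flat SH indices with near-zero transmission.
#' @slot kappa condition number over \code{bandSet} columns.
#' @slot bandSet integer vector of bands used for \code{kappa}.
#' @slot svThreshold relative singular-value / column-norm threshold.
#' @export
setClass("AuditReport",
  representation(A = "matrix", singularValues = "numeric",
                 nullFunctions = "matrix", columnNorms = "numeric",
                 holes = "integer", kappa = "numeric", bandSet = "integer",
                 svThreshold = "numeric")
)

#' Per-voxel peak orientations of an ODF field
#'
#' @slot axes 4D array (nx, ny, nz, 3) of canonical unit axes (z >= 0
#'   hemisphere, ties broken toward +y then +x).
#' @slot peakValue 3D array of ODF maxima (peak-cylinder lengths).
#' @slot degenerate logical 3D array flagging near-isotropic voxels.
#' @slot spacingNm voxel spacing (nm).
#' @export
setClass("PeakField",
  representation(axes = "array", peakValue = "array", degenerate = "array",
                 spacingNm = "numeric")
)
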