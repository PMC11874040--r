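# Forward model: irradiance volumes from an ODF field under a measurement
# scheme, computed in the Fourier domain (per-frequency multiply-accumulate
# with the spatio-angular transfer function), plus shot/read noise.

# zero-pad a 3D array by `pad` voxels on each side
.pad3 <- function(a, pad) {
  if (pad == 0L) return(a)
  d <- dim(a)
  out <- array(0, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- a
  out
}

.crop3 <- function(a, pad, dims) {
  if (pad == 0L) return(a)
  a[pad + seq_len(dims[1]), pad + seq_len(dims[2]), pad + seq_len(dims[3])]
}

#' Forward-project an ODF field through a measurement scheme
#'
#' Implements the shift-invariant spatio-angular forward model: the
#' irradiance spectrum of each measurement is the sum over the 15 angular
#' channels of the transfer function times the object's channel spectra.
#' Linear in the field (doubling the fluorophores doubles the irradiance)
#' and spatially shift-invariant (circular boundaries; zero-padding
#' suppresses wraparound).
#'
#' @param field an \linkS4class{ODFField}.
#' @param scheme a \linkS4class{MeasurementScheme}.
#' @param cfg an \linkS4class{OpticsConfig}.
#' @param mode transfer-function fidelity, "factored" or "coupled".
#' @param pad zero-padding in voxels (default 16).
#' @param tf optional precomputed \linkS4class{TransferFunction} on the
#'   padded grid (must match dims + 2*pad and spacing).
#' @return a noiseless \linkS4class{IrradianceStack}.
#' @export
forwardProject <- function(field, scheme, cfg = opticsConfig(),
                           mode = c("factored", "coupled"), pad = 16L,
                           tf = NULL) {
  mode <- match.arg(mode)
  dims <- dim(field@coefficients)[1:3]
  pdims <- dims + 2L * pad
  if (is.null(tf)) {
    tf <- transferFunction(scheme, cfg, dims = pdims,
                           spacingNm = field@spacingNm, mode = mode)
  }
  if (!identical(as.integer(tf@dims), as.integer(pdims)) ||
      tf@spacingNm != field@spacingNm) {
    stop("transfer function grid does not match the (padded) field grid")
  }
  if (nrow(tf@a) != nrow(scheme@specs)) {
    stop("scheme does not match the transfer function")
  }
  nmeas <- nrow(scheme@specs)
  vols <- vector("list", nmeas)
  if (tf@mode == "factored") {
    cf <- matrix(field@coefficients, ncol = 15L)
    for (p in seq_len(nmeas)) {
      sp <- array(cf %*% tf@a[p, ], dims)      # angular contraction first
      G <- stats::fft(.pad3(sp, pad))
      B <- if (tf@detView[p] == "A") tf@otfA else tf@otfB
      g <- Re(stats::fft(G * B, inverse = TRUE)) / prod(pdims)
      vols[[p]] <- .crop3(g, pad, dims)
    }
  } else {
    # coupled: channel spectra once, then per-measurement contraction with
    # the per-(l,m) transverse kernels and the axial Gaussian
    Fk <- vector("list", 15L)
    for (k in 1:15) {
      Fk[[k]] <- stats::fft(.pad3(field@coefficients[, , , k], pad))
    }
    axA <- .axial_otf("A", cfg, pdims, field@spacingNm)
    axB <- .axial_otf("B", cfg, pdims, field@spacingNm)
    for (p in seq_len(nmeas)) {
      K <- tf@kernels[[p]]                     # (n1*n2) x 15 complex
      G <- array(0 + 0i, pdims)
      if (tf@detView[p] == "A") {
        # kernel lives on the (x, y) plane; broadcast along z
        for (k in 1:15) {
          G <- G + Fk[[k]] * array(rep(K[, k], times = pdims[3]), pdims)
        }
        G <- G * axA
      } else {
        # kernel lives on the (y, z) plane; broadcast along x
        for (k in 1:15) {
          G <- G + Fk[[k]] * array(rep(K[, k], each = pdims[1]), pdims)
        }
        G <- G * axB
      }
      g <- Re(stats::fft(G, inverse = TRUE)) / prod(pdims)
      vols[[p]] <- .crop3(g, pad, dims)
    }
  }
  new("IrradianceStack", volumes = vols, scheme = scheme,
      spacingNm = field@spacingNm, countsPerUnit = 1,
      noiseModel = "none", seed = NA_real_)
}

#' Apply a noise model to an irradiance stack
#'
#' Poisson: values become draws of Poisson(countsPerUnit * irradiance)
#' scaled back by 1/countsPerUnit, so the mean is preserved and the stack
#' keeps its physical units; \code{countsPerUnit} is recorded for
#' count-threshold analyses.  Gaussian: additive N(0, sd) read noise in
#' count units.
#'
#' @param stack an \linkS4class{IrradianceStack}.
#' @param model "poisson" or "gaussian".
#' @param countsPerUnit photon counts per irradiance unit (Poisson gain).
#' @param sdCounts Gaussian read-noise standard deviation (counts).
#' @param seed integer seed (reproducible draws).
#' @return a noisy \linkS4class{IrradianceStack}.
#' @export
addNoise <- function(stack, model = c("poisson", "gaussian"),
                     countsPerUnit = 1, sdCounts = 0, seed = 1L) {
  model <- match.arg(model)
  vols <- stack@volumes
  set.seed(seed)
  for (p in seq_along(vols)) {
    v <- vols[[p]]
    if (model == "poisson") {
      if (any(v < -1e-12)) {
        stop("Poisson noise requires a nonnegative stack")
      }
      v[v < 0] <- 0
      d <- dim(v)
      v <- array(stats::rpois(length(v), countsPerUnit * v) / countsPerUnit,
                 d)
    } else {
      v <- v + array(stats::rnorm(length(v), 0, sdCounts / countsPerUnit),
                     dim(v))
    }
    vols[[p]] <- v
  }
  new("IrradianceStack", volumes = vols, scheme = stack@scheme,
      spacingNm = stack@spacingNm, countsPerUnit = countsPerUnit,
      noiseModel = model, seed = as.numeric(seed))
}

setMethod("show", "IrradianceStack", function(object) {
  d <- dim(object@volumes[[1]])
  cat("IrradianceStack: ", length(object@volumes), " volumes of ",
      paste(d, collapse = "x"), " @ ", object@spacingNm, " nm; noise = ",
      object@noiseModel, "\n", sep = "")
})

#' @rdname forwardProject
#' @param stack an IrradianceStack.
#' @export
stackVolumes <- function(stack) stack@volumes
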