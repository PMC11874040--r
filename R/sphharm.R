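# Real spherical harmonics on the even bands l = 0, 2, 4 (15 functions).
#
# Convention (documented contract, see the vignette): real, orthonormal on
# the unit sphere, no Condon-Shortley phase.  Flat ordering k = 1..15:
#   (0,0), (2,-2), (2,-1), (2,0), (2,1), (2,2),
#   (4,-4), (4,-3), (4,-2), (4,-1), (4,0), (4,1), (4,2), (4,3), (4,4).
# Negative m pairs with sin(|m| phi), positive m with cos(m phi).

#' Flat index table for the even spherical-harmonic bands
#'
#' @return data.frame with columns \code{k} (1..15), \code{l}, \code{m}.
#' @export
shIndexTable <- function() {
  l <- c(0L, rep(2L, 5L), rep(4L, 9L))
  m <- c(0L, -2:2, -4:4)
  data.frame(k = seq_len(15L), l = l, m = m)
}

#' Flat index for a (l, m) pair
#'
#' @param l even band index in \{0, 2, 4\}.
#' @param m intraband index, -l <= m <= l.
#' @return integer flat index in 1..15.
#' @export
shFlatIndex <- function(l, m) {
  if (length(l) != 1L || length(m) != 1L || l %% 2 != 0 || l < 0 || l > 4 ||
      abs(m) > l) {
    stop("invalid spherical-harmonic index: need even l in {0,2,4}, |m| <= l")
  }
  tab <- shIndexTable()
  tab$k[tab$l == l & tab$m == m]
}

# cos(m*phi)*sin(theta)^m and sin(m*phi)*sin(theta)^m as polynomials in
# (x, y) via Re/Im of (x + i y)^m; avoids the phi singularity at the poles.
.sh_cs <- function(x, y, m) {
  switch(as.character(m),
    "1" = list(c = x, s = y),
    "2" = list(c = x^2 - y^2, s = 2 * x * y),
    "3" = list(c = x^3 - 3 * x * y^2, s = 3 * x^2 * y - y^3),
    "4" = list(c = x^4 - 6 * x^2 * y^2 + y^4,
               s = 4 * x^3 * y - 4 * x * y^3),
    stop("internal: unsupported m"))
}

#' Evaluate the 15 real even spherical harmonics at unit directions
#'
#' @param directions numeric n x 3 matrix (or length-3 vector) of unit
#'   directions.
#' @return n x 15 matrix of basis values, columns in flat order
#'   (see \code{\link{shIndexTable}}).
#' @export
shBasisMatrix <- function(directions) {
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1L)
  stopifnot(ncol(directions) == 3L)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("directions must be unit vectors")
  x <- directions[, 1L]; y <- directions[, 2L]; z <- directions[, 3L]
  Y <- matrix(0, nrow(directions), 15L)
  Y[, 1L] <- 1 / (2 * sqrt(pi))
  # l = 2.  K(2,m) = sqrt(5/(4 pi) * (2-m)!/(2+m)!), x sqrt(2) for m > 0.
  # P2^m / sin^m as polynomials in z (no Condon-Shortley):
  #   P2 = (3z^2 - 1)/2, P2^1/s = 3z, P2^2/s^2 = 3.
  n20 <- sqrt(5 / (16 * pi))
  n21 <- sqrt(15 / (4 * pi))
  n22 <- sqrt(15 / (16 * pi))
  cs1 <- .sh_cs(x, y, 1L); cs2 <- .sh_cs(x, y, 2L)
  Y[, 2L] <- n22 * cs2$s                                      # (2,-2)
  Y[, 3L] <- n21 * y * z                                      # (2,-1)
  Y[, 4L] <- n20 * (3 * z^2 - 1)                              # (2, 0)
  Y[, 5L] <- n21 * x * z                                      # (2, 1)
  Y[, 6L] <- n22 * cs2$c                                      # (2, 2)
  # l = 4.  P4 = (35z^4 - 30z^2 + 3)/8, and divided Legendre polynomials
  #   P4^1/s   = (35z^3 - 15z)/2,  P4^2/s^2 = (15/2)(7z^2 - 1),
  #   P4^3/s^3 = 105 z,            P4^4/s^4 = 105.
  cs3 <- .sh_cs(x, y, 3L); cs4 <- .sh_cs(x, y, 4L)
  k40 <- 3 / (16 * sqrt(pi))
  k41 <- sqrt(2 * 9 / (4 * pi) * factorial(3) / factorial(5))
  k42 <- sqrt(2 * 9 / (4 * pi) * factorial(2) / factorial(6))
  k43 <- sqrt(2 * 9 / (4 * pi) * factorial(1) / factorial(7))
  k44 <- sqrt(2 * 9 / (4 * pi) * factorial(0) / factorial(8))
  p41 <- (35 * z^3 - 15 * z) / 2
  p42 <- (15 / 2) * (7 * z^2 - 1)
  p43 <- 105 * z
  p44 <- 105
  Y[, 7L]  <- k44 * p44 * cs4$s                               # (4,-4)
  Y[, 8L]  <- k43 * p43 * cs3$s                               # (4,-3)
  Y[, 9L]  <- k42 * p42 * cs2$s                               # (4,-2)
  Y[, 10L] <- k41 * p41 * cs1$s                               # (4,-1)
  Y[, 11L] <- k40 * (35 * z^4 - 30 * z^2 + 3)                 # (4, 0)
  Y[, 12L] <- k41 * p41 * cs1$c                               # (4, 1)
  Y[, 13L] <- k42 * p42 * cs2$c                               # (4, 2)
  Y[, 14L] <- k43 * p43 * cs3$c                               # (4, 3)
  Y[, 15L] <- k44 * p44 * cs4$c                               # (4, 4)
  Y
}

#' Evaluate one real spherical harmonic
#'
#' @param l even band index in \{0, 2, 4\}; @param m intraband index.
#' @param direction unit 3-vector or n x 3 matrix of unit directions.
#' @return numeric value(s) of the orthonormal real harmonic Y_lm.
#' @export
realSH <- function(l, m, direction) {
  k <- shFlatIndex(l, m)
  drop(shBasisMatrix(direction)[, k])
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch.
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * (e$vectors[1L, idx])^2)
}

#' Build a quadrature grid on the sphere
#'
#' Product grid: Gauss--Legendre nodes in cos(theta) x uniform azimuth.
#' Exact for spherical polynomials up to degree min(2*nTheta - 1, nPhi - 1);
#' the default (degree-27 exactness, 392 points) comfortably integrates the
#' degree-8 products arising from degree-4 band-limited physics.  The grid
#' is antipodally symmetric by construction (even nPhi, symmetric nodes).
#'
#' @param nTheta number of Gauss--Legendre polar nodes (default 14).
#' @param nPhi number of uniform azimuthal nodes, even (default 28).
#' @return a \linkS4class{SphereGrid}.
#' @export
sphereGrid <- function(nTheta = 14L, nPhi = 28L) {
  if (nPhi %% 2L != 0L) stop("nPhi must be even (antipodal symmetry)")
  gl <- .gauss_legendre(nTheta)
  phi <- 2 * pi * (seq_len(nPhi) - 1L) / nPhi
  ct <- rep(gl$nodes, each = nPhi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = nTheta)
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$weights, each = nPhi) * (2 * pi / nPhi)
  new("SphereGrid", directions = dirs, weights = w)
}

#' @describeIn sphereGrid number of grid points
#' @param x a SphereGrid
#' @export
setMethod("length", "SphereGrid", function(x) nrow(x@directions))

setMethod("show", "SphereGrid", function(object) {
  cat("SphereGrid with", length(object), "directions; sum(w) =",
      format(sum(object@weights), digits = 10), "\n")
})

#' Grid directions and weights
#' @param grid a \linkS4class{SphereGrid}.
#' @return \code{gridDirections}: n x 3 matrix; \code{gridWeights}: length-n
#'   vector of steradian weights.
#' @export
gridDirections <- function(grid) grid@directions

#' @rdname gridDirections
#' @export
gridWeights <- function(grid) grid@weights

# Cached basis matrix per grid (keyed on dimensions; grids are deterministic
# given (nTheta, nPhi)).
.sh_cache <- new.env(parent = emptyenv())
.basis_for <- function(grid) {
  key <- paste0("Y_", length(grid), "_",
                format(sum(grid@directions[1, ]), digits = 16))
  if (is.null(.sh_cache[[key]])) {
    .sh_cache[[key]] <- shBasisMatrix(grid@directions)
  }
  .sh_cache[[key]]
}

#' Project sampled sphere values onto the even bands l <= 4
#'
#' Quadrature projection F_lm = sum_j w_j f(s_j) Y_lm(s_j); exact (hence
#' idempotent with \code{\link{shEvaluate}}) for band-limited inputs.
#'
#' @param values numeric vector (length = grid size) or n_fun x n_grid
#'   matrix of function samples at the grid directions.
#' @param grid a \linkS4class{SphereGrid}; must integrate degree-8 products
#'   exactly (checked).
#' @return length-15 coefficient vector (or n_fun x 15 matrix).
#' @export
shProject <- function(values, grid = sphereGrid()) {
  .check_quadrature(grid)
  Y <- .basis_for(grid)
  WY <- Y * grid@weights
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(grid))
    values %*% WY
  } else {
    stopifnot(length(values) == length(grid))
    drop(crossprod(WY, values))
  }
}

#' Evaluate a spherical-harmonic expansion on a grid
#'
#' @param coefficients length-15 vector (or n_fun x 15 matrix) of flat-order
#'   coefficients.
#' @param grid a \linkS4class{SphereGrid} or an n x 3 direction matrix.
#' @return numeric vector (or n_fun x n matrix) of function values.
#' @export
shEvaluate <- function(coefficients, grid = sphereGrid()) {
  Y <- if (is(grid, "SphereGrid")) .basis_for(grid) else shBasisMatrix(grid)
  if (is.matrix(coefficients)) {
    stopifnot(ncol(coefficients) == 15L)
    tcrossprod(coefficients, Y)
  } else {
    stopifnot(length(coefficients) == 15L)
    drop(Y %*% coefficients)
  }
}

# Quadrature degree check: the Gram matrix of the 15 basis functions must be
# the identity (degree-8 integrands).
.check_quadrature <- function(grid) {
  key <- paste0("ok_", length(grid))
  if (isTRUE(.sh_cache[[key]])) return(invisible(TRUE))
  Y <- .basis_for(grid)
  G <- crossprod(Y * grid@weights, Y)
  if (max(abs(G - diag(15))) > 1e-8) {
    stop("sphere grid too sparse for band limit L = 4 ",
         "(Gram matrix deviates from identity)")
  }
  .sh_cache[[key]] <- TRUE
  invisible(TRUE)
}

#' Generalized fractional anisotropy of an ODF
#'
#' GFA = std(psi) / rms(psi) over the sphere; for an orthonormal basis this
#' equals sqrt(1 - F00^2 / sum(F^2)).  0 for isotropic ODFs, -> 1 for
#' sharply peaked ones.
#'
#' @param coefficients length-15 coefficient vector.
#' @param method "coefficients" (closed form, default) or "samples"
#'   (sphere quadrature of std/rms; agrees to 1e-6 on band-limited input).
#' @param grid SphereGrid used by the sample formula.
#' @return scalar in [0, 1].
#' @export
gfa <- function(coefficients, method = c("coefficients", "samples"),
                grid = sphereGrid()) {
  method <- match.arg(method)
  total <- sum(coefficients^2)
  if (total == 0) stop("GFA undefined for an all-zero ODF")
  if (method == "coefficients") {
    return(sqrt(max(0, 1 - coefficients[1L]^2 / total)))
  }
  w <- grid@weights
  psi <- shEvaluate(coefficients, grid)
  mu <- sum(w * psi) / (4 * pi)
  ms <- sum(w * psi^2) / (4 * pi)
  sqrt(max(0, (ms - mu^2) / ms))
}

# Dense hemisphere of directions for peak search (Fibonacci lattice mapped
# to z >= 0; ODFs are even so a hemisphere suffices).
.peak_dirs <- function(n = 1800L) {
  key <- paste0("peakdirs_", n)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  i <- seq_len(n) - 0.5
  z <- i / n                      # z in (0, 1): upper hemisphere
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  st <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(st * cos(phi), st * sin(phi), z)
  .sh_cache[[key]] <- d
  d
}

#' Canonicalize an axis to the reporting hemisphere
#'
#' Dipole orientations are axes: s and -s are equivalent.  The canonical
#' representative has z > 0; on the z = 0 circle ties break toward y > 0,
#' then x > 0.
#'
#' @param axes length-3 vector or n x 3 matrix.
#' @return same shape, canonicalized.
#' @export
canonicalAxis <- function(axes) {
  v <- if (is.null(dim(axes))) matrix(axes, nrow = 1L) else axes
  tol <- 1e-12
  flip <- v[, 3L] < -tol |
    (abs(v[, 3L]) <= tol & (v[, 2L] < -tol |
                            (abs(v[, 2L]) <= tol & v[, 1L] < 0)))
  v[flip, ] <- -v[flip, , drop = FALSE]
  if (is.null(dim(axes))) drop(v) else v
}

# One batched quadratic-refinement step on the sphere: for each row of
# `dirs` (current argmax of the expansion in `coeffs`), fit a quadratic on
# tangent-plane offsets and move to its stationary point (clamped).
.refine_peaks <- function(coeffs, dirs, h = 0.06) {
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, nrow = 1L)
  n <- nrow(dirs)
  # tangent frames
  up <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
  swap <- abs(dirs[, 3L]) > 0.9
  up[swap, ] <- matrix(rep(c(1, 0, 0), each = sum(swap)), ncol = 3L)
  e1 <- up - dirs * rowSums(up * dirs)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(dirs[, 2L] * e1[, 3L] - dirs[, 3L] * e1[, 2L],
              dirs[, 3L] * e1[, 1L] - dirs[, 1L] * e1[, 3L],
              dirs[, 1L] * e1[, 2L] - dirs[, 2L] * e1[, 1L])
  offs <- rbind(c(0, 0), c(h, 0), c(-h, 0), c(0, h), c(0, -h),
                c(h, h), c(-h, -h))
  vals <- matrix(0, n, nrow(offs))
  for (j in seq_len(nrow(offs))) {
    d <- dirs + offs[j, 1L] * e1 + offs[j, 2L] * e2
    d <- d / sqrt(rowSums(d^2))
    vals[, j] <- rowSums(shBasisMatrix(d) * coeffs)
  }
  # quadratic model v = b0 + b1 u + b2 w + b3 u^2 + b4 w^2 + b5 u w
  X <- cbind(1, offs[, 1L], offs[, 2L], offs[, 1L]^2, offs[, 2L]^2,
             offs[, 1L] * offs[, 2L])
  B <- vals %*% t(solve(crossprod(X), t(X)))   # n x 6 coefficients
  det2 <- 4 * B[, 4L] * B[, 5L] - B[, 6L]^2
  u <- (-2 * B[, 5L] * B[, 2L] + B[, 6L] * B[, 3L]) / det2
  w <- (-2 * B[, 4L] * B[, 3L] + B[, 6L] * B[, 2L]) / det2
  # a local maximum needs a negative-definite Hessian: det > 0 with
  # negative diagonal curvatures
  bad <- !is.finite(u) | !is.finite(w) | sqrt(u^2 + w^2) > 2 * h |
    det2 <= 0 | B[, 4L] >= 0
  u[bad] <- 0; w[bad] <- 0
  d <- dirs + u * e1 + w * e2
  d / sqrt(rowSums(d^2))
}

#' Peak orientation of an ODF
#'
#' The axis along which most dipoles are oriented: argmax of the
#' spherical-harmonic expansion over a dense hemisphere lattice, refined by
#' a local quadratic fit on the sphere, canonicalized with
#' \code{\link{canonicalAxis}}.  Near-isotropic ODFs (relative contrast
#' below \code{degenerateTol}) are flagged degenerate instead of reporting
#' a noise-driven direction.
#'
#' @param coefficients length-15 coefficient vector.
#' @param nDirections size of the search lattice.
#' @param degenerateTol relative contrast (max - min)/|mean| below which
#'   the peak is flagged degenerate (default 1e-3).
#' @param maxBand highest band used in the search (4 or 2).  Peaks of
#'   reconstructed fields are best taken from the fully recoverable
#'   l <= 2 bands: the l = 4 estimates of a six-measurement inversion are
#'   subspace projections whose leakage can bias the argmax (see the
#'   vignette).
#' @return list with \code{axis} (unit 3-vector), \code{value}
#'   (ODF maximum) and \code{degenerate} (logical).
#' @export
peakOrientation <- function(coefficients, nDirections = 1800L,
                            degenerateTol = 1e-3, maxBand = 4L) {
  stopifnot(length(coefficients) == 15L)
  if (maxBand == 2L) coefficients[7:15] <- 0
  D <- .peak_dirs(nDirections)
  v <- shEvaluate(coefficients, D)
  mu <- mean(v)
  if (mu == 0 || (max(v) - min(v)) < degenerateTol * abs(mu)) {
    return(list(axis = c(0, 0, 1), value = max(v), degenerate = TRUE))
  }
  d0 <- D[which.max(v), , drop = FALSE]
  for (it in 1:2) d0 <- .refine_peaks(coefficients, d0)
  val <- shEvaluate(coefficients, d0)
  list(axis = drop(canonicalAxis(d0)), value = as.numeric(val),
       degenerate = FALSE)
}

#' Per-voxel peak orientations of an ODF field
#'
#' Vectorized \code{\link{peakOrientation}} over a (masked) coefficient
#' field.
#'
#' @param field an \linkS4class{ODFField}.
#' @param mask optional logical 3D array; voxels outside it get NA axes.
#' @param nDirections search lattice size.
#' @param refine logical; run the batched quadratic refinement step
#'   (default TRUE).
#' @param degenerateTol relative contrast threshold, as in
#'   \code{\link{peakOrientation}}.
#' @param maxBand highest band used in the search (4, or 2 for
#'   reconstructed fields; see \code{\link{peakOrientation}}).
#' @return a \linkS4class{PeakField}.
#' @export
peakField <- function(field, mask = NULL, nDirections = 1200L,
                      refine = TRUE, degenerateTol = 1e-3, maxBand = 4L) {
  dm <- dim(field@coefficients)[1:3]
  cf <- matrix(field@coefficients, ncol = 15L)
  if (maxBand == 2L) cf[, 7:15] <- 0
  if (is.null(mask)) mask <- array(TRUE, dm)
  idx <- which(as.vector(mask))
  axes <- array(NA_real_, c(dm, 3L))
  pv <- array(NA_real_, dm)
  dg <- array(NA, dm)
  if (length(idx)) {
    C <- cf[idx, , drop = FALSE]
    D <- .peak_dirs(nDirections)
    V <- tcrossprod(C, shBasisMatrix(D))      # nvox x ndir
    best <- max.col(V, ties.method = "first")
    vmax <- V[cbind(seq_along(idx), best)]
    vmin <- V[cbind(seq_along(idx), max.col(-V, ties.method = "first"))]
    mu <- rowMeans(V)
    deg <- mu == 0 | (vmax - vmin) < degenerateTol * abs(mu)
    d <- D[best, , drop = FALSE]
    if (refine && any(!deg)) {
      d[!deg, ] <- .refine_peaks(C[!deg, , drop = FALSE],
                                 d[!deg, , drop = FALSE])
      vmax[!deg] <- rowSums(shBasisMatrix(d[!deg, , drop = FALSE]) *
                            C[!deg, , drop = FALSE])
    }
    d <- canonicalAxis(d)
    ax <- matrix(NA_real_, prod(dm), 3L)
    ax[idx, ] <- d
    axes <- array(ax, c(dm, 3L))
    pv[idx] <- vmax
    dg[idx] <- deg
  }
  new("PeakField", axes = axes, peakValue = pv, degenerate = dg,
      spacingNm = field@spacingNm)
}
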