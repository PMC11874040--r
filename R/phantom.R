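# Synthetic ODF-field generators with exact ground truth: Watson-profile
# shells (GUV membranes), tubular fibers (actin/cellulose), and nanowire
# fixtures with fiber fields laid along the wires.

#' ODFField constructor and accessors
#'
#' @param coefficients (nx, ny, nz, 15) array of flat-order SH
#'   coefficients.
#' @param spacingNm voxel spacing in nm (default 130, the finest display
#'   spacing of the modeled instrument).
#' @param originNm world coordinate of voxel (1,1,1) center.
#' @return an \linkS4class{ODFField}.
#' @export
odfField <- function(coefficients, spacingNm = 130,
                     originNm = c(0, 0, 0)) {
  new("ODFField", coefficients = coefficients, spacingNm = spacingNm,
      originNm = originNm)
}

#' @rdname odfField
#' @param field an ODFField.
#' @export
coefficientArray <- function(field) field@coefficients

#' @rdname odfField
#' @export
voxelSpacingNm <- function(field) field@spacingNm

setMethod("show", "ODFField", function(object) {
  d <- dim(object@coefficients)
  cat("ODFField ", paste(d[1:3], collapse = "x"), " voxels @ ",
      object@spacingNm, " nm, 15 SH channels (l <= 4)\n", sep = "")
})

setMethod("dim", "ODFField", function(x) dim(x@coefficients)[1:3])

#' Watson-profile ODF coefficients
#'
#' SH projection (even bands, l <= 4) of the antipodally symmetric Watson
#' density exp(kappa (s . axis)^2), normalized to unit mass (integral 1
#' over the sphere).  kappa > 0 gives a polar (dumbbell) ODF about the
#' axis, kappa < 0 a girdle (pancake) ODF in the perpendicular plane,
#' kappa = 0 the isotropic ODF.
#'
#' @param axis unit 3-vector (or n x 3 matrix for a batch).
#' @param kappa concentration parameter.
#' @param grid quadrature \linkS4class{SphereGrid}.
#' @param aliasWarn warn when |kappa| is too large for a faithful L = 4
#'   representation (default threshold 12).
#' @return length-15 coefficient vector (or n x 15 matrix).
#' @export
watsonODF <- function(axis, kappa, grid = sphereGrid(), aliasWarn = TRUE) {
  if (aliasWarn && abs(kappa) > 12) {
    warning("|kappa| = ", kappa, " concentrates beyond the L = 4 band ",
            "limit; the projected ODF is a smoothed representation",
            call. = FALSE)
  }
  ax <- if (is.null(dim(axis))) matrix(axis, nrow = 1L) else axis
  ax <- ax / sqrt(rowSums(ax^2))
  ct2 <- (ax %*% t(grid@directions))^2         # n x ngrid
  vals <- exp(kappa * ct2)
  cf <- shProject(vals, grid)
  if (is.null(dim(axis))) cf <- matrix(cf, nrow = 1L)
  mass <- cf[, 1L] * sqrt(4 * pi)
  cf <- cf / mass
  if (is.null(dim(axis))) drop(cf) else cf
}

# voxel-center world coordinates (nm) for a grid
.voxel_coords <- function(dims, spacingNm, originNm = c(0, 0, 0)) {
  list(x = originNm[1] + (seq_len(dims[1]) - 1) * spacingNm,
       y = originNm[2] + (seq_len(dims[2]) - 1) * spacingNm,
       z = originNm[3] + (seq_len(dims[3]) - 1) * spacingNm)
}

#' Spherical-shell (GUV) phantom with known radial ground truth
#'
#' Voxels within a shell of the given radius and width receive a
#' unit-density Watson ODF oriented along the local radial direction
#' ("normal" mode: membrane-crossing dyes like FM1-43) or a girdle ODF in
#' the tangent plane ("tangential" mode: in-membrane dyes).  The default
#' ~3 um radius matches a ~6 um-diameter vesicle.
#'
#' @param dims integer grid size (default 54^3).
#' @param spacingNm voxel spacing (default 130 nm).
#' @param radiusNm shell radius (default 3000 nm).
#' @param widthNm shell thickness (default 260 nm).
#' @param kappa Watson concentration (default 5; negated internally for
#'   tangential mode).
#' @param mode "normal" or "tangential".
#' @param center world center (nm); defaults to the grid center.
#' @param grid quadrature grid.
#' @return list with \code{field} (\linkS4class{ODFField}),
#'   \code{truthAxes} ((nx,ny,nz,3) canonical radial axes, NA off-shell)
#'   and \code{shellMask} (logical array).
#' @export
guvPhantom <- function(dims = c(54L, 54L, 54L), spacingNm = 130,
                       radiusNm = 3000, widthNm = 260, kappa = 5,
                       mode = c("normal", "tangential"), center = NULL,
                       grid = sphereGrid()) {
  mode <- match.arg(mode)
  dims <- as.integer(dims)
  if (is.null(center)) center <- (dims - 1) / 2 * spacingNm
  co <- .voxel_coords(dims, spacingNm)
  if (radiusNm + widthNm / 2 > min((dims - 1) / 2 * spacingNm)) {
    stop("shell radius exceeds the grid")
  }
  dx <- co$x - center[1]; dy <- co$y - center[2]; dz <- co$z - center[3]
  R2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  R <- sqrt(R2)
  shell <- abs(R - radiusNm) <= widthNm / 2
  idx <- which(shell)
  nx <- dims[1]; ny <- dims[2]
  i <- (idx - 1) %% nx + 1
  j <- ((idx - 1) %/% nx) %% ny + 1
  k <- (idx - 1) %/% (nx * ny) + 1
  rad <- cbind(dx[i], dy[j], dz[k]) / R[idx]
  kap <- if (mode == "normal") kappa else -kappa
  cf15 <- watsonODF(rad, kap, grid)
  cf <- matrix(0, prod(dims), 15L)
  cf[idx, ] <- cf15
  truth <- matrix(NA_real_, prod(dims), 3L)
  truth[idx, ] <- canonicalAxis(rad)
  list(field = odfField(array(cf, c(dims, 15L)), spacingNm),
       truthAxes = array(truth, c(dims, 3L)),
       shellMask = array(shell, dims))
}

# squared point-to-segment distances and auxiliary geometry, vectorized
# over points for one segment (a, b are length-3 nm endpoints)
.seg_geometry <- function(P, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 <= 0) stop("degenerate wire segment")
  t <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] +
        (P[, 3] - a[3]) * ab[3]) / L2
  tc <- pmin(1, pmax(0, t))
  cx <- a[1] + tc * ab[1]; cy <- a[2] + tc * ab[2]; cz <- a[3] + tc * ab[3]
  d2 <- (P[, 1] - cx)^2 + (P[, 2] - cy)^2 + (P[, 3] - cz)^2
  list(d2 = d2, closest = cbind(cx, cy, cz), tangent = ab / sqrt(L2))
}

#' Tubular fiber phantom along a polyline
#'
#' Voxels within \code{radiusNm} of the polyline receive a unit-density
#' Watson ODF along the local segment tangent; overlapping tubes (e.g.
#' crossing or self-intersecting fibers) sum, producing multilobed ODFs.
#'
#' @param polyline m x 3 matrix of world coordinates (nm).
#' @param dims,spacingNm grid geometry.
#' @param radiusNm tube radius (default 200 nm).
#' @param kappa Watson concentration (default 5).
#' @param field optional existing \linkS4class{ODFField} to add onto.
#' @param grid quadrature grid.
#' @return list with \code{field}, \code{truthAxes} (local tangent at the
#'   nearest segment, NA outside all tubes) and \code{tubeMask}.
#' @export
fiberPhantom <- function(polyline, dims = c(48L, 48L, 48L),
                         spacingNm = 130, radiusNm = 200, kappa = 5,
                         field = NULL, grid = sphereGrid()) {
  dims <- as.integer(dims)
  co <- .voxel_coords(dims, spacingNm)
  P <- cbind(rep(co$x, times = dims[2] * dims[3]),
             rep(rep(co$y, each = dims[1]), times = dims[3]),
             rep(co$z, each = dims[1] * dims[2]))
  nseg <- nrow(polyline) - 1L
  if (nseg < 1L) stop("polyline needs at least two points")
  cf <- if (is.null(field)) matrix(0, prod(dims), 15L) else
    matrix(field@coefficients, ncol = 15L)
  bestD2 <- rep(Inf, prod(dims))
  bestTan <- matrix(NA_real_, prod(dims), 3L)
  inTube <- rep(FALSE, prod(dims))
  for (s in seq_len(nseg)) {
    sg <- .seg_geometry(P, polyline[s, ], polyline[s + 1L, ])
    hit <- sg$d2 <= radiusNm^2
    if (any(hit)) {
      cf[hit, ] <- cf[hit, , drop = FALSE] +
        watsonODF(matrix(sg$tangent, sum(hit), 3L, byrow = TRUE), kappa,
                  grid, aliasWarn = FALSE)
      inTube[hit] <- TRUE
    }
    upd <- sg$d2 < bestD2
    bestD2[upd] <- sg$d2[upd]
    bestTan[upd, ] <- matrix(sg$tangent, sum(upd), 3L, byrow = TRUE)
  }
  truth <- matrix(NA_real_, prod(dims), 3L)
  truth[inTube, ] <- canonicalAxis(bestTan[inTube, , drop = FALSE])
  list(field = odfField(array(cf, c(dims, 15L)), spacingNm),
       truthAxes = array(truth, c(dims, 3L)),
       tubeMask = array(inTube, dims))
}

#' Nanowire fixture with an actin-like fiber field
#'
#' Lays suspended ~200 nm wires in one of three arrangements --
#' \code{single} (one wire), \code{paired} (two parallel wires), or
#' \code{crossed} (two orthogonal wires) -- and builds an ODF field of
#' fibers running parallel to the wires within \code{regionNm} of each
#' wire.  A configurable fraction of in-region voxels is replaced by
#' randomly oriented Watson lobes (disordered actin); zero disorder gives
#' a downstream parallelism of exactly 1.
#'
#' @param arrangement "single", "paired" or "crossed".
#' @param dims,spacingNm grid geometry.
#' @param spacingWiresNm separation between paired wires (default 2000).
#' @param regionNm half-thickness of the fiber region around each wire
#'   (default 520 nm).
#' @param kappa Watson concentration of fiber ODFs.
#' @param disorderedFraction fraction of voxels with random axes.
#' @param diameterNm wire diameter recorded in the wire table (200 nm).
#' @param seed integer seed for the disordered component.
#' @param grid quadrature grid.
#' @return list with \code{wires} (data.frame x1..z2,label,diameter_nm),
#'   \code{field}, \code{truthAxes}, \code{tubeMask}.
#' @export
wireFixture <- function(arrangement = c("single", "paired", "crossed"),
                        dims = c(48L, 48L, 24L), spacingNm = 130,
                        spacingWiresNm = 2000, regionNm = 520, kappa = 5,
                        disorderedFraction = 0, diameterNm = 200,
                        seed = 1L, grid = sphereGrid()) {
  arrangement <- match.arg(arrangement)
  dims <- as.integer(dims)
  ext <- (dims - 1) * spacingNm
  zmid <- ext[3] / 2
  ymid <- ext[2] / 2
  xmid <- ext[1] / 2
  mkw <- function(a, b, label) {
    data.frame(x1 = a[1], y1 = a[2], z1 = a[3], x2 = b[1], y2 = b[2],
               z2 = b[3], label = label, diameter_nm = diameterNm)
  }
  wires <- switch(arrangement,
    single = mkw(c(0, ymid, zmid), c(ext[1], ymid, zmid), 1L),
    paired = rbind(
      mkw(c(0, ymid - spacingWiresNm / 2, zmid),
          c(ext[1], ymid - spacingWiresNm / 2, zmid), 1L),
      mkw(c(0, ymid + spacingWiresNm / 2, zmid),
          c(ext[1], ymid + spacingWiresNm / 2, zmid), 2L)),
    crossed = rbind(
      mkw(c(0, ymid, zmid), c(ext[1], ymid, zmid), 1L),
      mkw(c(xmid, 0, zmid), c(xmid, ext[2], zmid), 2L))
  )
  ph <- NULL
  for (i in seq_len(nrow(wires))) {
    pl <- rbind(as.numeric(wires[i, c("x1", "y1", "z1")]),
                as.numeric(wires[i, c("x2", "y2", "z2")]))
    ph <- fiberPhantom(pl, dims, spacingNm, radiusNm = regionNm,
                       kappa = kappa,
                       field = if (is.null(ph)) NULL else ph$field,
                       grid = grid)
  }
  # recompute nearest-tangent truth over both wires jointly
  allpl <- lapply(seq_len(nrow(wires)), function(i) {
    rbind(as.numeric(wires[i, c("x1", "y1", "z1")]),
          as.numeric(wires[i, c("x2", "y2", "z2")]))
  })
  if (length(allpl) > 1L) {
    co <- .voxel_coords(dims, spacingNm)
    P <- cbind(rep(co$x, times = dims[2] * dims[3]),
               rep(rep(co$y, each = dims[1]), times = dims[3]),
               rep(co$z, each = dims[1] * dims[2]))
    bestD2 <- rep(Inf, prod(dims)); bestTan <- matrix(NA_real_, prod(dims), 3L)
    for (pl in allpl) {
      sg <- .seg_geometry(P, pl[1, ], pl[2, ])
      upd <- sg$d2 < bestD2
      bestD2[upd] <- sg$d2[upd]
      bestTan[upd, ] <- matrix(sg$tangent, sum(upd), 3L, byrow = TRUE)
    }
    tm <- as.vector(ph$tubeMask)
    truth <- matrix(NA_real_, prod(dims), 3L)
    truth[tm, ] <- canonicalAxis(bestTan[tm, , drop = FALSE])
    ph$truthAxes <- array(truth, c(dims, 3L))
  }
  if (disorderedFraction > 0) {
    set.seed(seed)
    idx <- which(as.vector(ph$tubeMask))
    nd <- round(disorderedFraction * length(idx))
    if (nd > 0) {
      pick <- sample(idx, nd)
      ax <- matrix(stats::rnorm(3 * nd), nd, 3L)
      ax <- ax / sqrt(rowSums(ax^2))
      cf <- matrix(ph$field@coefficients, ncol = 15L)
      cf[pick, ] <- watsonODF(ax, kappa, grid)
      ph$field <- odfField(array(cf, c(dims, 15L)), spacingNm)
    }
  }
  list(wires = wires, field = ph$field, truthAxes = ph$truthAxes,
       tubeMask = ph$tubeMask)
}
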