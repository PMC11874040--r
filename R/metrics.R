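# Scalar and directional summaries of reconstructed ODF fields, and
# comparisons against wire annotations: density, GFA maps, count masks,
# parallelism / radiality with respect to nearest wires, moment-of-inertia
# aspect ratio, angular histograms, and group statistics.

#' Density map of an ODF field
#'
#' The integral of each voxel's ODF over the sphere -- the total dipole
#' count -- equals sqrt(4 pi) times the l = 0 coefficient.
#'
#' @param field an \linkS4class{ODFField}.
#' @return 3D numeric array.
#' @export
densityMap <- function(field) {
  field@coefficients[, , , 1L] * sqrt(4 * pi)
}

#' GFA map of an ODF field
#'
#' @param field an \linkS4class{ODFField}.
#' @param densityFloor voxels with |density| below this fraction of the
#'   maximum get NA (GFA is undefined at zero and noise-dominated at low
#'   density).
#' @return 3D numeric array.
#' @export
gfaMap <- function(field, densityFloor = 1e-6) {
  cf <- matrix(field@coefficients, ncol = 15L)
  tot <- rowSums(cf^2)
  g <- sqrt(pmax(0, 1 - cf[, 1L]^2 / ifelse(tot > 0, tot, NA_real_)))
  dens <- abs(cf[, 1L])
  g[dens <= densityFloor * max(dens)] <- NA_real_
  array(g, dim(field@coefficients)[1:3])
}

# distances from all voxel centers to each wire segment; returns the
# nearest-segment index, distance, closest point and tangent per voxel
.nearest_wire <- function(dims, spacingNm, wires, originNm = c(0, 0, 0)) {
  co <- .voxel_coords(dims, spacingNm, originNm)
  P <- cbind(rep(co$x, times = dims[2] * dims[3]),
             rep(rep(co$y, each = dims[1]), times = dims[3]),
             rep(co$z, each = dims[1] * dims[2]))
  n <- nrow(P)
  bestD2 <- rep(Inf, n); bestSeg <- rep(NA_integer_, n)
  closest <- matrix(NA_real_, n, 3L); tangent <- matrix(NA_real_, n, 3L)
  ord <- order(wires$label)     # ties to the lower wire label
  for (i in rev(ord)) {
    sg <- .seg_geometry(P, as.numeric(wires[i, c("x1", "y1", "z1")]),
                        as.numeric(wires[i, c("x2", "y2", "z2")]))
    upd <- sg$d2 <= bestD2      # later (lower-label) pass wins ties
    bestD2[upd] <- sg$d2[upd]
    bestSeg[upd] <- i
    closest[upd, ] <- sg$closest[upd, , drop = FALSE]
    tangent[upd, ] <- matrix(sg$tangent, sum(upd), 3L, byrow = TRUE)
  }
  list(distNm = sqrt(bestD2), segment = bestSeg, closest = closest,
       tangent = tangent, P = P)
}

#' Qualifying-voxel mask
#'
#' A voxel qualifies when its total photon count summed across all
#' measurements strictly exceeds \code{countThreshold} and, when wires are
#' given, its center lies closer than \code{maxDistNm} to the nearest
#' wire segment.
#'
#' @param stack an \linkS4class{IrradianceStack} (counts =
#'   countsPerUnit * irradiance), or a 3D array of total counts.
#' @param countThreshold strict lower bound on total counts (default
#'   5000).
#' @param wires optional wire data.frame (columns x1..z2, label,
#'   diameter_nm).
#' @param maxDistNm wire-distance bound (default 5000 nm).
#' @param spacingNm required when \code{stack} is a plain array.
#' @return logical 3D array.
#' @export
qualifyingMask <- function(stack, countThreshold = 5000, wires = NULL,
                           maxDistNm = 5000, spacingNm = NULL) {
  if (is(stack, "IrradianceStack")) {
    counts <- Reduce(`+`, stack@volumes) * stack@countsPerUnit
    spacingNm <- stack@spacingNm
  } else {
    counts <- stack
    if (is.null(spacingNm) && !is.null(wires)) {
      stop("spacingNm needed with a plain count array and wires")
    }
  }
  m <- counts > countThreshold
  if (!is.null(wires)) {
    nw <- .nearest_wire(dim(counts), spacingNm, wires)
    m <- m & array(nw$distNm < maxDistNm, dim(counts))
  }
  m
}

# shared front end for parallelism/radiality
.peak_wire_metric <- function(peaks, wires, mask, what, form, onWireEpsNm) {
  dims <- dim(peaks@peakValue)
  if (!any(mask, na.rm = TRUE)) stop("empty qualifying mask")
  nw <- .nearest_wire(dims, peaks@spacingNm, wires)
  ax <- matrix(peaks@axes, ncol = 3L)
  sel <- as.vector(mask) & !is.na(ax[, 1L]) &
    !as.vector(peaks@degenerate)
  nExcluded <- 0L
  if (what == "radiality") {
    off <- nw$P - nw$closest
    perp <- off - nw$tangent * rowSums(off * nw$tangent)
    pn <- sqrt(rowSums(perp^2))
    onAxis <- pn < onWireEpsNm
    nExcluded <- sum(sel & onAxis)
    sel <- sel & !onAxis
    refDir <- perp / ifelse(pn > 0, pn, 1)
  } else {
    refDir <- nw$tangent
  }
  v <- rep(NA_real_, prod(dims))
  dot <- abs(rowSums(ax[sel, , drop = FALSE] *
                     refDir[sel, , drop = FALSE]))
  dot <- pmin(dot, 1)
  v[sel] <- if (form == "cos2") dot^2 else dot
  vals <- v[sel]
  list(values = array(v, dims), mean = mean(vals), sd = stats::sd(vals),
       n = length(vals), nExcludedOnWire = nExcluded)
}

#' Parallelism of peak orientations to their nearest wires
#'
#' Per-voxel |p . t|: the absolute cosine between the canonical peak axis
#' and the tangent of the nearest wire segment (cos^2 available via
#' \code{form}).  Degenerate-peak voxels are excluded.
#'
#' @param peaks a \linkS4class{PeakField}.
#' @param wires wire data.frame (columns x1..z2, label, diameter_nm).
#' @param mask logical qualifying mask (see \code{\link{qualifyingMask}}).
#' @param form "abscos" (default) or "cos2".
#' @return list with \code{values} (3D array, NA outside), \code{mean},
#'   \code{sd}, \code{n}.
#' @export
parallelism <- function(peaks, wires, mask, form = c("abscos", "cos2")) {
  form <- match.arg(form)
  .peak_wire_metric(peaks, wires, mask, "parallelism", form, 0)
}

#' Radiality of peak orientations about their nearest wires
#'
#' Per-voxel |p . r| with r the unit component of (voxel - nearest wire
#' point) perpendicular to the wire tangent.  Voxels lying on the wire
#' axis (perpendicular offset below \code{onWireEpsNm}) are excluded and
#' counted.
#'
#' @inheritParams parallelism
#' @param onWireEpsNm on-axis exclusion radius (default 1 nm).
#' @return list as in \code{\link{parallelism}} plus
#'   \code{nExcludedOnWire}.
#' @export
radiality <- function(peaks, wires, mask, form = c("abscos", "cos2"),
                      onWireEpsNm = 1) {
  form <- match.arg(form)
  .peak_wire_metric(peaks, wires, mask, "radiality", form, onWireEpsNm)
}

#' Aspect ratio of a density distribution
#'
#' Ratio of the largest to smallest eigenvalue of the moment-of-inertia
#' tensor of the masked density (density as a proxy for mass):
#' I = sum_i m_i (|r_i - rbar|^2 Id - (r_i - rbar)(r_i - rbar)^T).
#'
#' @param density 3D numeric array.
#' @param mask logical 3D array (nonempty, positive total mass).
#' @param spacingNm voxel spacing (nm).
#' @return list with \code{ratio} (>= 1, possibly Inf), \code{eigenvalues}
#'   and \code{degenerate} flag.
#' @export
aspectRatio <- function(density, mask = NULL, spacingNm = 1) {
  dims <- dim(density)
  if (is.null(mask)) mask <- array(TRUE, dims)
  idx <- which(as.vector(mask) & as.vector(density) > 0)
  if (!length(idx)) stop("empty mask or no positive mass")
  m <- as.vector(density)[idx]
  nx <- dims[1]; ny <- dims[2]
  i <- (idx - 1) %% nx + 1
  j <- ((idx - 1) %/% nx) %% ny + 1
  k <- (idx - 1) %/% (nx * ny) + 1
  R <- cbind(i, j, k) * spacingNm
  ctr <- colSums(R * m) / sum(m)
  Rc <- sweep(R, 2L, ctr)
  r2 <- rowSums(Rc^2)
  Imat <- diag(3) * sum(m * r2) - crossprod(Rc * sqrt(m))
  ev <- sort(eigen(Imat, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[1L] <= 1e-12 * ev[3L]) {
    return(list(ratio = Inf, eigenvalues = ev, degenerate = TRUE))
  }
  list(ratio = ev[3L] / ev[1L], eigenvalues = ev, degenerate = FALSE)
}

#' Angular histogram of peak axes (equal-area hemisphere projection)
#'
#' Maps each canonical axis into the hemisphere about \code{viewAxis},
#' projects by the Lambert azimuthal equal-area map onto the unit disc
#' (center = along the viewing axis, edge = in-plane orientations), and
#' bins on concentric equal-area rings.  Total counts are conserved.
#'
#' @param peaks a \linkS4class{PeakField}.
#' @param mask logical qualifying mask.
#' @param viewAxis unit 3-vector (default z).
#' @param ringBins integer bins per ring, innermost first (default
#'   c(1, 9, 22, 32): 64 bins on 4 equal-area rings).
#' @return list with \code{counts} (list of per-ring integer vectors),
#'   \code{total}, \code{ringEdges} (disc radii), \code{viewAxis}.
#' @export
angularHistogram <- function(peaks, mask, viewAxis = c(0, 0, 1),
                             ringBins = c(1L, 9L, 22L, 32L)) {
  viewAxis <- viewAxis / sqrt(sum(viewAxis^2))
  ax <- matrix(peaks@axes, ncol = 3L)
  sel <- as.vector(mask) & !is.na(ax[, 1L]) & !as.vector(peaks@degenerate)
  if (!any(sel)) stop("empty qualifying mask")
  a <- ax[sel, , drop = FALSE]
  s <- sign(a %*% viewAxis); s[s == 0] <- 1
  a <- a * drop(s)                          # fold into the view hemisphere
  ct <- pmin(1, pmax(-1, drop(a %*% viewAxis)))
  r <- sqrt(2) * sin(acos(ct) / 2)          # in [0, 1] on the hemisphere
  up <- if (abs(viewAxis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - viewAxis * sum(up * viewAxis); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(viewAxis[2] * e1[3] - viewAxis[3] * e1[2],
          viewAxis[3] * e1[1] - viewAxis[1] * e1[3],
          viewAxis[1] * e1[2] - viewAxis[2] * e1[1])
  phi <- atan2(drop(a %*% e2), drop(a %*% e1)) %% (2 * pi)
  nr <- length(ringBins)
  edges <- sqrt(seq_len(nr) / nr)
  ring <- findInterval(r, edges, left.open = FALSE) + 1L
  ring[ring > nr] <- nr
  counts <- vector("list", nr)
  for (q in seq_len(nr)) {
    nb <- ringBins[q]
    b <- floor(phi[ring == q] / (2 * pi) * nb) + 1L
    b[b > nb] <- nb
    counts[[q]] <- tabulate(b, nbins = nb)
  }
  list(counts = counts, total = sum(unlist(counts)), ringEdges = edges,
       viewAxis = viewAxis)
}

#' Compare per-cell metric summaries across arrangements
#'
#' Pairwise two-sample t-tests (pooled variance by default) on the group
#' means of each metric, and Pearson correlations between aspect ratio and
#' each metric across all rows.
#'
#' @param rows data.frame with columns \code{id}, \code{arrangement},
#'   and one column per metric (e.g. parallelism, radiality), plus
#'   \code{aspectRatio}.
#' @param metrics character vector of metric column names.
#' @param welch use Welch's unequal-variance t-test instead of pooled.
#' @return list with \code{tTests} (data.frame: metric, group1, group2,
#'   t, df, p) and \code{correlations} (data.frame: metric, r, p).
#' @export
groupCompare <- function(rows, metrics = c("parallelism", "radiality"),
                         welch = FALSE) {
  grp <- unique(rows$arrangement)
  if (length(grp) < 2L) stop("need at least two groups")
  tt <- NULL
  for (m in metrics) {
    for (i in seq_along(grp)) {
      for (j in seq_along(grp)) {
        if (j <= i) next
        x <- rows[[m]][rows$arrangement == grp[i]]
        y <- rows[[m]][rows$arrangement == grp[j]]
        if (length(x) < 2L || length(y) < 2L) {
          stop("need >= 2 rows per group for t-tests")
        }
        ht <- stats::t.test(x, y, var.equal = !welch)
        tt <- rbind(tt, data.frame(metric = m, group1 = grp[i],
                                   group2 = grp[j],
                                   t = unname(ht$statistic),
                                   df = unname(ht$parameter),
                                   p = ht$p.value))
      }
    }
  }
  cc <- NULL
  for (m in metrics) {
    if (sum(stats::complete.cases(rows[[m]], rows$aspectRatio)) < 3L) {
      stop("need >= 3 rows for correlations")
    }
    ct <- stats::cor.test(rows$aspectRatio, rows[[m]])
    cc <- rbind(cc, data.frame(metric = m, r = unname(ct$estimate),
                               p = ct$p.value))
  }
  list(tTests = tt, correlations = cc)
}
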