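# Independent oracles used across the suite.

# Closed-form collection-cone constants (Fourkas-type integrals of the
# sin^2 dipole pattern over a cone of half-angle asin(NA/n)):
#   C1 = (3/4) [(1 - a) - (1 - a^3)/3],  C2 = (3/8) a (1 - a^2),
# with a = cos(asin(NA/n)).  Derived by hand from
#   integral over the cone of (3/8 pi)(1 - (mu.r)^2) dOmega
# with the azimuthal integral done analytically.
oracle_detection_constants <- function(na, n) {
  a <- cos(asin(na / n))
  c(C1 = (3 / 4) * ((1 - a) - (1 - a^3) / 3),
    C2 = (3 / 8) * a * (1 - a^2))
}

# brute-force point-to-segment distance
oracle_point_segment_dist <- function(p, a, b) {
  ts <- seq(0, 1, length.out = 2001)
  min(sqrt(colSums((outer(b - a, ts) + a - p)^2)))
}

# uniformly random rotation matrix (QR of Gaussian with det fix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rotate an SH expansion by rotating sphere samples and re-projecting
rotate_coeffs <- function(coeffs, R, grid = sphereGrid()) {
  vals <- shEvaluate(coeffs, gridDirections(grid) %*% R)
  shProject(vals, grid)
}

# angle (degrees) between two axes (antipodal-invariant)
axis_angle_deg <- function(u, v) {
  acos(pmin(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

quiet_tf <- function(...) suppressWarnings(transferFunction(...))
quiet_fp <- function(...) suppressWarnings(forwardProject(...))
quiet_rec <- function(...) suppressWarnings(reconstructField(...))
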