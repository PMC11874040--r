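---
title: "Spatio-angular modeling and reconstruction of dipole orientation distributions"
author: "odfscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-angular modeling and reconstruction of dipole orientation distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odfscope)
```

## The model

A fluorophore with aligned excitation and emission transition moments is
an unsigned axis on the sphere.  Within a diffraction-limited voxel, the
ensemble of such axes is summarized by an orientation distribution
function (ODF) $f(\hat s)$: a nonnegative, antipodally symmetric function
whose value along $\hat s$ counts the dipoles oriented along that axis.
A volume of such voxels is the object $f(\mathbf r, \hat s)$ that the
package simulates and estimates.

Antipodal symmetry confines $f$ to even spherical-harmonic bands.  The
imaging physics is quadratic in the dipole axis twice over — polarized
excitation selects dipoles with probability $\cos^2\theta$ to the
illumination polarization $\hat p$, and a finite-NA objective collects a
dipole's $\sin^2\phi$ emission pattern with efficiency
$C_1 + C_2\sin^2\phi_d$, where $\phi_d$ is the angle to the detection
axis — so each measurement weights the ODF by a product of two quadratics
in $\hat s$.  Such a weight is *exactly* band-limited to $\ell \le 4$:
only the $\ell = 0, 2, 4$ bands of the object, fifteen real coefficients
per voxel, can reach the data.  `odfscope` therefore represents every ODF
by 15 coefficients in a real, orthonormal basis without the
Condon–Shortley phase, in the flat order
$(0,0), (2,-2)\ldots(2,2), (4,-4)\ldots(4,4)$ (see `shIndexTable()`).
This ordering is this package's convention, stated here and in the file
sidecars; other implementations of the same physics may order or
normalize differently.

Spatially, the instrument is a dual-view light-sheet pair: two orthogonal
water-immersion objectives (NA 1.1 along $z$, NA 0.67 along $x$), each
able to illuminate with a polarized sheet while the other detects.  The
forward model is a shift-invariant spatio-angular convolution; in the
Fourier domain each measurement's irradiance spectrum is
$$G_{pv}(\boldsymbol\nu) \;=\; \sum_{\ell = 0,2,4}\sum_{m=-\ell}^{\ell}
H_{pv,\ell m}(\boldsymbol\nu)\, F_{\ell m}(\boldsymbol\nu),$$
with transverse frequencies beyond $2\,\mathrm{NA}_v/\lambda$ unobserved.
`transferFunction()` builds $H$ in two fidelities:

* **factored** (default): $H_{pv,\ell m}(\boldsymbol\nu) =
  B_v(\boldsymbol\nu)\, a_{pv,\ell m}$, where $a$ are the
  spherical-harmonic coefficients of the measurement's angular response
  and $B_v$ is a scalar OTF — the circular-aperture autocorrelation
  transversely (strict $2\mathrm{NA}/\lambda$ cutoff) times a Gaussian
  axially.  This is fast and exact at zero frequency.
* **coupled**: per-$(\ell, m)$ transverse kernels obtained by projecting
  the orientation dependence of the vectorial dipole PSF onto the
  harmonics, so the spatial footprint varies with the angular index — the
  point response genuinely does not factor into a spatial part times an
  angular part.  An axial dipole's donut is wider than a transverse
  dipole's Airy-like spot, and the coupled mode carries that difference
  into $H$.  Both modes agree at $\boldsymbol\nu = 0$ by construction
  (the coupled kernels are energy-normalized to the exact collection
  efficiency, removing pupil-discretization error from the DC term).

The dipole PSF itself (`dipolePsf()`) uses a scalar-pupil vectorial
approximation: the far field $(\theta, \phi)$ components of the dipole
radiation pattern map to the $(\rho, \phi)$ pupil components after
collimation (no longitudinal component survives), with the aplanatic
$1/\sqrt{\cos\theta}$ apodization.  This reproduces the qualitative
morphology that matters at this scale — a transverse dipole focuses to a
centrally peaked spot, an axial dipole to an annulus with a dark
center — and conserves energy to better than 1% against the closed-form
cone integrals.  Full Richards–Wolf integration with index mismatch is
out of scope.

## Angular holes and light-sheet tilting

The zero-frequency rows of $H$ form the angular system matrix
(`angularSystemMatrix()`), expressed in the frame aligned with the two
detection axes ($z$ = high-NA axis, $x$ = low-NA axis).  For the untilted
six-measurement scheme (three polarizations per view), every row is a
polynomial that view A keeps even in $z$ and view B keeps even in $x$ and
free of azimuthal order 3.  Four harmonics therefore cannot reach the
data at all: $(2,1)$, $(4,1)$, $(4,3)$ and $(4,-3)$.  These are the
intraband angular holes `auditScheme()` reports; the $(2,1)$ hole is the
single missing member of the lowest anisotropic band and corresponds to
the ambiguity between dipole axes that bisect the two optical axes.  In
this idealized model the hole's transmitted amplitude is zero to rounding
(the measured fold-reduction ratio evaluates to $\sim 10^{15}$); a real
instrument with imperfect polarization sees a large-but-finite deficit.

Tilting the light sheet rotates the propagation axis within the sheet
plane about the measurement's detection axis, making polarization
components along the illumination axis accessible and filling the
$(2,1)$ hole.  `searchSchemes()` minimizes the condition number of the
$\ell \in \{0, 2\}$ block over subsets of a documented candidate grid
(both views, $\psi \in \{0^\circ, 30^\circ, \ldots, 150^\circ\}$,
$\tau \in \{-20^\circ, 0^\circ, 20^\circ\}$ — 36 candidates, hence
$\binom{36}{6} \approx 1.9 \times 10^6$ six-measurement subsets, searched
exhaustively offline).  The frozen `six_with_tilt` preset is the best
such scheme: five tilt-diverse view-A illuminations plus one tilted
view-B illumination, $\kappa_{\ell \le 2} = 9.11$ under the default
optics, zero holes in $\ell \in \{0,2\}$.  Six is also the smallest
measurement count that can reach full rank on those six coefficients —
five rows cannot span six dimensions, and the package verifies that some
six-measurement tilted scheme does.

One stated invariant deserves a caveat: appending a measurement can only
grow every singular value of the band-restricted matrix (interlacing)
and never lowers its rank, but the condition-number *ratio* is not
monotone — duplicating the dominant row grows $\sigma_{\max}$ without
touching $\sigma_{\min}$.  The property tests assert the monotone
quantities.

## Reconstruction

`reconstructField()` implements the per-frequency ridge estimator: FFT
each registered volume, collect the $n_{\rm meas}$ Fourier coefficients
at each frequency into a vector, multiply by
$W(\boldsymbol\nu) = (H^{\mathsf H}H + \eta I)^{-1}H^{\mathsf H}$
(15 × $n_{\rm meas}$), and inverse-FFT the 15 coefficient channels.  In
factored mode $H$ has at most two distinct row scales (one per detection
view), so $H^{\mathsf H}H = b_A^2 G_A + b_B^2 G_B$ with fixed 15 × 15
Gram blocks; the per-frequency solves run in compiled code.  Frequencies
outside both views' supports return zero; where only one view transmits,
only its rows enter.  At $\eta = 0$ a rank-deficient system falls back to
a pseudo-inverse with a relative cutoff and a warning.

The default $\eta = 0.0032$ was chosen once by an L-curve sweep on the
shell phantom at the reference photon budget (5,000 expected counts per
shell voxel): over $\eta \in [10^{-4}, 1]$ the maximum-curvature corner
of the log residual-norm versus log solution-norm curve sits at
$10^{-2.5}$.  Responses are photometrically normalized (an isotropic
unit-density ODF yields signal 1.0 in the brightest untilted
measurement), which makes this value dimensionless and transferable.

A six-measurement inversion has rank at most 6 per frequency, so the
estimate is the projection of the truth onto a 6-dimensional subspace of
the 15 coefficients — a subspace that is *not* the $\ell \le 2$ block,
because the measurement rows carry $\ell = 4$ content.  Two consequences
are modeled deliberately:

* Noiseless round trips reproduce the *projected* truth essentially
  exactly inside the common frequency support (correlation > 0.99); raw
  $\ell = 4$ channels are not individually recoverable.
* Peak orientations of reconstructed fields are extracted from the
  $\ell \le 2$ bands only (`peakField(..., maxBand = 2)`, the pipeline
  default for reconstructions).  The $\ell = 4$ estimates are subspace
  projections whose leakage biases the full-15 argmax by up to
  $\sim 36^\circ$ for unfavorably oriented Watson lobes, while the
  $\ell \le 2$ peak stays within $3^\circ$ of the true axis for *all*
  orientations under the tilted scheme.  This mirrors the physical
  argument that the $\ell = 2$ band already determines every
  recoverable orientation and $\ell = 4$ only sharpens angular detail.
  Tellingly, the worst-case $\ell \le 2$ peak error of the *untilted*
  scheme computes to $41.5^\circ$ — orientations near the view-bisecting
  ambiguity — which is why a 42-degree cone is the natural acceptance
  radius for this family of instruments.

No positivity or smoothness constraint beyond the ridge penalty is
applied; an optional post-hoc clamp of negative densities exists and is
recorded in the output's metadata when used.

## Synthetic data: what the generators state, and what they omit

Phantoms use the Watson density $\exp(\kappa (\hat s \cdot \hat\mu)^2)$,
normalized to unit mass, as the canonical concentrated ODF: antipodally
symmetric, two parameters, polar lobes for $\kappa > 0$ and girdles for
$\kappa < 0$.  $|\kappa| \gtrsim 12$ triggers an aliasing warning because
an $L = 4$ expansion can no longer follow the lobe.  Defaults state the
modeled world:

* **Shell ("GUV") phantom** — radius 3 µm (a ~6 µm vesicle), shell
  width 260 nm, membrane-normal Watson lobes with $\kappa = 5$
  (a moderately ordered membrane dye), 130 nm voxels.  Ground-truth
  radial axes are returned exactly.
* **Fiber phantom** — 200 nm-radius tubes along a polyline, lobes along
  the local tangent; overlapping tubes add, giving multilobed ODFs at
  crossings.
* **Wire fixtures** — single / paired / crossed ~200 nm wires with
  fiber fields laid parallel within 520 nm of each wire and an optional
  seeded disordered fraction (default 0, so downstream parallelism is
  exactly 1).
* **Noise** — Poisson shot noise at a stated gain; the reference budget
  is 5,000 expected total counts per shell voxel, matching the count
  threshold used for qualifying voxels.

The generators emulate geometry, band-limited angular structure, blur and
shot noise.  They do not emulate: deskew/registration residuals between
views, calibration drift or per-measurement gain errors, background
fluorescence, bleaching, saturation, fluorophore lifetime or rotational
diffusion during exposure, or sample motion between the six serial
measurements.  A green end-to-end test therefore establishes the
correctness of the model, audit and inversion chain — not robustness to
those real-world effects.

## Numerical choices

* Sphere quadrature: Gauss–Legendre × uniform-azimuth product grid, 392
  points, exact for spherical polynomials to degree 27 (degree-8 products
  arise from degree-4 physics; the margin is cheap).  The Gram matrix of
  the 15 basis functions is checked against identity at $10^{-8}$ before
  any projection.
* Peak search: Fibonacci hemisphere lattice (evenness of the bands makes
  a hemisphere sufficient) followed by a batched quadratic refinement on
  local tangent-plane offsets; stationary points are accepted only with a
  negative-definite Hessian.  Refined peaks of band-limited lobes are
  exact to $\sim 10^{-4}$ degrees.  Axes are canonicalized to $z \ge 0$,
  ties toward $+y$ then $+x$.  Near-isotropic voxels (relative contrast
  below $10^{-3}$) are flagged degenerate rather than assigned an
  arbitrary axis.
* Boundaries: the Fourier model is circular; the simulator and
  reconstructor zero-pad by 16 voxels by default to suppress wraparound.
  Exact per-frequency identities (DC totals, round-trip projections) hold
  in the unpadded circular setting, which the tests use.
* Angular holes: a coefficient counts as a hole when its column norm
  falls below $10^{-3}$ of the largest column norm; the same relative
  threshold separates structural nulls from weak transmission in the
  SVD.  With six measurements and 15 unknowns the SVD null space always
  has dimension ≥ 9; the audit reports both that null space and the
  column-norm holes, because only the latter are the per-harmonic
  "missing members" of a band.
* Tilt geometry: tilt rotates the propagation axis within the sheet
  plane about the measurement's detection axis; the polarization angle is
  measured in the plane perpendicular to the tilted propagation axis,
  with $\psi = 0$ along the detection axis.  Tilts beyond 35° are
  rejected (outside the modeled regime of a sheet still illuminating the
  same plane).
* 130 nm voxels transversely undersample the NA-1.1 view (Nyquist
  $1/(260\,\mathrm{nm})$ vs cutoff $2 \times 1.1 / 500\,\mathrm{nm}$);
  `transferFunction()` warns.  This matches how such instruments are
  actually sampled; the warning is informational and the demo pipelines
  suppress it knowingly.

## Metrics

Density is $\sqrt{4\pi} F_{00}$ (the spherical integral of the ODF);
GFA is $\mathrm{std}/\mathrm{rms}$ over the sphere, equal to
$\sqrt{1 - F_{00}^2 / \sum F_{\ell m}^2}$ in an orthonormal basis — both
forms are implemented and agree to $10^{-6}$.  Parallelism and radiality
are first-order axis cosines: $|\hat p \cdot \hat t|$ against the nearest
wire's tangent and $|\hat p \cdot \hat r|$ against the perpendicular
offset direction; the squared-cosine variants are available behind a
flag, but the first-order forms are the package's convention (their
ranges are compatible with the published group means for cells on
nanowires).  Nearest wires are assigned by point-to-segment distance with
ties to the lower label; voxels on a wire axis are excluded from
radiality with a reported count.  Qualifying voxels require total counts
*strictly* above 5,000 and, when wires are given, a wire distance below
5 µm.  The aspect ratio is the extreme-eigenvalue ratio of the
moment-of-inertia tensor with reconstructed density as mass.  Angular
histograms bin canonical axes on a Lambert equal-area disc (4 equal-area
rings with 1/9/22/32 azimuthal bins); the tested contract is count
conservation and the center/edge semantics.  Group comparisons use
pooled-variance two-sample t-tests (Welch behind a flag) and Pearson
correlations.

## Worked example

```{r demo, eval = FALSE}
library(odfscope)
res <- runDemo()          # 48^3 shell, six_with_tilt, Poisson noise
res$fractionInCone        # percent of qualifying peaks within 42 degrees
show(res$audit)
```

On the untilted scheme (`runDemo(schemeName = "six_no_tilt")`) the audit
reports the four angular holes and the reconstruction loses the
orientations near the view bisectors; with tilting the holes close and
essentially all qualifying peaks fall inside the 42-degree cone.

## Known limitations

* The coupled transfer-function mode materializes per-frequency matrices
  and is restricted to small grids; factored mode is the pipeline
  default.
* Real-data preprocessing (deskew, dual-view registration, gain
  calibration) is explicitly out of scope; the simulator emits
  already-registered volumes.
* Orientation recovery is characterized for single-lobe (Watson) voxels;
  multilobed voxels are represented and simulated faithfully, but peak
  extraction reports only the global argmax per voxel.
* The instrument's exact tilt/polarization sets are not public in the
  modeled source; the frozen tilted preset is the package's own
  condition-number optimum over the documented grid.
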