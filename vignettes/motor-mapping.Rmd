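---
title: "Motor map construction and comparison: models, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor map construction and comparison: models, parameters and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motormap)
```

`motormap` reconstructs continuous response surfaces from navigated TMS
stimulation records and derives the quantitative descriptors of cortical
muscle representations. This vignette is the package's own account of the
model it implements: the geometry, the two surface constructions, the
descriptors, the Earth Mover's Distance comparison, the synthetic-data
generator, and the numerical decisions behind each.

## Geometry: one sphere, one patch

Stimulation coordinates (coil position on the scalp, or the electric-field
maximum when the navigation system provides one — the EF maximum is
preferred automatically) are scattered in 3D. All analysis happens on the
sphere fitted to them by least squares:

1. an algebraic (linearized) fit solves
   $|p|^2 = 2\,p\cdot c + (R^2 - |c|^2)$ for an initial center and radius;
   a rank-deficient system means coplanar or collinear points, which is an
   error;
2. the geometric objective $\sum_i (\lVert p_i - c\rVert - R)^2$ is then
   minimized by Levenberg–Marquardt.

Points are projected radially onto the sphere. The *patch of interest*
(POI) is the convex hull of the projected points dilated by a margin
(influence radius + two grid spacings — the smallest patch on which a map
can decay to zero), and carries an orthonormal frame whose $+z$ axis points
from the sphere center through the patch centroid. Angular coordinates
$(\alpha, \beta)$ of a surface point are defined by its direction being
proportional to $(\tan\alpha, \tan\beta, 1)$ in that frame.

**Unwrap/wrap.** Transfer between the patch and the plane uses the
azimuthal-equidistant projection: a point at central angle $\gamma$ and
azimuth $\theta$ maps to $(k\cos\theta, k\sin\theta)$ with $k = R\gamma$,
so the planar distance from the origin *is* the geodesic distance from the
patch center, and areas distort only tangentially, by
$\operatorname{sinc}(s/R)$ at planar radius $s$. Two conventions deserve a
note:

- The azimuth is computed as $\theta = \operatorname{atan2}(\tan\beta,
  \tan\alpha)$. Together with the inverse $\alpha =
  \arctan(x_{3D}/z_{3D})$, $\beta = \arctan(y_{3D}/z_{3D})$ this makes
  wrap ∘ unwrap the exact identity, which is the governing contract — the
  round trip over randomized patch points is exact to $10^{-9}$ rad. A
  transposed azimuth (swapping the roles of $\alpha$ and $\beta$) would
  swap the two angles on every round trip.
- Sign and zero-division branches are subsumed by the two-argument
  arctangent; the patch center itself maps to the origin.
- The in-plane orientation of the frame's $x$ axis (projection of world
  $+x$, falling back to $+y$) is an arbitrary choice; every reported
  statistic is rotation-invariant, only PNG orientation depends on it.

The POI hull and its dilation are computed in the unwrapped plane. For a
single point the dilated boundary is an exact geodesic disc; for extended
patches the planar hull deviates from the geodesic hull only at second
order in patch size over $R$ (below one percent for the ≤ 40 mm patches
this tool targets).

**Grid.** A regular square lattice of fixed 1 mm spacing (not a user
parameter) is laid over the unwrapped POI; cells whose centers fall inside
the boundary are kept, wrapped back, and carry their spherical area
$s_i = (\text{spacing})^2 \operatorname{sinc}(s/R)$. Summed cell areas
reproduce spherical-cap closed forms within 1 % for caps of radius
≥ 10 mm.

## From stimuli to surfaces

**Merging.** Repeated stimulations of the same target are pooled by
single-linkage clustering at a geodesic *merge radius*, each cluster
becoming one merged point with the spherical mean location and the mean
(or maximal) response; clusters with fewer repetitions than
`min_repetitions` are dropped. The default merge radius is **2 mm** — the
navigation accuracy, the same quantity as the kernel parameter $b$. This
default matters: with a 5 mm stimulation node grid and a navigation error
bounded by 2 mm, single-linkage chaining at 3 mm can fuse neighboring
nodes into one blob (adjacent-node stimuli can land within 1 mm of each
other), destroying the map's spatial structure. At 2 mm each node's
repeat cluster survives intact.

**Kernel (abrupt) construction.** The surface is the pointwise maximum of
exponential kernels, $h(A) = \max_i h_i\, a^{r^2(A, A_i)/b^2}$, with $r$
geodesic. $a$ is the fraction of one kernel's volume beyond radius $b$
(so $b$ is the navigation accuracy in a $1-a$ share of stimuli); defaults
$a = 0.05$, $b = 2$ mm. The profile is a Gaussian in disguise,
$\exp(-r^2 \ln(1/a)/b^2)$, and the outside-$b$ volume fraction integrates
to exactly $a$ — the package's acceptance script verifies the 5 % figure
numerically.

**Smooth construction (default).** TMS cannot stimulate one point without
co-stimulating its neighborhood, so a smoothly varying surface through all
merged points is the physiological default. The exact interpolation
contract is: the surface passes through every merged point (within 0.5 %
of the maximum response), is continuous, nonnegative, and reaches zero
level at the *influence radius* (default 5 mm) from the nearest merged
point. Internals are the package's own choice: the discrete thin-plate
bending energy $\lVert z_{xx}\rVert^2 + 2\lVert z_{xy}\rVert^2 +
\lVert z_{yy}\rVert^2$ is minimized over the unwrapped lattice with
penalty-weighted bilinear interpolation rows at the merged points
(weight $10^8$ relative to the $O(1)$ bending rows, leaving node residuals
orders of magnitude below the tolerance) and every lattice node at or
beyond the influence radius held at zero; the sparse normal equations are
solved by Cholesky factorization. Negative undershoot is clipped to zero
(responses are amplitudes). Holding the whole outer region at zero acts
like a clamped plate edge: relative to an unclamped thin-plate RBF
interpolant the surface sags by 1–2.5 % within one node spacing of the
data hull's edge, while cells two node spacings inside stay at the data
plateau (tests pin both behaviors). Duplicate planar locations with
conflicting heights are rejected as inconsistent.

**Thresholding.** The minimum signal level surface (default 50 μV,
concentric with the fitted sphere) removes cells below threshold; the
remainder — the `th_map` — is what all further statistics use. Raising
the threshold never increases the area.

## Descriptors

- **Area**: $\sum s_i$ over suprathreshold cells (projection of the
  `th_map` onto the POI).
- **Volume**: $\sum h_i s_i$, measured from the zero level (the sphere
  surface), reading "volume under the surface" literally; an
  above-threshold alternative would subtract the threshold plane and can
  be obtained as `map_volume(th) - threshold * map_area(th)`.
- **CoG**: the printed Cartesian weighted means — $\sum h_i x_i / \sum
  h_i$ over merged points (raw) or $\sum h_i s_i x_i / \sum h_i s_i$ over
  cells (map) — computed componentwise and then projected radially back to
  the sphere, since the raw mean lies strictly inside it. Both the
  projected point and the unprojected mean are retained.
- **Hotspots**: merged point of maximal response and cell of maximal
  height; ties break by distance to the corresponding CoG, then by the
  first identifier.
- **Overlap**: of two thresholded maps on one shared geometry — the
  intersection of the suprathreshold cell sets with the cellwise *minimum*
  height. The minimum is the intersection-consistent choice (overlap of a
  map with itself is the map; every overlap statistic is bounded by either
  input), and gives the overlap the same set of properties as any map.

Maps that are to be compared must be built on one shared geometry
(`map_geometry()` fitted to the union of all sessions' points); comparing
maps from independent fits is refused rather than silently resampled.

## Relative EMD between excitability profiles

Two maps with equal areas and volumes can still differ in where their
response mass sits. Both maps are normalized by volume to unit mass
(masses $h_i s_i / V$ per cell), and the Earth Mover's Distance is the
minimal work to transform one distribution into the other with geodesic
ground distances. The result is reported relative to the work needed to
move a point mass between the two ends of the subject's *active area* —
all stimulated points where any channel in any session exceeded the
threshold; $d_{\max}$ is their maximal pairwise geodesic distance — so
identical profiles give 0 % and two extreme single-peak maps give 100 %.
The raw distance is a true metric on normalized maps over a fixed grid,
and the relative value is invariant to scaling either map's heights.

The transportation problem is solved exactly by a least-cost-initialized
transportation simplex (MODI pivots on the basis tree, degenerate pivots
allowed with deterministic tie-breaking); tests verify it against a
brute-force LP on small instances to $10^{-6}$. Maps with more than 300
suprathreshold cells are first aggregated into at most 300 mass-weighted
clusters by a deterministic spherical Lloyd iteration; on synthetic bumps
halving the cap moves the relative EMD by well under half a percentage
point. A `points` mode computes the same comparison between the raw merged
response distributions instead of the interpolated cells; the cell mode is
the default.

## Synthetic sessions and what they do (not) show

The generator emulates the standard protocol: a virtual grid of
stimulation nodes at 5 mm spacing covering a ~21 mm patch on an 85 mm
head sphere (57 nodes), each node visited 5 times in a seeded
pseudo-random order (≈ 285 stimuli per session), navigation error
tangential, truncated-Gaussian, bounded by 2 mm. Responses are sums of
geodesic Gaussian bumps $A e^{-r^2/2\sigma^2}$ per channel, scaled by
multiplicative lognormal noise (sdlog 0.2, mean 1 — the standard
MEP-amplitude variability model), plus an additive baseline (sd 2 μV),
floored at zero. Ground truth (area, volume, CoG, hotspot of the
thresholded true field) comes from quadrature on a 0.25 mm lattice, four
times finer than the analysis grid; for a single bump the suprathreshold
radius has the closed form $\sigma\sqrt{2\ln(A/T)}$.

Passing recovery tests on these sessions demonstrates the numerical
pipeline — interpolation, thresholding, integration, transport — under
realistic sampling and noise. It does not validate the biology: real maps
are not sums of isotropic Gaussians, real noise is not independent across
stimuli (excitability drifts), and the scalp is not a sphere. The
generator also writes fixtures in both input formats, which is how the
readers are tested without any deposited data.

## Numerical choices and degenerate inputs

- Geodesics use the chord/`asin` form, exact at zero separation (the
  `acos` form has a $10^{-6}$ mm noise floor that would break
  identity-of-indiscernibles tests).
- Grid spacing, quadrature resolution and the EMD cluster cap are internal
  constants (1 mm, 0.25 mm, 300); tests may pass finer spacings through
  internal arguments.
- Problem sizes in the test suite (patches of 16–21 mm radius, 20-seed
  recovery loops, ≤ 350-bin exact transport solves) keep the full suite
  around one to two minutes while exercising every contract at realistic
  scale.
- Empty results are legal where the science allows them (an empty
  thresholded map has area 0) and errors where it does not (CoG, hotspot
  and EMD of an empty map; active areas with fewer than two qualifying
  points; projection of the sphere center; patches reaching a hemisphere).
- All randomness is confined to the synthetic generator and derived from
  its integer seed; construction, statistics, rendering and serialization
  are deterministic, and repeated pipeline runs produce byte-identical
  workbooks, JSON containers and PNGs (file timestamps inside the XLSX
  archive are pinned).

## Known limitations

- One patch per map: bi-hemispheric representations need two separate
  analyses; ellipsoid or cortical-surface geometry is out of scope.
- The smooth construction's clamped zero region slightly depresses the
  surface near sparsely sampled hull edges (see above); kernel maps are
  unaffected.
- EF-based response weighting is not implemented (only the EF maximum as
  an alternative stimulation coordinate); no group-level statistics.
- The `.nbe` dialect is an open stand-in for proprietary navigation
  exports; converting vendor files is a user step.
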