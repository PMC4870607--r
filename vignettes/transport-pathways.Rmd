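---
title: "Parameterizing transport pathways in porous scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing transport pathways in porous scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreperc)
```

## The problem

Porous tissue-engineering scaffolds (freeze-dried collagen being the
canonical example) support tissue ingrowth only if cells and nutrients can
travel through the pore space. "Interconnectivity" is the umbrella term for
this property, but a single global number hides most of what matters: how
accessibility depends on the size of the traveling object, on the direction
of travel, and on the length scale over which it is measured. `poreperc`
implements a ladder of four analyses of increasing discrimination on a 3D
binary pore/wall image:

* **Flood fill** — the largest connected pore component as a fraction of
  total pore volume. Relevant for small-molecule diffusion; for typical
  scaffolds it is near 100% and says nothing about cell-scale transport.
* **3D sphere accessibility ("shrink-wrap")** — the pore volume a virtual
  sphere of diameter $d$ can reach when entering from all surfaces. A
  pathway counts only if it is wider than $d$ at *every* point.
* **Directional accessibility** — the same with all faces but one sealed,
  exposing anisotropy.
* **Percolation diameter** — the intercept $d_c$ of $d$ against
  $L^{-1/0.88}$, where $L(d)$ is the maximum accessible distance of the
  sphere's center from the entry face. $d_c$ is the largest sphere that can
  travel infinitely far through the structure in that direction, and is the
  package's headline statistic: unlike percent interconnectivity it is, by
  construction, an extrapolation to infinite sample size.

Percent interconnectivity at diameter $d$ follows the accessible-volume
ratio

$$\mathrm{interconnectivity}(\%) = \frac{V - V_s}{V - V_m} \times 100,$$

with $V$ the ROI volume, $V_s$ the volume inaccessible to the sphere, and
$V_m$ the solid volume — i.e. accessible pore volume over total pore
volume.

## The accessibility model

All geometry reduces to one constructive definition. Distances are
center-to-center Euclidean distances in micrometers on an isotropic voxel
grid.

1. A sphere of diameter $d$ **fits** at a pore voxel iff no wall voxel
   center lies strictly within $d/2$ — equivalently the Euclidean distance
   transform (EDT) of the wall phase is $\ge d/2$ there. The EDT is exact
   (Felzenszwalb–Huttenlocher separable algorithm in compiled code), so
   fitting is a sharp threshold, not an approximation.
2. Open faces are padded with $\lceil d/2 \rceil + 1$ layers of free space
   (the sphere approaches from outside and may touch surface pores); sealed
   faces are padded with wall. Sealed plates span the full padded extent:
   an "artificially enclosed" face behaves as an infinite plate, so
   approach paths near a sealed edge are blocked by it.
3. The **center mask** is the set of fitting positions 6-connected (by
   default) to an open face's pad region. 6-connectivity is chosen because
   a sphere sliding between two diagonally adjacent positions could clip
   walls; 26-connectivity is available by flag and is the main place a
   different shrink-wrap implementation could diverge from this one.
4. The **access mask** (the Eq.-style accessible volume $V - V_s$) is the
   center mask dilated by the closed discrete ball of radius $d/2$,
   intersected with pore. Dilation happens before cropping the padding, so
   surface pores touched from outside are counted even when no center
   position exists inside the volume.

Step 4 has a consequence worth stating plainly: a dead-end channel narrower
than the sphere has an *empty center mask* but a *non-empty access mask*
near its mouth — the sphere parked outside the open face can still touch
the first $\lceil d/2\rceil$ voxels. This is the deliberate reading of
"accessible from the surface"; tests pin it down.

Because the same discrete-ball definition can be evaluated by explicit
enumeration, the package ships a brute-force oracle
(`brute_force_accessible()`) that re-derives both masks from first
principles with array shifts and an independent (igraph-based) component
labeler. The test suite requires *exact mask equality* between the two
routes on hundreds of random phantoms; equivalence is definitional, not
statistical.

### Numerical choices

* Radius comparisons happen on integer squared voxel distances with a
  $10^{-9}$ slack, so "wall at exactly $d/2$" is permitted regardless of
  floating-point representation, identically in both routes.
* $d \le 2\times$ spacing degenerates to a plain face-seeded flood fill
  (every pore voxel fits).
* A sphere of radius $r$ cannot center itself within $r$ of the sealed far
  face, so "percolates" means the center reached the *last center-feasible
  slab*, not the literal last voxel slab. Percolating points report the
  full physical span as $L$ (the measurement is censored there).
* $L$ is measured over center positions, not the swept volume: the object's
  reach is where its center can travel; swept-volume reach would inflate
  $L$ by $d/2$.
* In `despeckle_keep_largest()`, a size tie between components keeps the
  one containing the lowest-index voxel in column-major scan order. The
  2×2×2 majority filter resolves ties to wall, so preprocessing can close,
  never open, marginal passages — conservative for accessibility claims.

### Monotonicity of the interconnectivity curve

The center mask is exactly nested in $d$, so curves computed with
`accounting = "center"` are exactly non-increasing. The default swept
accounting is the accessible-volume definition, but the closed discrete
ball grows in integer jumps: at even voxel diameters the shell at exactly
$r$ joins the ball, and on highly regular structures (e.g. throat lattices
whose widths are commensurate with the scan) the curve can *increase* by a
few percentage points between adjacent diameters. On disordered phantoms
the effect is below half a percentage point, which is what the property
tests assert; the exact-monotonicity guarantee belongs to the center
accounting only.

## Percolation fitting

Percolation theory gives $L \propto (d - d_c)^{-0.88}$ near threshold in
3D, so $d$ is linear in $L^{-1/0.88}$ with intercept $d_c$ and a slope
("gradient") that reflects the smallest representative volume of the
structure. The exponent 0.88 is the 3D correlation-length exponent; it is a
parameter of `fit_percolation_diameter()` but is never estimated from data
— fitting a two-parameter power law to a handful of points is unstable.

Scanned points are classified into the three regimes: Region 1 (the sphere
crosses the finite dataset; $L$ is censored at the span), Region 2
($0 < L <$ span; usable), Region 3 ($L$ under a depth floor of 3 sphere
radii — only surface roughness is probed; the floor is configurable, as no
principled criterion exists). Only Region-2 points enter the unweighted OLS
fit of $d$ on $L^{-1/0.88}$; a negative intercept is clamped to zero with a
warning flag. Fewer than three usable points raise a condition that the CLI
surfaces as exit code 2 with the remediation hint to enlarge the volume.

**Sub-volume pooling.** On small datasets $L(d)$ is a staircase pinned by a
single bottleneck: over the whole Region-2 window $L$ barely moves, and the
fit degenerates (typically to a negative intercept). `subvolume_scan()`
splits the dataset into $k^3$ blocks and pools their Region-2 points,
sampling the ensemble of bottleneck configurations; the pooled fit recovers
the intercept to within about one voxel of the direct bisection threshold
in validation, at the cost of a low $r^2$ (the pooled points scatter — the
intercept, not the fit quality, is the estimand). This is the small-volume
analogue of measuring a physically larger dataset, and is how the
acceptance suite exercises the end-to-end pipeline.

`percolation_threshold_direct()` provides the model-free check: bisection
on $d$ of the "percolates" flag, i.e. the largest sphere that crosses the
*finite* volume. On synthetic structures whose threshold is known by
construction, every phantom's nominal ground truth is re-measured with this
oracle before being used in any other test, so discretization shifts
(square throats of width $t$ voxels pass spheres of $t$ or $t+1$ voxels
depending on parity; a circular hole of diameter 5 voxels passes
$2\sqrt{8} \approx 5.7$) never silently enter expectations.

## What the phantoms emulate — and what they do not

* `make_throat_lattice()` / `make_disordered_throat_lattice()`: pores
  joined by prismatic throats; transport is throat-limited, the feature the
  shrink-wrap probes. The disordered variant (integer widths uniform on
  [4, 12] voxels by default, lattice pitch 16, pore diameter 14) has a
  genuine finite-width percolation transition and is the substrate for
  end-to-end $d_c$ validation. Defaults put roughly 8 cells per 128-voxel
  axis — small enough to analyze at desk scale, large enough for Region-2
  points to exist.
* `make_lamellar()`: plate-like walls normal to x with wide channels along
  z (width 12 voxels) and narrow random wall holes (diameter 5 voxels),
  reproducing the directionally solidified architecture whose z-axis
  percolation diameter is roughly double the transverse one.
* `make_equiaxed_foam()`: smoothed-Gaussian-field foam, statistically
  isotropic, porosity met by quantile thresholding and then despeckled in
  both phases. Default porosity is 0.75: above ~0.8 the field's solid phase
  drops below its percolation threshold and fragments, which despeckling
  would then delete. Real freeze-dried scaffolds reach ~99% porosity only
  because their walls are connected *sheets*; the foam generator does not
  emulate sheet-like walls, curved anisotropic pore shapes, or wall
  thickness distributions. A green isotropy test therefore establishes that
  the *method* detects no spurious anisotropy, not that the phantom is a
  faithful collagen scaffold.

All generators are bit-reproducible from their seed. Because no public
micro-CT volumes accompany the methodology, the quantitative desk-scale
claims (mask equality, $d_c$ recovery, anisotropy ratios) are all made on
these phantoms; the paper-scale numbers (99% flood fill, $d_c$ of 30–40
micrometers on collagen) require the original scans and are deliberately
not asserted anywhere in the package.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `connectivity` | center space | 6 | diagonal slides can clip walls; 26 opt-in |
| `exponent` | fit | 0.88 | 3D correlation-length exponent; fixed, never fitted |
| `floor_radii` | region split | 3 | depth floor (in sphere radii) separating Region 3 |
| `splits` | `subvolume_scan` | 2 | 8 blocks; balances ensemble sampling vs block size |
| `tol_um` | bisection | spacing/2 | threshold precision; floor at spacing/4 |
| `spacing_um` | everywhere | — | isotropic only; anisotropic data are rejected at read time rather than silently mishandled by the EDT |

## Known limitations

* The original shrink-wrap implementation in commercial CT software is
  undocumented; this package's constructive definition (EDT threshold +
  seeded connectivity + ball dilation) is the contract, and the
  connectivity choice is the likeliest source of divergence from it.
* Percolating $L$ values are censored at the dataset span, and points near
  percolation are excluded from fits rather than capped.
* No tortuosity, permeability, or diffusion modeling: accessibility is
  purely geometric.
* Binary input is the contract boundary: only a plain grayscale threshold
  is offered, no trainable segmentation.
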