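# poreperc

Transport-pathway analysis of porous scaffold volumes: sphere
accessibility and percolation scaling on 3D binary pore/wall images.

## What it does, and for whom

Tissue-engineering scaffolds work only if cells can travel through them.
Given a binary micro-CT volume (pore vs wall, isotropic voxel spacing),
`poreperc` quantifies the transport pathways at four levels:

1. **Flood fill** — largest connected pore fraction (percent of pore
   volume).
2. **3D sphere accessibility** — the pore volume a virtual sphere of
   diameter *d* can reach from the sample surfaces; a pathway counts only
   if it is wider than *d* everywhere. Percent interconnectivity is the
   accessible-volume ratio
   `(V − V_s) / (V − V_m) × 100`
   (*V* ROI volume, *V_s* inaccessible volume, *V_m* solid volume).
3. **Directional accessibility** — the same with a single open face,
   exposing anisotropy.
4. **Percolation diameter *d_c*** — from percolation scaling
   `L ∝ (d − d_c)^−0.88`, the intercept of *d* against `L^(−1/0.88)`,
   where *L(d)* is the maximum accessible distance of the sphere center
   from the entry face. *d_c* is the largest sphere that can travel
   infinitely far through the structure in a given direction — a
   length-scale-independent transport statistic.

The geometric core is an exact Euclidean distance transform: a sphere fits
where the EDT of the wall phase is at least *d*/2; reachability is seeded
connectivity from open faces; accessible volume is ball dilation of the
reachable centers. A brute-force enumeration oracle re-derives the same
masks independently, and the test suite requires exact equality.

Because no public scaffold scans accompany the methodology, the package
includes seeded phantom generators with known ground truth (regular and
disordered throat lattices, lamellar plate structures, equiaxed foams) and
a direct bisection percolation threshold as the model-free check on every
scaling fit.

## Worked example

A disordered throat lattice — spherical pores on a 10-voxel pitch joined
by throats of random width 3–7 voxels — at the 3.74 um voxel size typical
of high-resolution scaffold micro-CT:

```r
library(poreperc)

scaf <- make_disordered_throat_lattice(
  shape = c(96, 96, 96), pitch = 10, pore_diameter = 8,
  throat_range = c(3, 7), spacing_um = 3.74, seed = 1)
scaf
#> voxel_grid: 96 x 96 x 96 voxels (z,y,x), 3.74 um/voxel
#>   porosity 56.2%, physical extent 359 x 359 x 359 um

flood_fill_fraction(scaf)
#> [1] 100
```

Every pore voxel is in one connected component — flood fill sees a
perfectly interconnected structure. Sphere accessibility disagrees as the
probe grows (diameters 2–8 voxels, i.e. 7.5–30 um):

```r
cur <- interconnectivity_curve(scaf, voxels_to_um(c(2, 3, 4, 5, 6, 8), 3.74),
                               face_set("z-"))
as.data.frame(cur)
#>   diameter_um interconnectivity_percent
#> 1        7.48                    100.00
#> 2       11.22                     99.49
#> 3       14.96                     99.96
#> 4       18.70                     82.16
#> 5       22.44                     86.30
#> 6       29.92                      3.44
```

A ~30 um object reaches almost nothing from the z face even though the
structure is "100% interconnected" by flood fill. (The small non-monotonic
blips are a discrete-ball parity effect of the swept-volume accounting on
regular lattices; see the vignette.) The percolation diameter makes this
size dependence a single number. Sub-volume pooling samples the ensemble
of bottlenecks (single small volumes give a staircase *L(d)* that defeats
the fit), and the direct bisection threshold checks the extrapolation:

```r
sc  <- subvolume_scan(scaf, "z-", voxels_to_um(seq(2, 9, 0.5), 3.74),
                      splits = 2)
fit <- fit_percolation_diameter(sc)
fit
#> percolation_fit (face z-): d_c = 25.44 um, gradient = 260.6, r^2 = 0.02331
#>   12 Region-2 points, exponent 0.88

percolation_threshold_direct(scaf, "z-")
#> [1] 23.08534
```

The fitted intercept (25.4 um) and the model-free crossing threshold
(23.1 um) agree to well under a voxel-equivalent (3.74 um). The low r^2 is
expected for pooled lattice scans — the intercept, not the line quality,
is the estimand. On the lamellar phantom the same machinery returns a
z-axis *d_c* roughly double the x-axis value, the anisotropy signature of
directionally solidified scaffolds.

## Command line

```sh
Rscript inst/cli/poreperc analyze --input scan.tif --spacing-um 3.74 \
    --direction 3d,z-,x- --subvolumes 2 --out results/
Rscript inst/cli/poreperc phantom --kind lamellar --shape 64,64,84 \
    --seed 7 --out lamellar.tif
```

`analyze` writes interconnectivity curves (CSV), percolation scans and
fits (CSV/JSON), and a `report.json`, all stamped with a config hash;
reruns are byte-identical. Exit code 2 means too few Region-2 points to
fit (enlarge the volume or widen the diameter range).

Volumes are multipage TIFF (uncompressed 8-bit, WALL = 255, PORE = 0,
spacing in the ImageDescription) or raw bytes with a JSON sidecar.

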