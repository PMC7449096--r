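---
title: "Walnut morphometric phenotyping from X-ray CT: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walnut morphometric phenotyping from X-ray CT: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutct)
```

## The measurement problem

In-shell walnut quality is described by a mix of external morphometry (nut
length and the two transverse diameters, volume, surface area, shape and
roundness indices) and internal anatomy that classically requires cracking
the nut: shell thickness, kernel volume, the kernel/nut filling ratio and
the enclosed empty space. X-ray computed tomography provides a reconstructed
3D greyscale volume of a whole batch of nuts held in low-attenuation floral
foam, from which all fourteen descriptors can be quantified non-destructively.
`nutct` implements that pipeline end to end:

1. **Preprocessing** — Gaussian denoising, greyscale thresholding into a
   foreground mask (a voxel is foreground iff its intensity strictly exceeds
   the threshold `tau`), morphological opening/closing and removal of small
   spots. The foam holder is eliminated purely by the threshold: the foam is
   chosen for low X-ray attenuation, so it sits below `tau` together with
   air.
2. **Individualization** — 3D connected-component labelling of the mask,
   optional watershed splitting of touching nuts, convex-hull estimation
   and per-nut sub-volume export.
3. **Part segmentation** — histogram clustering, multi-level thresholding
   and marker-based watershed separate each nut into shell, kernel and
   enclosed empty space, with a shell-integrity quality control that
   excludes damaged nuts.
4. **Trait quantification** — the fourteen descriptors per nut.
5. **Dataset statistics** — descriptive summaries, Pearson correlations,
   PCA and per-accession rankings over the resulting trait table.

## Traits and formulas

For a nut with volume $V_n$ (mm³) and surface area $A$ (mm²):

* sphericity $\Psi = \pi^{1/3}(6V_n)^{2/3}/A$ — 1 for a sphere, smaller
  otherwise;
* rugosity $\Omega = A/\sqrt[3]{36\pi V_n^2}$ — the reciprocal of $\Psi$;
* shape factor VA3D $S_1 = A^3/(36\pi V_n^2) = \Omega^3$;
* Feret shape $S_2 = D/d$, where $d$ is the minimum caliper width over all
  3D directions and $D$ the maximum caliper width over directions at 90° to
  the minimising direction.

Because $\Psi$, $\Omega$ and $S_1$ are all derived from the *same* measured
pair $(V_n, A)$, the identities $\Psi\,\Omega = 1$ and $S_1 = \Omega^3$ hold
to machine precision on every measured nut; the test suite asserts them at
$10^{-9}$ on every run. Volumes are voxel counts times the voxel volume, and
$V_n = V_s + V_k + V_e$ holds exactly by construction, since the three
compartments partition the nut foreground.

Compartment volumes, thickness and the filling ratio $R = 100\,V_k/V_n$ come
from the part label map; $L$, $F$, $P$ are extents along the principal axes
of the nut voxel cloud; $A$ comes from a triangulated isosurface; $T$ is the
mean inscribed-sphere (local) thickness of the shell.

## Numerical choices

**Surface area.** Counting exposed voxel faces overestimates the area of
smooth objects by tens of percent (about 1.5× for a sphere), which would
destroy the sphericity/rugosity scale — the observed $\Psi$ of real nuts
(up to ~0.93) would be unreachable. `surface_area()` instead smooths the
binary indicator with a small Gaussian (1.5 voxels) and triangulates the 0.5
isosurface by marching tetrahedra; on digitised spheres at nut-scale
resolution it is accurate to ~1%. The independent oracle route uses the
coarea identity (the integral of the gradient magnitude of a smoothed
indicator equals the interface area), so the two estimators never share
code. Sharp polyhedral edges are the worst case for both: the smoothing
rounds edges with a bias that decays like one over the edge length in
voxels, which the unit-cube test demonstrates.

**Feret geometry.** Caliper widths are evaluated on convex-hull vertices
over a quasi-uniform Fibonacci direction lattice (2,000 directions by
default) followed by local cone refinement; $D$ is then the maximum width
over a dense circle of directions orthogonal to the minimising direction.
The brute-force oracle uses 20,000+ directions with no refinement. At kink
minima (boxes) pure sampling has first-order error, which the refinement
removes; on smooth convex bodies both converge quadratically.

**Convex hulls.** No exact-arithmetic 3D hull is needed: hull vertices are
extracted as support points (extreme voxels over the direction lattice) and
the filled hull mask is the sampled half-space intersection, rasterised
exactly per grid column — the feasible x-range of a convex region in each
(y, z) column is an interval. With 1,280 directions the overshoot is far
below one voxel for nut-sized objects.

**Shell thickness.** The inscribed-sphere (Hildebrand–Rüegsegger) local
thickness: the thickness at a voxel is the diameter of the largest sphere
inside the shell covering that voxel, computed by painting spheres seeded at
distance-ridge voxels in descending radius order. Distances to background
voxel *centres* carry a positive bias of about half a voxel, so measured
thickness runs ~0.5–1 voxel high; at the reference 0.1 mm resolution that is
5–10% of the thinnest published shells (0.73 mm) and within the stated
tolerance for shells of 1 mm and above.

**Histogram clustering.** The intensity histogram is binned (1,024 bins,
each occupied bin represented by the mean intensity of its voxels, so exact
levels are recovered exactly) and split into `k` contiguous clusters by
exact weighted 1-D k-means, solved by dynamic programming over cluster
boundaries. This is deliberately initialisation-free: optimal 1-D clusters
of sorted data are contiguous, so the global optimum is computable and the
result is fully deterministic. Cluster ranges are `(low, high]` intervals
with interior boundaries at midpoints between adjacent centres. The
automatic `tau` is the boundary below the kernel cluster — with the default
`k = 4` (air, foam, kernel, shell) the midpoint between the foam and kernel
centres — reproducing the histogram-driven manual threshold choice of the
original workflow while remaining overridable.

**Watershed.** Marker-based priority-flood on the gradient magnitude;
markers are voxels within a quarter range-width of the kernel and air
cluster *centres* (centred on the centre, not the range, so a cluster lying
at the observed extreme — noise-free air at the minimum — still yields
markers). Flooding is FIFO on ties, hence deterministic.

**Empty space by enclosure, not greyscale.** Cavity air is
indistinguishable in intensity from exterior air, so empty space is defined
geometrically: the interior is whatever cannot be reached from the volume
border without crossing shell (6-connected flood against a 26-connected
shell, the complementary-connectivity convention that prevents diagonal
leaks). A nut whose cavity is reachable from outside, or whose shell is
fragmented, fails QC and is excluded from the trait table — the
damaged-shell exclusion rule.

**Enclosure merging in labelling.** A thresholded walnut is topologically a
shell plus contents; a dried kernel that has shrunk off the inner wall is a
separate connected component floating in the cavity. `label_walnuts()`
therefore assigns any component that cannot reach the volume border without
crossing foreground to the component enclosing it. Without this, every nut
with a detached kernel would count twice.

**Touching nuts.** `split_touching()` is opt-in (the foam holder normally
separates nuts). Components are first hole-filled so the distance transform
measures nut radii rather than shell half-thicknesses; seed blobs are
regions deeper than 60% of the component's maximum depth, merged by
single-linkage below the minimum seed separation, and a component is split
only when two seed groups remain — two fused nuts have two deep distance
maxima, a single bumpy nut has one.

## The phantom generator

Every stage is validated against synthetic scans with known ground truth.
A phantom nut is a radial geometry $R(u) = r_{\mathrm{ell}}(u) + a\,B(u)$:
an ellipsoid radius function modulated by a smooth band-limited angular bump
field (a seed-keyed mixture of six cosine harmonics, normalised to unit
amplitude). The shell is the radial band $(R-t, R]$; the kernel is a
soft-union (log-sum-exp blend) of two ellipsoidal lobes whose overall scale
is solved by bisection so the kernel occupies the requested fraction of the
nut volume — the lobe geometry scales linearly, so the fill fraction is
monotone in the scale. Lobes are clipped at the cavity wall: at high fill
targets the kernel presses against the shell (as in a well-filled nut), at
low targets it floats free (as in an over-dried one); both regimes occur in
practice and both are exercised by the tests. Greyscale levels mimic the
four-cluster CT histogram (air 0, foam 25, kernel 90, shell 160, additive
Gaussian noise with σ = 5, about 3% of the shell–air contrast), and cavity
air deliberately shares the exterior air level. Defaults reproduce a typical
nut of the reference population: semi-axes 19.2 × 16.1 × 16.6 mm, shell
1.0 mm, 30% kernel filling.

Ground truth comes in three grades: closed forms for spheres (volumes,
$4\pi r^2$, $\Psi=\Omega=S_2=1$, $T=t$); analytic values for smooth
ellipsoids (Legendre elliptic-integral surface area via Carlson symmetric
forms, exact radial integrals for the offset-shell volumes, $S_2 = a/c$);
and a brute-force oracle on a grid at least twice as fine as the working
grid for bumpy surfaces (voxel counting, coarea surface area, exhaustive
Feret sampling). Because the generator offsets the outer surface radially,
the true *normal* wall thickness is $t\cos\theta$ where $\theta$ is the
radial-to-normal angle; the ground-truth thickness is the volume-weighted
mean of that quantity, evaluated by direction sampling with a numerical
angular gradient — for a sphere it reduces to $t$ exactly.

`make_scan()` assembles batches: nuts with random rotations placed on a
grid, at random non-overlapping positions, or as deliberately touching
pairs, embedded in foam-level background, with a ground-truth label map
numbering each nut's solid material. `damage_shell()` drills an air channel
through the shell; a voxel is converted only when the hole covers it with a
full-voxel margin, so holes narrower than about one voxel are invisible at
the working resolution, exactly as in a real scan.

What the phantoms do *not* emulate: partial-volume blur at material
interfaces, beam hardening, ring artifacts, kernel internal anatomy, and
spatially correlated noise. Passing the phantom suite therefore demonstrates
the correctness of the geometry and measurement chain under controlled
noise, not robustness to every scanner artifact; on real scans the
histogram-clustered thresholds and the QC rule are the main defences.

## Validation conditions and problem sizes

The package's own validation (test suite plus acceptance script) uses:

* **formula identities** on exact quantities (machine precision);
* **a 30-phantom recovery suite** at the reference 0.1 mm voxel size on
  roughly 200³ grids — scaled-down nuts (semi-axes 6.2–8.3 mm, shells
  1.0–1.4 mm, fills 20–25%, noise σ = 5) so thirty full
  generate–segment–measure cycles stay affordable; recovered volumes agree
  with truth within 3%, shell thickness within 10%, filling ratio within
  one percentage point, sphericity/rugosity within 1% and Feret shape
  within 2%;
* **a 12-nut batch** at 0.2 mm voxels with half-scale nuts (the shell
  remains 5 voxels thick), individualized with per-nut Dice above 0.99, and
  a touching sphere pair (r = 15 mm, centres 29.1 mm apart) split by the
  watershed splitter with at least 95% per-nut recovery;
* **a full-pipeline digitised sphere** (r = 15 mm, 0.1 mm voxels) whose
  measured sphericity lands within 0.1% of the theoretical value 1.

Boundary recovery carries about one voxel of rim uncertainty, so mask Dice
scores scale with voxel size over nut radius; the unit tests at deliberately
coarse voxels (0.15–0.4 mm) assert correspondingly scaled bounds and state
so inline.

The per-nut dataset behind the published population statistics (161
accessions) is a journal supplement not redistributable with the package;
the statistics functions are validated against hand-computed oracles and
synthetic tables, and the acceptance test that reproduces the printed
population values runs only when that CSV is placed at
`inst/extdata/additional_file_3.csv` before building.

## Known limitations and open conventions

* **Face vs profile diameter.** The suture plane is not detectable from
  geometry alone. By convention `F` is the extent along the second principal
  axis and `P` along the third; `swap_face_profile = TRUE` swaps them. In
  the published population the profile diameter exceeds the face diameter on
  average, so pure extent ordering cannot reproduce that assignment — the
  ambiguity is surfaced rather than hidden.
* **Thickness bias.** See above: ~+0.5 voxel; thin shells (< 10 voxels)
  approach the resolution floor and should be interpreted accordingly.
* **TIFF carries no spacing metadata**, so `voxel_size_mm` must be given
  explicitly for TIFF stacks — never silently defaulted. Anisotropic NRRD/
  MetaImage spacing is rejected rather than resampled.
* **Proprietary scanner containers are out of scope**; convert to NRRD,
  MetaImage or TIFF stacks first.

## A worked example

```{r, eval = FALSE}
library(nutct)

# synthetic batch of five nuts in foam
sp <- phantom_spec(outer_radii_mm = c(6.5, 5.2, 5.6),
                   shell_thickness_mm = 1.2, bump_amplitude_mm = 0.3,
                   kernel_fill_target = 0.3, noise_sigma = 4, seed = 21)
scan <- make_scan(5, sp, layout = "grid", voxel_size_mm = 0.3, seed = 11)

res <- run_pipeline(scan$volume, accession_id = "DEMO")
res$traits[, c("nut_id", "Vn_mm3", "T_mm", "FillingRatio_pct", "Sphericity")]
res$qc_report$excluded

summarize_traits(res$traits)
```
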