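# angiotomo

Simulation and analysis of propagation-based (in-line) X-ray
phase-contrast tomography of vascular networks, in R.

Mapping the three-dimensional microvasculature of whole organs — for
example the brain of a rat — can be done without any contrast agent:
a dehydrated sample with air-filled vessel lumina is imaged with a
partially coherent synchrotron beam, and refractive-index gradients at the
tissue/air interfaces produce bright/dark Fresnel fringes ("edge
enhancement") that make vessels of a few voxels in diameter visible.
Turning such scans into numbers — bifurcation counts, segment lengths,
vessel volume fraction, the diameter spectrum — requires a long chain of
image-processing stages, each with failure modes of its own.  `angiotomo`
implements that chain as tested, reusable code and, because raw beamline
data of this kind are not publicly available, ships a synthetic vascular
phantom generator so that every stage is verifiable end to end against
exact ground truth.

The package is aimed at imaging methodologists and quantitative biologists
who want to prototype, stress-test or teach this pipeline at desk scale.

## The model in brief

A sample is described by its complex refractive index
`n = 1 − δ + iβ`; the absorption coefficient is `μ = 4πβ/λ`.  For each
projection angle the volume's `δ` and `β` are line-integrated, the exit
wave `exp{−(2π/λ)(p_β + i p_δ)}` is propagated to the detector with the
Fresnel transfer function `H(u,v) = exp{−iπλz(u²+v²)}`, and detector
counts are formed as `dark + Poisson(flat · I)`.  Phase retrieval is the
single-distance homogeneous-object TIE filter

    F = IFFT[ FFT(I_norm) / (1 + πλz(δ/β)(u² + v²)) ],   t = −ln(F)/μ

with `δ/β = 400` by default, applied per projection; slices are then
reconstructed by parallel-beam filtered back-projection (Ram-Lak kernel),
rescaled to 8-bit grey, and — when the sample was captured as two
vertically overlapping half-scans — stitched by FFT phase correlation.
Vessels are recovered by grey-level segmentation (Otsu), inversion inside
the tissue hull and morphological cleanup; morphometry comes from
topology-preserving 3D thinning, a Euclidean distance map for diameters,
and a centerline graph in which a *segment* joins two bifurcations, a
bifurcation and an end point, or two end points, with end points excluded
from the bifurcation count and vessel volume fraction defined as
vasculature voxels over sample voxels.  Virtual micro-endoscopy plans
shortest paths along the centerlines and emits rotation-minimizing camera
poses plus PLY/VRML surface meshes.

## Worked example

```r
library(angiotomo)

scan <- simulate_scan(seed = 1)   # phantom -> acquire -> retrieve -> FBP
res  <- analyze_scan(scan)        # segment -> skeleton -> graph -> metrics

print(scan$geometry)
print(res$metrics)
print(res$recovery)
cat("Dice vs ground truth:", round(res$dice, 3), "\n")
```

```
<scan_geometry> 20 keV (lambda 6.199e-05 um), pixel 5.92 um, z 5e+05 um,
  180 angles over 180 deg, detector 128 x 128 px
<network_metrics> 16 bifurcations, 32 segments, total length 2356 um,
  vessel volume 1.804e+06 um^3 (fraction 0.009856), 75.0% of segments < 30 um
<recovery_report> diameter bias -3.46 um, RMSE 4.35 um; length RMSE 20.4 um;
  unmatched 0.0%
Dice vs ground truth: 0.971
```

The phantom behind this run is a seeded four-level bifurcating tree (15
bifurcations, 31 segments, mean diameters 23–52 µm) inside an ellipsoidal
parenchyma, imaged at 20 keV with 5.92 µm pixels, 50 cm propagation
distance and 180 projections over 180°.  The analysis recovers the vessel
mask with Dice 0.97 and per-segment diameters with an RMSE of 4.35 µm —
under one voxel — through the entire acquisition/retrieval/reconstruction/
segmentation chain; 75 % of recovered segments are thinner than 30 µm
versus a ground-truth fraction of 77 %.  (The one extra junction/segment
pair relative to the generating tree is a near-wall reconstruction
artifact of this seed; segmentation against the ground-truth mask, as run
in the acceptance script, recovers the counts exactly.)

Endoscopy on the same network:

```r
g   <- res$graph
dm  <- res$distance
eps <- which(g$nodes$kind == "endpoint")
pth <- plan_path(g, eps[1], eps[2])
cam <- camera_poses(pth, dm)
write_path_csv(cam, "flythrough.csv")
write_ply(export_surface(res$vessel_mask), "vessels.ply")
```

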