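---
title: "Phase-contrast vascular tomography in silico: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-contrast vascular tomography in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`angiotomo` re-creates, as verifiable code, the analysis chain used to map
cerebral microvasculature with propagation-based synchrotron phase-contrast
imaging: simulated acquisition of a weakly absorbing sample, single-distance
TIE-HOM phase retrieval, filtered back-projection, hemi-scan stitching,
grey-level vessel segmentation, skeleton-based network morphometry, and
virtual micro-endoscopy.  Because real beamline data of this kind are tens
of gigabytes and not publicly deposited, every stage is exercised end to end
on synthetic vascular phantoms whose ground truth is known exactly.  This
vignette explains the models behind each stage, the parameters that matter,
and precisely what the passing test suite does and does not demonstrate
about real data.

## Imaging model

A monochromatic parallel beam of energy $E$ (default 20 keV, wavelength
$\lambda = hc/eE \approx 0.62$ Å) traverses a sample described by its
complex refractive index $n = 1 - \delta + i\beta$.  The phase decrement
$\delta$ drives phase shift, the absorption index $\beta$ drives
attenuation through $\mu = 4\pi\beta/\lambda$.  The sample is a dehydrated
tissue block whose vessel lumina are filled with air: vessel voxels carry
exactly the optical constants of the space outside the sample
($\delta = \beta = 0$), which is the entire contrast mechanism — no
contrast agent appears anywhere in the model.

`project_volume()` forms parallel-beam line integrals of $\delta$ and
$\beta$ by rotating the volume about the vertical axis (bilinear in-plane
interpolation, unit-voxel steps).  `fresnel_propagate()` builds the exit
wave $\exp\{-(2\pi/\lambda)(\,p_\beta + i\,p_\delta)\}$ and applies the
Fresnel transfer function
$H(u,v) = \exp\{-i\pi\lambda z (u^2+v^2)\}$ at the sample-to-detector
distance $z$ (default 50 cm).  At the default pixel size of 5.92 µm the
per-pixel Fresnel number is $p^2/\lambda z \approx 1.13$, i.e. solidly in
the near-field regime where the bright/dark edge fringes appear that make
unstained vessel walls visible; `fresnel_number()` warns when a requested
configuration leaves that regime.

Frames are reflect-padded to at least twice the next power of two before
any FFT.  Reflection (rather than zero) padding avoids the wrap-around
fringes a discontinuous periodic extension would inject, and the *same*
padding is used by the retrieval filter so that forward-then-inverse tests
isolate algorithmic error rather than padding mismatch.

Detector counts follow `raw = dark + Poisson(flat · I) + read noise`, with
a smooth deterministic vignette on the flat field so `flat_dark_correct()`
is exercised nontrivially.  The exposure-to-photon conversion of a real
beamline is unknowable from a published exposure time alone, so
`photons_per_pixel` is an explicit simulation knob (default $10^4$, a
typical well-fill count for a synchrotron CCD); the Poisson mean is tested
to be unbiased against the noiseless signal.

A sample taller than the detector is captured as two vertically
overlapping half-scans (`acquire(split = TRUE)`, default overlap 200 px,
the standard hemi-scan overlap at full scale).

## Phase retrieval

`tie_hom_filter()` implements the single-distance homogeneous-object
transport-of-intensity filter

$$ F \;=\; \mathcal{F}^{-1}\!\left[\frac{\mathcal{F}(I_{\mathrm{norm}})}
  {1 + \pi\lambda z(\delta/\beta)(u^2+v^2)}\right], $$

followed by $t = -\ln(F)/\mu$ in `retrieve_thickness()`.  The
$\delta/\beta$ ratio is the method's one empirical parameter; the package
default is 400, matching the single-material assumption used for
dehydrated brain tissue with air-filled vessels, and it is an ordinary
function argument because in practice it is tuned against a preliminary
scan.  Retrieval is applied per projection before reconstruction — the
standard usage of the single-distance filter, since the transport equation
is formulated in the projection domain.  Numerical choices: the intensity
is floored at $10^{-6}$ of its mean before the logarithm (noise can
otherwise produce non-positive values), and the zero-frequency gain of the
filter is exactly 1, so constant backgrounds pass through unchanged.

The filter is a strong low-pass (suppression length
$\sqrt{\lambda z (\delta/\beta)/4\pi} \approx 31$ µm here).  Applied to raw
intensity it would blur vessels badly; applied to *Fresnel-propagated*
intensity it approximately deconvolves the propagation, which is why the
round trip on a smooth 128³ phantom recovers projected thickness to
0.02 % RMS and why a ≥ 5-fold suppression of edge fringes is asserted as a
test property rather than assumed.

## Reconstruction and stitching

`fbp_reconstruct()` is parallel-beam filtered back-projection: each
detector row is convolved with the band-limited ramp kernel
($h_0 = 1/4\Delta^2$, $h_n = -1/(\pi n \Delta)^2$ for odd $n$; Shepp-Logan
apodization optional), then back-projected with linear interpolation and
scaled by $\pi/N_\theta$.  The discrete kernel — rather than a plain
$|f|$ multiplier — is what keeps the interior mean of an analytic disc
within 2 % of truth (no DC cupping).  Angles must be uniformly spaced
over ≈ 180°; resampling irregular angle lists is deliberately out of
scope.  Projection uses linear interpolation, so the reconstruction
tolerances (5 % RMSE on the disc, 5 % re-projection consistency) account
for interpolation bandwidth, not just noise.

`rescale_grey8()` truncates at the (0.1, 99.9) percentiles by default and
maps affinely to 0–255 (round half up), storing the mapping as an
attribute so it is invertible up to truncation.  All later segmentation
operates on this 8-bit scale.

`find_shift_fft()` registers the two half-scans by phase correlation (the
argmax of the inverse FFT of the normalized cross-power spectrum).  The
slice axis is zero-padded to the joint height of both stacks before
correlating: stitching offsets exceed half the stack height, which would
alias under plain circular correlation.  Shifts are integer by design —
slice merging is integral by nature — and `merge_halves()` drops the lower
stack's copies of the overlapped slices (optional linear cross-fade),
giving `n_upper + n_lower − overlap` output slices.  Degenerate
(near-constant) inputs return a low correlation score and are flagged
unreliable rather than silently registered.

## Segmentation

`segment_parenchyma()` thresholds the grey volume (Otsu by default, fixed
threshold for reproducibility), keeps the largest 26-connected component
and fills its interior cavities, producing the sample hull.
`extract_vessels()` then inverts inside the hull: vessels are the
below-threshold voids enclosed by tissue, which by construction excludes
exterior air.  Connectivity is the standard dual pair — foreground
26-connected, background 6-connected — chosen to avoid topological
paradoxes and to match the thinning stage.  `morphological_clean()`
performs a true Euclidean-ball opening (realized exactly via the distance
transform) of radius 1 voxel plus removal of 26-components below 27 voxels
(≈ one 3³ blob); the defaults remove reconstruction speckle below the
smallest resolvable vessel (~2 voxels at 5.92 µm) without erasing real
vessels, and cleaning is idempotent.

## Network morphometry

`skeletonize()` is topology-preserving 3D thinning: directional
sub-iterations delete *simple* border points one at a time (simplicity
re-checked at deletion time using the standard two-condition
characterization — one 26-component of foreground in the 26-neighbourhood,
one 6-component of background in the 18-neighbourhood), retaining curve
endpoints.  Components, tunnels and cavities of the input are provably
preserved.  Two systematic consequences are documented rather than hidden:
a finite tube's centerline retracts by roughly one radius per end (the
medial axis of a capped cylinder genuinely shortens; the reference
implementations behave identically), and the fixed order of the six
directional sub-iterations makes the skeleton — hence total length —
slightly axis-dependent (a few percent under axis permutation; counts and
volumes are invariant).

`build_graph()` classifies skeleton voxels by 26-neighbour count
(1 endpoint / 2 path / ≥ 3 junction), merges 26-adjacent junction voxels
into junction nodes, and traces segments: a segment connects two
bifurcations, a bifurcation and an end point, or two end points of an
isolated section; an isolated closed loop is one segment.  Two skeleton
artifacts of thick junctions are consolidated, with counts reported:
dangling spurs shorter than 1.2× the local vessel radius (such a spur lies
inside the junction blob and cannot be a resolved branch), and junction
pairs connected by a path shorter than 1.2× the local radius (thinning can
split one anatomical branch point in two).  Sub-resolution self-loops of
≤ 5 voxels are likewise removed: voxelizing the crotch of a bifurcation
can pinch a one-voxel tunnel between the daughter tubes, which thinning
faithfully preserves as a tiny cycle, but a real loop that small would be
below the resolution limit.

Per-segment diameter is twice the Euclidean distance-map value averaged
over the central 80 % of the path — junction-adjacent samples reflect the
junction blob, not the vessel.  Global metrics follow the morphometric
definitions: bifurcations count junction nodes only (end points excluded),
vessel volume fraction is vasculature voxels over sample voxels, and the
diameter spectrum uses 10 µm bins over 0–150 µm plus an overflow bin, with
the fraction of segments below 30 µm reported separately (a length-weighted
variant is available, since the literature is not explicit about the
weighting).  On every acyclic phantom the Euler relation
`segments = junctions + endpoints − components` is asserted.

## Virtual micro-endoscopy

`plan_path()` maps two points to their nearest centerline voxels and runs
a shortest path (by segment length, via `igraph`) through the centerline
graph, splitting segments at mid-segment entry points.  `camera_poses()`
smooths the path with a 5-point moving average (endpoints pinned; the
window auto-reduces if smoothing would push a pose into the wall), sets
the forward vector to the local tangent and propagates the up vector with
the double-reflection rotation-minimizing frame, so the camera never spins
about its view axis; the tested property is that the up vector never
rotates more than the tangent does between consecutive poses.  On a
voxelized centerline the tangent itself can turn by tens of degrees at a
junction, so an absolute bound of a few degrees would only hold for smooth
analytic paths.  Every pose is checked to lie strictly inside the lumen
(positive distance-map value).  `export_surface()` extracts the 0.5
iso-surface with marching cubes in its tetrahedral decomposition (six
tetrahedra per cell around the main diagonal; the split is
translation-invariant, hence watertight), writes PLY and VRML 2.0, and the
camera path exports as CSV for any renderer.

## The synthetic phantom: what it emulates, and what it does not

`vascular_phantom()` grows a seeded bifurcating tree: child radius is
`radius_decay` times the parent's (default 0.79, the cube root of ½ —
Murray's law for a symmetric bifurcation), branch angle 45° ± 5° jitter at
opposite azimuths, lengths shrinking by 0.78 per level, all inside an
ellipsoidal parenchyma so the sample has genuine exterior air.  Radii taper
linearly along each tube.  The default scale — 128³ voxels at 5.92 µm,
root radius 26 µm, four levels — puts segment mean diameters at about
23–52 µm (3.5–9 voxels), straddling the 30 µm reporting threshold.

Real arterial trees branch without touching themselves, and the network
analysis assumes an embedded tube system, so placement is collision-aware:
the nominal direction is used unless the new segment would come within
12 µm (≈ 2 voxels) surface-to-surface of a non-adjacent segment or leave
the volume, in which case a fixed, deterministic fan of alternative
azimuths/polar angles (and, in crowded regions, shorter branches) is
scored and the best-clearing candidate used.  Identical seeds therefore
still give bit-identical trees.  Sibling tubes legitimately share their
origin, so only their distal halves enter the clearance computation.

The phantom deliberately does **not** emulate: capillary beds below the
resolution limit, anastomoses and loops (real cortical networks have
them; the generator is a tree precisely so that count oracles are exact),
organ-shaped hulls, vessel wall contrast, detector blur, ring artifacts,
or beam hardening.  Passing tests therefore demonstrate the correctness of
the *algorithms* under a controlled forward model, and the achievable
accuracy at this voxel size — they do not certify segmentation accuracy on
real tissue, where grey-level statistics are richer than a two-material
mixture.

## Problem sizes and accuracy achieved

The suite and the acceptance script run at desk scale: 128³ volumes, 180
projections over 180° (the full-scale 720-projection, 963 × 1933-pixel
geometry remains available via `scan_geometry()` /
`read_geometry_config()`).  At these sizes the chain achieves, per run of
`scripts/acceptance.R`: TIE-HOM round-trip error ≈ 0.02 % RMS; disc-phantom
FBP RMSE ≈ 4.9 % of contrast with the interior mean within 0.1 %;
noiseless and 100-photon stitching exact in 20/20 trials; vessel-mask Dice
≈ 0.97 end to end; diameter RMSE ≈ 0.7 voxel through the full imaging
chain; the below-30 µm segment fraction recovered within ≈ 1.3 percentage
points of truth; and bifurcation/segment counts equal to the generating
tree's traversal oracle.

## Known limitations

* Single-distance TIE-HOM assumes one $\delta/\beta$ material; multi-layer
  samples retrieve with bias.  Multi-distance or CTF-type schemes are out
  of scope.
* Thinning shortens open tube ends by about one radius; lengths of
  terminal segments are accordingly conservative.
* Phase correlation returns integer shifts only; sub-voxel registration
  and rotation ("offset angle") correction beyond translation are not
  modelled.
* The two half-scans are simulated from one consistent volume; mechanical
  drift between the half acquisitions is not modelled.
* Diameters below ~3 voxels are increasingly quantized; at the default
  5.92 µm pixel this mirrors the physical resolution limit, below which
  real capillaries (4–7 µm) are invisible as well.
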