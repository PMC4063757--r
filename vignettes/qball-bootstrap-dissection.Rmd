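---
title: "Q-ball residual-bootstrap tractography: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Q-ball residual-bootstrap tractography: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qballtract)
```

## What this package computes

`qballtract` implements a complete in-vivo white-matter dissection
pipeline for high-angular-resolution diffusion imaging (HARDI): per-voxel
constant-solid-angle (CSA) q-ball orientation distribution functions
(ODFs) from a spherical-harmonic fit of the diffusion signal, residual
bootstrap resampling of that fit to express measurement uncertainty in the
tracking directions, streamline propagation with a closest-peak constraint
and FA/angle stopping rules, bundle selection and quality control against
cortical parcellation labels, and group-level probabilistic maps and
termination tables. The study design it supports is the dissection of a
long association bundle (the inferior fronto-occipital fasciculus, IFOF)
from a single gate region in the external/extreme capsule through which
all of its components pass.

The package is organised around S4 containers (`DWIVolume`,
`GradientTable`, `ImageGrid`, `Tractogram`, `LabelVolume`,
`TerminationTable`) with plain-text interchange formats: NIfTI volumes,
FSL-style `bval`/`bvec` files, TrackVis TRK tractograms, and CSV
termination tables.

## Signal model and CSA reconstruction

Per voxel, the attenuation $E(\mathbf{g}) = S(\mathbf{g})/S_0$ at the
diffusion-weighted directions is clamped to $[\varepsilon, 1-\varepsilon]$
and transformed to $y(\mathbf{g}) = \ln(-\ln E(\mathbf{g}))$. This
double-log quantity is linear in a real, symmetric, orthonormal
spherical-harmonic basis of even orders $\ell \le L$ (default $L = 4$,
15 coefficients against 55 directions), fit by unregularised least
squares. The CSA ODF follows per harmonic:

$$\psi_{\ell m} = c_{\ell m} \cdot \bigl[-\ell(\ell+1)\bigr] \cdot
  \frac{2\pi P_\ell(0)}{16\pi^2}, \qquad \ell > 0,$$

with $P_\ell$ the Legendre polynomial ($2\pi P_\ell(0)$ is the
Funk–Radon transform in the SH domain and $-\ell(\ell+1)$ the
Laplace–Beltrami operator), and the $\ell = 0$ coefficient set to
$1/\sqrt{4\pi}$, which fixes $\int_{S^2} \psi \, d\Omega = 1$ for every
voxel. Fractional anisotropy comes from an unweighted log-linear tensor
fit with eigenvalues clipped at zero.

Numerical choices, all configurable:

* **Attenuation clamp** $\varepsilon = 10^{-3}$. The double log is
  undefined at 0 and 1; the clamp bounds the transform without touching
  typical white-matter attenuations at $b = 2000$ s/mm².
* **No Laplace–Beltrami regularisation by default** ($\lambda = 0$).
  With 55 directions for 15 coefficients the fit is well conditioned;
  an optional $\lambda$ is exposed for sparser schemes.
* **Basis convention is explicit.** Coefficient vectors carry a basis
  tag (`rsh-even-orthonormal-v1`), and the CSA transform refuses
  coefficients from another convention — a silent basis mismatch is the
  classic q-ball failure mode. Because both the least-squares projection
  and the per-degree CSA multiplier are invariant to the choice of real
  orthonormal basis, the test suite can verify ODF *values* against a
  fully independent Python implementation built on scipy's spherical
  harmonics; agreement is at machine precision.
* **Negative lobes.** CSA ODFs can dip slightly negative; values are
  clipped at zero for peak finding only, the stored SH representation is
  untouched.
* An order-4 fit carries visible truncation error for a sharp
  single-tensor profile (held-out RMSE of the transformed signal around
  0.03–0.04); the error falls below $10^{-2}$ at order 8. Order 4 is kept
  as the default because the residual bootstrap is better behaved with
  more residual degrees of freedom, and 45°-scale peak separation does
  not require a sharper basis.

## Residual bootstrap

The bootstrap operates on the quantity that is linear in the SH basis —
the transformed signal — not on raw DWI values. With hat matrix diagonal
$h_i$ of the fit, residuals are leverage-corrected,
$\tilde r_i = r_i / \sqrt{1 - h_i}$, resampled i.i.d. with replacement
within the voxel, added to the fitted values, refit through the cached
design pseudo-inverse and pushed through the CSA transform. Tests verify
that the corrected residuals recover an injected Gaussian noise scale
within 10% and that the bootstrap mean matches the least-squares fit
within Monte-Carlo error.

Draws are keyed by a counter-based RNG mixing (master seed, streamline
id, step index), so the full pipeline is bit-reproducible for a given
master seed and independent of execution order. One fresh bootstrap ODF
is drawn per (streamline, voxel-visit); how many times a voxel is visited
therefore determines how often its uncertainty is re-expressed, and the
seeding density is the only run-multiplicity parameter.

## Peaks and propagation

Peaks are strict local maxima of the clipped, antipodally symmetrised ODF
over the adjacency graph of a subdivided icosahedral sphere (2562
vertices, about 4° spacing; peaks sit on vertices, with no sub-vertex
refinement — adequate against a 45° separation rule). Candidates are
retained greedily in descending value order under the two rejection
rules: a candidate closer than 45° to a larger retained peak is dropped,
as is one below 0.25 of the ODF maximum over the sphere (read literally:
the maximum of the whole sampled ODF, not of the largest peak). At most
three peaks are kept. At a 90° equal-fraction crossing the order-4 CSA
ODF genuinely exhibits a third, perpendicular local maximum at about 0.3
of the maximum; the rules retain it, and the tests therefore check the
two *largest* peaks against the true axes.

Tracking is bidirectional from every seed. At the seed each retained peak
of a fresh bootstrap ODF starts its own streamline pair along $\pm$ the
peak axis; at every subsequent step only the peak closest to the incoming
direction (after antipodal sign alignment) contributes — the
closest-peak constraint that keeps a second fiber population in a voxel
from bleeding into the track. Steps are 1.1 mm (half a 2.2 mm voxel;
the protocol itself does not fix a step size). Growth stops when the
trilinearly interpolated FA ahead falls below 0.15, the turn between
consecutive step directions exceeds 60°, the track leaves the grid, the
peak set is empty, or a 2000-step safety cap is hit. ODF and peak lookup
are nearest-voxel, because the bootstrap model is per-voxel by
construction; FA is interpolated to avoid blocky stopping. Seed lattices
are $n^3$ per voxel, strictly interior (offsets $(i+0.5)/n$), with
$n = 11$ as the protocol default — 1331 seeds per ROI voxel.

Both stopping rules are audited post hoc in the tests on every emitted
streamline rather than trusted from the propagation loop.

## Dissection and group products

The gate ROI is an explicit voxel mask (a helper builds rectangular masks
on a plane, the shape of a hand-drawn coronal gate; on phantoms the gate
comes from the ground-truth geometry — manual ROI drawing is outside what
software can reproduce). Posterior selection uses an axis-aligned plane
filter that keeps streamlines with a segment crossing or touching the
plane (inclusive rule). Automated quality control implements the two
published exclusion rules operationally: loops as cumulative unsigned
turning above 360°, and grey-matter traversal as interior points entering
more than two distinct cortical labels (endpoints legitimately occupy
two). Cortical VOIs are grown 2 mm into white matter by centre-distance
dilation (nearest label wins, ties to the smaller id); note that with
2.2 mm voxels a 2.0 mm depth grows nothing under the centre-distance
rule — the first shell sits 2.2 mm away. Endpoint classification tests
only the two streamline endpoints, by nearest voxel.

Density maps count each streamline at most once per voxel, with voxel
membership by point containment after supersampling segments at
half-voxel spacing (the brute-force enumeration oracle in the tests bounds
this choice). Binary visitation masks (count ≥ 1), summed across subjects
and divided by $n$, give percentage probability maps whose values are
exact multiples of $1/n$; rendering masks use an inclusive 20% threshold
and are nested under increasing level. Spatial normalisation to a common
space is out of scope: group operations verify grid identity and assume
registration happened upstream.

Termination tables are subject × VOI binary matrices; the summary row is
the exact column percentage. The package ships the four published
20-subject tables (left/right × anterior/posterior) as checksummed CSV
fixtures, with footnoted "very few streamlines" entries carried as
indicator 1 plus a flag — reproducing the tables' counting convention
while preserving the distinction (the minimum-streamline threshold is
configurable for reanalysis). Transcription integrity is enforced by md5
checksums and per-table flag counts at load time; the summaries reproduce
every printed percentage exactly. One known source inconsistency is
recorded: the discussion text of the source tables quotes 30% for the
left cuneus where the table itself gives 35%; the fixture follows the
table.

## The synthetic phantoms

No imaging data accompany the study design, so validation runs on
multi-tensor tube phantoms with full ground truth. Bundles are tubes of
radius 2.6 mm around natural-spline centerlines on a 2.2 mm isotropic
grid; per voxel, every bundle whose tube contains the voxel centre
contributes a compartment with equal fractions, directions given by the
centerline tangent. Fiber tensors use eigenvalues
$(1.7, 0.3, 0.3)\times10^{-3}$ mm²/s (FA ≈ 0.8); the background is
isotropic at $0.9\times10^{-3}$ mm²/s (FA ≈ 0), bracketing the 0.15
stopping threshold. The acquisition scheme is 55 electrostatic-repulsion
directions at $b = 2000$ s/mm² plus one $b_0$ (minimum pairwise angle
about 18°); noise is Rician at configurable SNR, $\sigma = S_0/\mathrm{SNR}$.

Three presets:

* **straight** — one straight bundle; end-to-end sanity (≥ 95% of gate
  seeds connect the two end labels noiselessly).
* **crossing-90** — two orthogonal bundles; the q-ball-versus-tensor
  comparison. At SNR 30 with fixed seeds, bootstrap q-ball tracking
  traverses the crossing to the far label while single-tensor
  principal-direction tracking stalls there (the mixed tensor is oblate,
  its principal axis unstable), which is the motivating property for
  HARDI tracking over DTI.
* **ifof-like** — four bundles gathered through a narrow 3×3-voxel gate
  (each threading it at a small distinct offset, emulating the
  external/extreme-capsule bottleneck), fanning anteriorly to four
  frontal labels and posteriorly to three occipital/parietal/fusiform
  labels, plus a perpendicular bundle crossing the anterior fan
  (emulating corona-radiata/SLF interference). At SNR 30, all seven
  termination labels are reached in each of five bootstrap replicates.

What the phantoms deliberately do not model: head geometry and gyral
folding, partial-volume T2 contrast, susceptibility and eddy artifacts,
fiber dispersion and bottleneck kissing configurations, and registration
error. Passing tests therefore demonstrate correctness of the
reconstruction–bootstrap–tracking–classification chain under the model's
own assumptions, not clinical performance on real data.

## Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately small
scale, chosen so the whole suite completes in minutes while every
statistical check retains a comfortable margin: single-voxel experiments
use 500 bootstrap draws; phantom tracking uses 2–3 seeds per axis
(8–27 per voxel) on grids of roughly $20^3$–$24\times40\times14$ voxels.
The protocol-scale density of $11^3$ seeds per voxel is exercised where
the seed lattice itself is the quantity under test. All randomness flows
from explicit seeds: phantom noise from the phantom seed, bootstrap draws
from the counter-based scheme keyed by the master seed, so every result
in the package is exactly reproducible.

## Known limitations

* Single-shell CSA only; no multi-shell models and no spherical
  deconvolution (sharper but computationally impractical under
  per-visit bootstrap resampling, which is also the trade recorded in the
  source protocol).
* Peak localisation is vertex-limited (~4°); sub-degree angular claims
  are outside its resolution.
* The loop rule (360° cumulative turning) and the grey-matter-traversal
  rule are operational stand-ins for what was originally a
  neuroradiologist's visual inspection; they formalise the two stated
  artifact classes and nothing more.
* `dilateLabels` is a brute-force centre-distance dilation; it is exact
  but quadratic in region size, sized for parcellation-scale labels, not
  whole-brain masks.
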