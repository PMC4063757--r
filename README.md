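# qballtract

Q-ball residual-bootstrap tractography and white-matter bundle dissection
in R.

## The problem

Diffusion-tensor (DTI) tractography fails in voxels where fiber
populations cross, which is exactly where long association bundles such
as the inferior fronto-occipital fasciculus (IFOF) pick up their
"non-classical" branches — fanning frontal terminations and parietal
projections that cross the corona radiata and superior longitudinal
fasciculus. This package implements, as tested and reusable components,
the HARDI pipeline used to dissect such bundles from a single gate region
in the external/extreme capsule:

1. **CSA q-ball reconstruction.** The attenuation $E = S/S_0$ at 55
   directions ($b = 2000$ s/mm²) is transformed to $\ln(-\ln E)$ and fit
   with real symmetric spherical harmonics of even orders up to 4. The
   constant-solid-angle ODF follows per harmonic as
   $\psi_{\ell m} = c_{\ell m}\,[-\ell(\ell+1)]\,2\pi P_\ell(0)/(16\pi^2)$
   with the $\ell = 0$ term fixed to $1/\sqrt{4\pi}$ (unit integral).
2. **Residual bootstrap.** Leverage-corrected residuals
   $r_i/\sqrt{1-h_i}$ of the per-voxel fit are resampled per
   (streamline, voxel-visit) to produce bootstrap ODFs — tracking
   directions sampled from measurement uncertainty, reproducible through
   a counter-based RNG.
3. **Peak extraction** with the two refinement rules: drop peaks closer
   than 45° to a larger peak, and peaks below 0.25 of the ODF maximum.
4. **Tracking**: bidirectional streamlines from dense in-voxel seed
   lattices (11³ per voxel in the protocol), closest-peak direction
   selection, FA ≥ 0.15 and ≤ 60°-per-step stopping rules.
5. **Dissection**: plane filters, loop/grey-matter-traversal QC, 2 mm
   label dilation into white matter, endpoints-only VOI classification.
6. **Group products**: streamline density maps, binary visitation masks,
   percentage probability maps with a 20% rendering threshold, and
   subject × VOI termination tables with exact "% of 1" summaries.
7. **Synthetic phantoms**: multi-tensor tube geometries (straight,
   90° crossing, and a gate/fan layout with a perpendicular crossing
   bundle) with ground-truth labels, plus the four published 20-subject
   termination tables as checksummed fixtures.

Interchange formats are NIfTI, FSL `bval`/`bvec`, TrackVis TRK and CSV.
See the vignette (`vignettes/qball-bootstrap-dissection.Rmd`) for the
models, parameter choices and limitations.

## Worked example

Track the 90°-crossing phantom at SNR 30 from its gate ROI and classify
terminations:

```r
library(qballtract)
phantom <- makePhantom(phantomPreset("crossing-90", snr = 30, seed = 1))
cfg <- trackingConfig(seedsPerAxis = 2L)   # 8 seeds per gate voxel
bundle <- trackBundle(phantom$dwi, phantom$gate, cfg, masterSeed = 42)
bundle
#> Tractogram: 25 streamlines, 3-40 points, step 1.1 mm
#>   ImageGrid: 21 x 21 x 9 voxels, 2.2 x 2.2 x 2.2 mm
attr(bundle, "log")$terminationReasons
#>        angle fa_threshold
#>           12           38

classifyTerminations(bundle, phantom$labels, subject = "phantom-01")
#>   voi        name count indicator
#> 1   1    near_end    22         1
#> 2   2     far_end    16         1
#> 3   3  cross_left     0         0
#> 4   4 cross_right     0         0
```

The bundle enters at `near_end`, traverses the 90° crossing and reaches
`far_end` with 16 supporting streamlines; the crossing bundle's own
labels are untouched (the closest-peak rule keeps tracking from turning
into it). The same call with `method = "tensor"` — single-tensor
principal-direction tracking on identical data — reaches `far_end` with
0 streamlines: the crossing defeats the tensor model, which is the case
for q-ball tracking in one table.

The published termination tables ship as fixtures:

```r
fx <- loadTableFixtures()
summarizeTerminations(fx$left_posterior, format = TRUE)["cuneus"]
#>   cuneus
#> "35.00%"
```

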