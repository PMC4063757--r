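Package: qballtract
Title: Q-Ball Residual-Bootstrap Tractography and White-Matter Bundle
    Dissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of constant-solid-angle q-ball orientation
    distribution functions from high-angular-resolution diffusion MRI,
    residual-bootstrap resampling of the spherical-harmonic signal fit,
    streamline tractography with closest-peak direction selection and
    fractional-anisotropy/angle stopping rules, bundle dissection against
    cortical parcellation label volumes (plane filters, quality-control
    exclusions, label dilation into white matter, endpoint classification),
    and group-level probabilistic maps and termination-table summaries.
    Includes multi-tensor phantom generators with ground truth for
    end-to-end validation, plus readers and writers for NIfTI, FSL
    bval/bvec and TrackVis TRK formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
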