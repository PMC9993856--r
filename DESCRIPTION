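Package: sctdir
Title: Synthetic-CT-Assisted Deformable Registration for CBCT Contour Propagation
Version: 0.1.0
Authors@R: person("Maintainer", "sctdir", email = "sctdir@example.org", role = c("aut", "cre"))
Description: Tools for adaptive-radiotherapy image workflows in which daily
    cone-beam CT (CBCT) is first translated into a CT-quality synthetic CT
    (sCT) by a one-way contrastive generative model (patch-wise NCE loss plus
    an adversarial term), and planning-CT contours are then propagated by
    log-domain diffeomorphic demons registration. Includes a digital phantom
    generator (planning-CT-like slices, known smooth deformations, CBCT-style
    degradations: shading bias field, streaks, noise, contrast compression),
    minimal NIfTI-1 input/output, rigid pre-alignment and resampling,
    segmentation overlap and surface-distance metrics (DSC, HD95, ASD), and a
    two-arm experiment driver comparing direct pCT-CBCT registration with the
    sCT-assisted route.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
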