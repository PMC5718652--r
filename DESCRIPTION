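Package: portalreg
Title: Portal Image-DRR Registration for Radiotherapy Setup Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates patient setup errors in external-beam radiotherapy by
    registering a megavoltage portal radiograph to the planning digitally
    reconstructed radiograph (DRR). Three user-specified control points
    (isocenter plus one point on each graticule axis) anchor an affine
    portal-to-DRR transform with out-of-plane plate-tilt correction; the
    corrected pair is fused in complementary colors for visual verification,
    and the beam's-eye-view field shift (and optional in-plane rotation) is
    estimated automatically by multiresolution hill climbing on the mutual
    information of the joint intensity histogram. A synthetic phantom module
    renders chest- and pelvis-like DRR/portal image pairs with burned-in
    field and graticule at known offsets, and an evaluation module scores
    estimates against truth (distance, consistency, accuracy bins, paired
    t-test) so the whole pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
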