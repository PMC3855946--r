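Package: ctus
Title: Fast B-Mode Ultrasound Simulation from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates B-mode ultrasound sector images from 3D CT volumes.
    Tubular structures are enhanced with a multiscale Hessian vesselness
    filter so that vasculature renders anechoic; thin-plate-spline
    interpolation maps between the rectangular scanline grid and the
    display sector; echoes are generated by an adjacent-region acoustic
    model (intensity-difference reflection weights with bone and air
    clamps, Lambert directional response, power-law attenuation, seeded
    speckle); and multiple transducer elements are integrated with a
    Kaiser window before linear scaling to 8-bit. Includes a synthetic CT
    phantom generator (vessels, liver-like tissue, bone, air) with
    ground-truth masks, and readers/writers for NIfTI, MetaImage,
    raw+sidecar volumes and PNG/PGM images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    RNifti,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
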