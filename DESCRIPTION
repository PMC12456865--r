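Package: nirpdt
Title: Virtual Trials of Near-Infrared Photodynamic Therapy in Digital Breast Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Voxel-based simulation pipeline for estimating the therapeutic
    effect of near-infrared photodynamic therapy (NIR-PDT) delivered by
    upconversion-nanoparticle photosensitizer constructs (UCQRs) in the
    breast. Provides a seeded generator of labeled prone-breast voxel
    phantoms with controllable glandular density, BI-RADS-style density
    classification, duct-confined spherical tumor embedding, a weighted-packet
    Monte Carlo engine for 808-nm light transport in heterogeneous labeled
    media (Henyey-Greenstein scattering, Fresnel refraction, Russian
    roulette), the UCQR energy-transfer cascade converting local fluence into
    a per-session photodynamic dose in photons per cubic centimetre, and
    threshold-based planning of the number of irradiation sessions required
    to treat the whole tumor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
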