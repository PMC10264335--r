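Package: monopet
Title: Monte Carlo Simulation and NEMA NU-2 Performance Analysis of
    Monolithic-Detector Long Axial FOV PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale Monte Carlo event generator and analysis pipeline
    for cylindrical PET scanners built from monolithic LYSO detector
    modules. Simulates positron decays, annihilation photon transport
    through attenuating phantoms (photoelectric absorption and
    Klein-Nishina Compton scattering), crystal detection with energy and
    timing blur, paralysable per-module dead time and coincidence sorting
    with ground-truth event lineage. Implements the NEMA NU-2018
    performance measurements (sensitivity, count rates, noise equivalent
    count rate, scatter fraction, spatial resolution, image quality) and
    list-mode MLEM / TOF-MLEM reconstruction with attenuation correction
    from a voxelised mu-map.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
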