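Package: ordose
Title: Discrete-Ordinates Boltzmann Dose Engine for Photon and Proton Beams
Version: 0.9.0
Authors@R: person("ordose", "developers", role = c("aut", "cre"),
    email = "ordose@example.org")
Description: A deterministic radiotherapy dose engine that solves the linear
    Boltzmann transport equation (LBTE) by the method of discrete ordinates on
    Cartesian voxel phantoms.  Photon beams are transported through Compton
    scattering with a chained electron stage (Moller and Mott scattering);
    proton beams are transported with a continuous-slowing-down fixed source
    and elastic (Mott) scattering, including spread-out Bragg peak
    construction.  The package also provides an analytic proton depth-dose
    comparator in the Bortfeld family, synthetic phantom and beam fixtures,
    a spatial-uncertainty kernel for robust planning, adaptive voxel
    coarsening, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
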