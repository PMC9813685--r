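Package: tpmsflip
Title: Charge-Flipping Phase Retrieval for Triply Periodic Minimal
    Surface Like Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Iterative crystallographic phase retrieval for materials whose
    electron density organises on a triply periodic minimal surface (TPMS),
    such as lyotropic liquid-crystal bicontinuous cubic phases and
    mesoporous silicas.  Implements a charge-flipping variant with two-sided
    density thresholds, an optional volume-fraction density shift, periodic
    flipping/threshold parameter schedules, an optional real structure-factor
    (centrosymmetry) constraint and a generic symmetry-orbit projection of
    initial phases.  Provides the density-range indicator I_rho and the
    Hessian-convexity indicator I_K for candidate ranking, the
    amplitude-weighted phase-agreement score R_p (minimised over origin
    shifts and Babinet inversion), an exhaustive sign-search oracle for
    centrosymmetric data, a synthetic TPMS diffraction-data generator,
    plain-text reflection (hkl) files, CCP4/MRC density maps and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
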