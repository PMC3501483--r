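Package: chr2pore
Title: Photocurrent Kinetics, GHK Permeability and Excluded-Volume Pore
    Size for Channelrhodopsin-2
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for two-electrode voltage-clamp (TEVC)
    photocurrent recordings of channelrhodopsin-2 (ChR2) and related
    constructs: segmentation and (bi)exponential fitting of light-evoked
    current traces (tau_on, tau_decay, tau_off, Iss/Ip), assembly of
    current-voltage relations and reversal-potential extraction,
    Goldman-Hodgkin-Katz (GHK) conversion of reversal-potential shifts
    into relative permeability ratios, and excluded-volume estimation of
    the minimum pore diameter from the linear relation between the square
    root of permeability ratios and alkali-cation radius.  Includes a
    synthetic-data generator (four-state photocycle ODE plus constant-field
    current simulator) that emulates the oocyte recording protocol with
    known ground truth, so every stage of the pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
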