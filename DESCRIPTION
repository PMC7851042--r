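Package: reflexsim
Title: Closed-Loop Simulation of a Biomimetic Stretch Reflex for Cable-Driven Prosthetic Hands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software closed-loop simulator of a monosynaptic stretch-reflex
    controller for a cable-driven prosthetic hand. Surface EMG (or a synthetic
    amplitude-modulated noise surrogate) is decoded into an alpha motor command
    by a nonlinear Bayesian grid filter; the command drives six size-ranked
    pools of Izhikevich spiking motoneurons whose spike trains activate a
    spike-driven Hill-type muscle with force-length and force-velocity scaling;
    muscle tension actuates a virtual torque motor, cable and hand plant with
    contactable objects; musculotendinous and contractile-element lengths are
    reconstructed from motor rotation and fed to a bag1/bag2/chain muscle
    spindle whose Group Ia afferents close the reflex loop. Includes scripted
    virtual experiments (aperture-command curve, quasi-static stiffness probe,
    beam-press event timeline) and Fitts-law throughput metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
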