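Package: vesiclefill
Title: Quantitative Analysis and Biophysical Modelling of Synaptic Vesicle
    Glutamate Loading from Live-Cell pHluorin Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing synaptic-vesicle re-acidification and
    neurotransmitter filling from live-cell fluorescence imaging of
    pH-sensitive reporters (synaptopHluorin, CypHer5E) and of a dual
    ratiometric chloride/pH sensor (ClopHensor-type). Provides a trous
    (starlet) wavelet detection of functional boutons from stimulation
    difference images, per-bouton trace extraction and mono-exponential
    kinetic fitting, Henderson-Hasselbalch mapping between normalized
    fluorescence and luminal pH, calibration and inversion of the
    ratiometric chloride/pH sensor, closed-form proton and charge budget
    calculators for a single vesicle, and a single-vesicle
    electro-chemical flux simulator (V-ATPase pump, glutamate/H+ exchange
    through the vesicular glutamate transporter, chloride channel
    conductance, fast luminal buffer equilibria). A synthetic-data
    generator with persisted ground truth emulates image stacks, bouton
    traces and calibration datasets for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
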