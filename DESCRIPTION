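Package: ppikin
Title: Kinetic Modelling of Platelet Phosphoinositide Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic modelling of the phosphoinositide and inositol
    phosphate pathway in platelets downstream of the collagen receptor GPVI.
    Provides a family of eleven ordinary-differential-equation model variants that
    encode competing hypotheses about pathway regulation (stimulated lipid
    phosphatase activity, calcium-dependent kinase recruitment, a secondary
    intracellular PtdIns pool, protein sequestration of PtdIns(3,4,5)P3 and
    PtdIns(4,5)P2, and alternative synthesis routes), together with stiff
    integration, a synthetic time-course generator emulating CRP-stimulation
    data, Latin-hypercube multistart bounded least-squares calibration, AICc
    model ranking with parameter-uncertainty quantiles, local sensitivity
    analysis, and in-silico inhibitor and stimulus-reshaping experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
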