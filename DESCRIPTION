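Package: coldshift
Title: Kinetic Modeling of Chloroplast Gene Expression Under Cold Shift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-reaction kinetic model of transcription, translation and
    degradation of mRNA and protein in the chloroplast, with machinery to
    study acclimation to a drop in temperature. Provides temperature scaling
    of rate constants (Arrhenius, Stokes-Einstein diffusion, Q10 factors,
    encounter-count reasoning), exact steady states and a closed-form
    solution of the linear cascade, a numerical integrator for piecewise
    temperature-shift protocols, analysis of compensatory control points
    (required fold-changes, mRNA side effects, transition times and the
    cost-versus-speed Pareto front), a synthetic western-blot time-course
    generator with replicate noise and slow shared fluctuation, and
    least-squares recovery of rate constants from time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
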