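Package: dnadyn
Title: Langevin Dynamics of Structured DNA Assemblies with Finite-Element
    Base-Pair Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained equilibrium and non-equilibrium dynamics of
    structured DNA assemblies (DNA origami). Each base pair is a rigid node
    with six degrees of freedom; intrahelical steps, interhelical crossovers,
    single-stranded connections and breakable blunt-end stacking bonds are
    finite elements. Hydrodynamics enter through the generalized
    Rotne-Prager-Yamakawa mobility matrix with translation-rotation coupling,
    and the Langevin equation is integrated with a Gronbech-Jensen-Farago
    scheme extended by half-time stepping and Simpson's rule for the internal
    force. Includes screened Debye-Hueckel electrostatics with ion-concentration
    schedules, Morse-potential base stacking fitted from potentials of mean
    force, parametric builders for duplexes, helix bundles, wireframe polygons
    and a two-arm switch, plus trajectory analysis: RMSD/RMSF, quasi-harmonic
    (PCA) and normal-mode frequencies, Pearson and mutual-information
    correlation maps, base-pair step parameters and opening angles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    ggplot2,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
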