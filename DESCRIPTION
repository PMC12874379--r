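Package: gridff
Title: Grid-Projected Force Fields for Molecules on Rigid Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Precomputes the noncovalent interaction field of a rigid
    crystalline substrate on 3D grids (factorized Morse components under
    Lorentz-Berthelot mixing, plus reciprocal-space Poisson electrostatics)
    and interpolates it with tricubic B-splines whose forces are exact
    analytic gradients of the interpolated energy.  On top of the field it
    provides FIRE structural relaxation, Langevin dynamics over replica
    batches, rigid and relaxed manipulation scans (vertical pulls, lateral
    maps, dragging over defects) and minima-hopping configuration sampling
    with RMSD-based uniqueness, together with a direct pairwise-sum plus
    Ewald reference backend that every grid result can be validated against.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
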