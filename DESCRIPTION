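Package: smipp
Title: Dual-Space Phasing of Atomic-Resolution Diffraction Data with
    Inner-Pixel Preservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab initio recovery of crystallographic structure-factor phases
    from normalized moduli |E| at atomic resolution, in space group P1, by an
    iterative dual-space FFT algorithm: a sign mask of the current density
    turns rho into |rho|, the origin-free difference synthesis delta is
    multiplied by the mask to give the eta product function, and a modified
    tangent formula (the angular part of eta's Fourier transform) updates the
    phases.  An inner-pixel-preservation (ipp) density modification keeps
    only the 27-voxel neighbourhoods of the strongest eta peaks, which
    accelerates convergence markedly.  Includes a synthetic P1 point-atom
    crystal generator for the three scatterer classes (weak, medium, strong),
    trial drivers with random or shifted-modulus starting phases, ground-truth
    scoring with origin and enantiomorph search, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
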