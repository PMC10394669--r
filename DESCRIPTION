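Package: dlsinvert
Title: Regularized Inversion of Dynamic Light Scattering Autocorrelation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-angle dynamic light scattering (DLS)
    measurements of macromolecules in solution.  Second-order autocorrelation
    curves are converted to first-order data through the Siegert relation and
    inverted into intensity-weighted hydrodynamic-radius distributions by
    Tikhonov-Phillips regularized non-negative least squares on a log-spaced
    radius grid.  The regularization parameter can be fixed or selected
    automatically from the corner of the L-curve located with the triangle
    method.  Fitted distributions are summarized per region of interest by
    peak radius, weighted harmonic mean and polydispersity index.  A Mie
    scattering forward simulator generates realistic synthetic correlograms
    from Gaussian particle-size populations for validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
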