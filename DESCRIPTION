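Package: xylemflow
Title: Hydraulic Network Modelling and Inverse Pressure Estimation for Xylem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models steady pressure-driven sap flow on vessel/pit resistance
    networks of plant xylem. Vessel lumina are Hagen-Poiseuille resistors and
    inter-vessel pit fields are area-normalized resistors; Kirchhoff node
    balance is solved sparsely. Top boundary pressures are inferred from an
    observed per-pixel flow raster (e.g. flow MRI) by minimizing a windowed
    residual objective, either as a single uniform pressure, by matching
    total flow, or independently per vessel group as a bound-constrained
    linear least-squares problem. Includes flow-weighted summary statistics,
    Nash-Sutcliffe efficiency, transverse pressure-gradient analysis,
    sliding-window tests of Hagen-Poiseuille deviations, Ohm's-law analogue
    networks of heterogeneously connected xylem, and a synthetic network and
    flow-map generator for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite,
    tiff,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
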