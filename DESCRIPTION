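Package: coalGrowth
Title: Coalescent Genealogies for Stochastic Tissue Growth Models
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward stochastic simulators of growing tissues (layer-by-layer
    Wright-Fisher growth with constant or linearly growing population, and
    Eden lattice growth in bounded (1+1)- and (2+1)-dimensional and unbounded
    radial geometries, with optional cell diffusion), together with backward
    lineage tracing of full cell genealogies to their most recent common
    ancestor. Provides exact-coalescent (Fu) transition matrices, Kingman
    closed forms, spatio-temporal front statistics (depth and radius
    distributions, front roughness), and the scaling analyses that connect
    coalescence times and lineage survival to the dynamic exponents of
    Kardar-Parisi-Zhang fractal growth: the T_MRCA ~ N^z law, effective
    population rescaling, and the lineage-survival exponent
    alpha = (d-1)/z.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), ape, withr, optparse
Config/testthat/edition: 3
biocViews: Coalescent, Genetics, CellBiology, Software
RoxygenNote: 7.3.3
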