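Package: rsaRates
Title: Residue-Level dN/dS Versus Solvent Accessibility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for residue-level analysis of how protein core size and
    expression level shape the linear relationship between evolutionary rate
    (dN/dS) and relative solvent accessibility (RSA). Computes per-residue
    solvent accessible surface area by Shrake-Rupley sphere sampling,
    normalizes it to RSA and transfers it across homologs; joins RSA with
    four-taxon codon alignments, assigns proteins to core-size and expression
    groups by ranked fractions, and concatenates gapless codon columns into
    RSA bins; estimates a single dN/dS per bin by maximum likelihood under a
    Goldman-Yang codon model with codon-column bootstrap standard errors (and
    a Nei-Gojobori counting oracle); fits error-weighted straight lines to
    rate-versus-RSA points, compares slopes and intercepts by t-tests, and
    builds fold-change-versus-RSA curves with propagated errors. A
    site-heterogeneous codon simulator with known ground-truth lines,
    expression-dependent codon bias and synonymous-rate scaling exercises the
    whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ape,
    Biostrings,
    bio3d,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), Matrix, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
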