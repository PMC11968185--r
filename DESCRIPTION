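Package: antagsim
Title: Sexually Antagonistic Selection on Continuous Traits: Invasion
    Analysis, Forward Simulation, and Genomic Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study whether sexually antagonistic selection maintains
    genetic polymorphism in continuous traits. Provides sex-specific fecundity
    landscapes (power and Gaussian families), an adaptive-dynamics engine that
    locates singular trait values and classifies selection as diversifying,
    stabilizing, or directional, an individual-based continuum-of-alleles
    simulator, a polygenic diallelic two-sex Wright-Fisher simulator with
    autosomal, X-hemizygous, and pseudoautosomal inheritance modes, and the
    summary statistics used to probe genomic signatures of sexual antagonism
    (between-sex FST among successful parents, sex-specific fitness
    associations, minor-allele-frequency spectra, sex load).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
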