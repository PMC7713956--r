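Package: meiodrive
Title: Transmission Ratio Distortion and Meiotic Drive Tests in Hybrid
    Backcross Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test for meiotic drive in multi-generation hybrid
    backcross pedigrees genotyped at microsatellite markers linked to
    centromeres or distal chromosome ends. The package traces the
    subspecies origin of marker alleles through the pedigree, infers null
    alleles, classifies parental genotype constellations by their
    informativeness, counts informative allele transmissions, estimates
    the drive parameter k against a male-derived background transmission
    rate, and tests for chromosome-specific and genome-wide distortion
    using exact binomial tests, offset binomial GLMs and binomial
    random-intercept models fitted by adaptive Gauss-Hermite quadrature.
    A forward simulator of ZW meiosis with configurable centromeric
    (meiosis I) and distal (meiosis II) drive reproduces the structure of
    a two-step backcross breeding design, including null alleles,
    infertile eggs, chromosomal abnormalities and founder introgression,
    so that every analysis stage can be validated against simulated
    ground truth. A window-based scan flags introgressed founder genome
    regions from lineage-specific SNP counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
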