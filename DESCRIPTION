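Package: mitocage
Title: Selection on Mitochondrial Haplotypes in Population Cages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for perturbation-reperturbation population-cage
    experiments on competing mitochondrial DNA haplotypes. Estimates
    per-generation selection coefficients as slopes of log haplotype
    frequency on generation, summarizes replicate cages with
    random-intercept mixed models fit by maximum likelihood (parametric
    bootstrap confidence intervals, repeatability V_R = v/(v+r),
    likelihood-ratio tests), analyzes non-competitive isofemale fecundity
    with linear models, and provides a generative Wright-Fisher simulator
    of the cage design (multinomial drift, genotyping subsampling with
    scoring failures, isofemale reperturbation) for validation and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), lme4, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
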