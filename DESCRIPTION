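Package: glycowall
Title: Enzymatic-Fingerprint MS Annotation and Cell-Wall Omics Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying fruit cell-wall dynamics from enzymatic
    fingerprinting. Parses xyloglucan letter codes (G/X/L/F) and
    hexose/pentose composition codes, computes sodiated monoisotopic
    oligosaccharide masses, annotates MALDI-TOF digest peak lists within a
    mass tolerance, and normalizes intensities to digest-specific reference
    ions. Adds cell-wall composition accounting (starch-corrected
    non-starch polysaccharides, degree of methylesterification, sequential
    digest release fractions, stage-wise ANOVA), microarray-style
    differential statistics (lowess and quantile normalization,
    empirical-Bayes moderated t-tests, correlation-distance hierarchical
    clustering, qPCR relative expression), and correlation-based
    integration of biochemical and transcriptomic profiles (PCA, genotype
    pooling, thresholded Pearson networks). Includes seeded synthetic-data
    generators emulating the five-stage apple fruit study design for
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
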