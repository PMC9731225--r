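Package: imputeval
Title: Reference-Panel Genotype Imputation, Meta-Imputation and
    Accuracy Evaluation on Synthetic Multi-Population Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained framework for studying how reference-panel
    ancestry and genotyping-array content drive genotype-imputation
    accuracy.  Simulates phased multi-population haplotype panels with
    tunable divergence under a forward Wright-Fisher model, designs
    population-optimized tag-SNP array manifests, applies a
    reference-panel quality-control cascade (exact Hardy-Weinberg test,
    missingness, low-complexity masking, indel/multi-allelic/singleton
    removal, cross-dataset presence), imputes array-masked targets with
    a Li-Stephens haplotype-copying hidden Markov model, combines
    dosages from several reference panels by accuracy-weighted
    meta-imputation, scores results with aggregated R-squared and the
    percentage of well-imputed variants binned by non-reference allele
    frequency, and localizes inter-population differences in linkage
    disequilibrium with a windowed eigenvalue (varLD-style) scan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
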