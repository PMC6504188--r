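Package: hlafinemap
Title: Fine-Mapping of HLA Association Signals from Imputed Dosages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for fine-mapping disease association signals
    across the HLA region from SNP2HLA-style imputed dosages of SNPs,
    classical alleles and amino-acid residues. Implements multi-allelic
    omnibus likelihood-ratio tests with nested conditional analysis,
    cohort meta-combination (sample-size weighted, inverse-variance and
    Fisher's method), liability-scale heritability from odds ratios,
    risk-residue burden and genetic risk score analyses, EM haplotype
    estimation with Lewontin linkage disequilibrium statistics, a
    contact-potential based immunogenic-peptide preference score for
    binding-groove residues, autoantigen charge/pI profiling, and a
    synthetic-cohort generator with planted causal residues so every stage
    is testable without restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pROC,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
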