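Package: panelpute
Title: Reference-Panel Construction and Genotype Imputation with a
    Haplotype-Copying Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds merged genotype reference panels from heterogeneous
    array- and sequence-derived datasets (quality-control filtering,
    Hardy-Weinberg exact testing, strand harmonization via allele codes
    and flanking sequences, duplicate removal and intersection merging),
    phases and imputes low-density study sets up to panel density with a
    Li-Stephens haplotype-copying hidden Markov model scaled by a genetic
    map, and quantifies imputation accuracy by hold-out masking: dosage
    R-squared, hard-call concordance, and stratification by the per-site
    Info certainty score.  Includes a breed-structured haplotype
    simulator so the whole study design runs end-to-end on synthetic
    data, plus panel-composition ablation and identity-by-state
    multidimensional scaling experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
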