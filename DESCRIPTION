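Package: potapop
Title: Genotyping Quality Control, Admixture and Core Selection for
    Polyploid Genebank Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for SNP-array dosage genotyping of clonal, mixed-ploidy
    germplasm collections such as cultivated potato. Provides paired-sample
    fingerprint identity checks and collection error rates, SNP-based ploidy
    prediction and heterozygosity from five-cluster array calls, a Gibbs
    sampler for STRUCTURE-style Bayesian admixture of arbitrary-ploidy
    dosage genotypes with replicate management and Evanno delta-K model
    selection, a rule-based taxonomic classifier driven by admixture
    proportions, UPGMA dendrograms and PCA for diversity analysis, and core
    and mini-core subset selection under the accession-to-nearest-entry
    objective. A synthetic multi-ploidy collection generator with full
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
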