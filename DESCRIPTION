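Package: kapkit
Title: Characterization and Molecular Evolution of Tandem KRTAP Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining, classifying and analysing the evolution of
    keratin-associated protein (KRTAP) gene families in genomic scaffolds.
    Includes a synthetic-genome simulator for tandem single-exon gene clusters
    with gene conversion (optionally GC-biased), pseudogenization and assembly
    fragmentation; seed-and-extend homology search with frameshift-aware
    translated alignment; integrity (intact/partial/pseudogene), compositional
    class (high-sulfur vs high glycine-tyrosine) and subfamily classification;
    neighbor-joining phylogenies on p-distances with bootstrap interior-branch
    support; modified Nei-Gojobori synonymous/nonsynonymous divergence; GENECONV
    style gene-conversion fragment tests and MaxChi recombination scans; codon
    site models (M0, M1a, M2a, M7, M8) with likelihood-ratio tests for positive
    selection; and repertoire tabulation with pseudogenization rates, subfamily
    presence and Dollo gain/loss mapping on a species tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
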