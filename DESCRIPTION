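Package: ovisMstn
Title: Population Genetics and In Silico Prioritization of Intronic SNPs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population-genetic and in silico functional
    characterization of intronic single-nucleotide polymorphisms, built
    around the nine-variant panel segregating in intron 1 of the ovine
    myostatin (MSTN) gene.  Provides per-locus diversity statistics
    (observed and expected heterozygosity, Wright's FIS, polymorphic
    information content) with Hardy-Weinberg chi-square tests; EM-based
    haplotype frequency estimation and phase assignment from unphased
    diploid genotypes; pairwise linkage disequilibrium (D, D-prime,
    r-squared) and Fisher exact tests from inferred gamete counts; IUPAC
    ambiguity-coded genotype motif tallies; allele-aware position weight
    matrix scanning with exact score-distribution p-values; molecular
    dynamics trajectory metrics (RMSD, RMSF, radius of gyration,
    solvent-accessible surface area, hydrogen-bond counts, principal
    component analysis, free energy landscapes); and seeded synthetic-data
    generators, including a deterministic reconstruction of a 54-animal
    Ukrainian Carpathian Mountain sheep cohort from its published summary
    frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
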