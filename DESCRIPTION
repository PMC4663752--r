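Package: pseudomap
Title: Genetic-Map-Guided Pseudomolecule Construction and Assembly Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for evaluating de novo genome assemblies and anchoring them
    onto high-density genetic linkage maps. Provides length-based assembly
    statistics (N50, NG1-NG100 curves, coverage, gap fraction), telomere-motif
    scanning and k-mer based genome-size estimation; construction of genetic
    maps from F2 genotype matrices (EM recombination-fraction estimation,
    linkage grouping, marker ordering, Haldane and Kosambi map functions);
    placement of SNP array probes on scaffolds, detection of misassemblies as
    contradictions between physical and genetic marker order, ordering and
    orienting scaffolds into pseudomolecules with estimated inter-scaffold
    gaps, and AGP v2.0 emission; variant-level filtering rules for error
    correction and marker design (strand-bias testing, flank screens, marker
    spacing, homopolymer classification, sequence editing with coordinate
    remapping); terminal-overlap contig merging and contained-contig removal;
    gene-family size-delta accounting and recombination-landscape tracks; and
    a synthetic diploid-cross simulator that generates every input with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
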