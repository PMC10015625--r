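Package: introscape
Title: Windowed Introgression Landscapes, Topology Weighting, and
    Mating-System Reconstruction for Resequenced Species Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the genomic landscape of
    interspecific introgression from biallelic SNP data in windows along
    the genome. Implements allele-frequency ABBA-BABA machinery (D with
    block-jackknife significance, D_min over trio arrangements, f_hom
    admixture fractions, windowed f_dM scans and putatively-introgressed
    region calling), five-taxon D_FOIL tests that separate ancestral from
    directional post-speciation gene flow, Twisst-style topology
    weighting over taxon groups with canonical topology identifiers and
    normalized quartet scores, windowed Weir-Cockerham F_ST with outlier
    indices and region classification, recombination-quantile
    partitioning and binned correlations against covariate tracks,
    sweep-track intersection, and two-state Mk maximum-likelihood
    ancestral reconstruction of mating system. A built-in multispecies
    coalescent simulator with dated admixture pulses and
    recombination-dependent retention of introgressed ancestry provides
    ground-truthed synthetic data for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
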