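Package: gbspanel
Title: Curation and Diversity Analysis of Genotyping-by-Sequencing Inbred Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing large inbred genotyping-by-sequencing
    (GBS) panels: site-level quality filtering including a biparental
    error-correction filter, window-based nearest-neighbor imputation of
    missing genotypes, IBS/IBD relatedness with duplicate detection and
    merging, principal-coordinate ordination, and genome-windowed diversity
    statistics (Weir-Cockerham fixation index, nucleotide divergence,
    shared-haplotype length sampling, and linkage-disequilibrium decay).
    A synthetic-panel generator with known ground truth (population
    structure, pedigrees, biparental families, genotype-dependent
    missingness, and base-call errors) provides a parameter-recovery test
    surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    MASS,
    igraph,
    data.table,
    vcfR
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Genetics, SNP, PopulationGenetics, QualityControl
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'GenotypePanel-methods.R'
    'diversity.R'
    'family-filter.R'
    'gbspanel-package.R'
    'haplotype-length.R'
    'impute.R'
    'io-hapmap.R'
    'io-vcf.R'
    'ld.R'
    'ordination.R'
    'relatedness.R'
    'simulate-panel.R'
    'simulate-perturb.R'
    'site-filters.R'
    'utils.R'
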