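Package: BarcodeClones
Title: Barcode-Genotype Clone Maps from Long Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters high-fidelity long reads of barcoded, mutagenized clone
    libraries into clones by combining barcode similarity with genotype
    coherence. Reads are aligned to a reference amplicon; barcodes and
    candidate variants are extracted with their quality scores; reads sharing
    identical (virtual) barcodes are seeded into clusters whose genotypes
    agree, and clusters with similar barcodes are iteratively merged under
    edit-distance, Jaccard-similarity and size-divergence criteria. Per-clone
    consensus barcodes and error-filtered genotypes are called and translated
    to protein consequences. Dual flanking barcodes enable detection of
    non-unique barcodes and PCR-crossover chimeras. A seeded read simulator
    with ground truth supports end-to-end validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AmpliconLayout-class.R'
    'BarcodeClones-package.R'
    'CloneCalls-class.R'
    'ReadExtractions-class.R'
    'CloneClusterSet-class.R'
    'cluster.R'
    'consensus.R'
    'extract.R'
    'pipeline.R'
    'qc.R'
    'simulate.R'
    'utils.R'
    'variants.R'
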