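Package: utrlens
Title: Characterization of Untranslated Regions for Post-Transcriptional
    Regulation Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize catalogs of alternative 5' and 3'
    untranslated region (UTR) variants and their coding sequences:
    length and G+C composition statistics with UTR-CDS correlation,
    upstream AUG/ORF detection with Kozak-context and cap-distance
    classification, polyadenylation-signal typing and efficiency
    classification, over-represented oligonucleotide detection against
    Markov backgrounds, miRNA target-site accessibility scoring
    (duplex/opening energies), minimum-free-energy and suboptimal
    secondary-structure censuses by abstract shape, and conservation
    statistics including codon-position-partitioned identity and
    Nei-Gojobori Ka/Ks. A synthetic-data generator with planted,
    recoverable features supports end-to-end validation without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Software, SequenceAnalysis, Transcription, GeneRegulation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
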