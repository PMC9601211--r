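Package: OpxScreen
Title: Gene-Neighborhood Screening for Short OPX Proteins Coupled to
    Outer-Membrane Beta-Barrel Translocons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects outer-membrane polysaccharide export (OPX, Wza-like)
    proteins in annotated prokaryotic genomes from Poly_export (PF02563)
    domain hits, corroborates them by polysaccharide-biosynthesis gene
    context within a five-gene neighborhood, assigns export pathways
    (Wzx/Wzy-dependent, ABC transporter-dependent, or PCP-adjacent) from
    the closest context gene, removes redundancy by greedy incremental
    clustering at a 90 percent identity threshold, scans 3-state secondary
    structure for C-terminal alpha-helices, identifies and verifies coupled
    outer-membrane beta-barrel partner genes (at least 16 strands, OM
    localization), and classifies short (<= 280 aa) OPX proteins into the
    coupled/no-helix versus uncoupled/helix dichotomy. Includes a seeded
    synthetic-genome generator with planted export systems and ground
    truth for end-to-end validation, plus the pulldown enrichment decision
    rule (peptide-count filter, fold-change and Welch-test thresholds) for
    interaction proteomics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    BiocGenerics,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, SequenceAnalysis, Clustering, Classification
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'OpxScreen-package.R'
    'barrel-couple.R'
    'enrichment.R'
    'genome-io.R'
    'helix-scan.R'
    'identity-cluster.R'
    'opx-detect.R'
    'pipeline.R'
    'synthetic-data.R'
    'utils.R'
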