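Package: wrkycensus
Title: Genome-Wide Census of WRKY Transcription Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide annotation of plant WRKY
    transcription factor families from a predicted proteome, gene models and
    expression matrices. Detects WRKY core heptapeptides and parses the
    downstream zinc finger into spacer lengths and terminal residue type;
    assigns group labels (I, IIa-IIe, III, IV) from domain inventory and
    reference-tree placement; computes Table-style physicochemical profiles
    (molecular weight, isoelectric point, aliphatic index, GRAVY, instability
    index); derives exon-intron organization with intron phases and R-/V-type
    domain introns from GFF3; detects gene clusters and tandem duplications;
    builds neighbor-joining phylogenies with bootstrap support from
    progressive domain alignments; and turns expression matrices into
    qualitative tissue, developmental-trend and treatment-response calls.
    Includes a seeded synthetic-data generator that plants every ground-truth
    feature so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
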