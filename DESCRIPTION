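Package: aoxkit
Title: Curation Toolkit for Plant Alternative Oxidase (AOX) Gene Families
Version: 0.1.0
Authors@R: person("aoxkit", "maintainers", email = "aoxkit@example.org",
    role = c("aut", "cre"))
Description: Tools for curating plant alternative oxidase (AOX) gene
    families from genomic, coding, promoter and protein sequences:
    spliced-alignment delineation of exon/intron structure, splice-variant
    comparison, signature-motif and diagnostic-residue classification with
    systematic isoform naming, alignment-based transfer of residue
    numbering onto the Trypanosoma brucei AOX reference with functional
    domain profiling, degenerate (IUPAC) promoter motif scanning, CpG
    island detection by windowed observed/expected statistics, protein
    molecular weight and isoelectric point computation, and expression
    ratio matrices for heat-map display. Includes a synthetic gene-family
    generator with a ground-truth manifest so every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    grDevices,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
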