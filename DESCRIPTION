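Package: aluexon
Title: Detection and Classification of Intergenic Alu Exonisation Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects exonisation of intergenic Alu elements from
    splice-junction evidence in aligned RNA-seq reads. Candidate Alu exons
    are called from predicted exons whose splice sites fall inside antisense
    Alu elements and are supported by junction-spanning reads, linked to
    upstream genes through the splice-junction graph, and classified as
    intergenic when they lie downstream of the gene's last genuine
    polyadenylation site. For intergenic events the package assigns the
    splicing mechanism (terminal-exon skipping versus cryptic 5' splice-site
    activation), measures polyA-to-exon distances and the splicing
    contribution at the Alu exon 3' splice site, and estimates per-condition
    inclusion levels. Additional modules score tissue-wise relative abundance
    of Alu-exon-containing isoforms from FPKM tables, apply a three-criterion
    human/mouse ortholog filter for Alu-derived 3' extensions, and simulate
    annotation bundles and read sets with planted events for end-to-end
    validation against a ground-truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    rlang,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
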