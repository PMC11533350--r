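Package: magqc
Title: Quality Classification of Metagenome-Assembled Genomes Under the
    MIMAG Standards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies metagenome-assembled genomes (MAGs) into
    high-quality, near-complete, medium-quality, low-quality and failed
    draft categories from CheckM-style completeness/contamination
    estimates and Bakta-style tRNA/rRNA annotations, following the MIMAG
    reporting standards with the near-complete extension. Computes
    per-bin assembly statistics (size, N50, longest contig, contig
    count), emits the recommended MIMAG metadata as CSV, sorts bin FASTA
    files into per-quality directories, and renders deterministic
    per-run and cross-run comparison reports for benchmarking binning
    tools. Includes a seeded synthetic-fixture generator so the whole
    pipeline is testable without external tools or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
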