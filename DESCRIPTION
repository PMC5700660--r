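Package: cogview
Title: Comparative Visualization of Prokaryotic Gene Neighborhoods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates prokaryotic proteins with COG and Pfam profile-HMM
    hits, resolves overlapping hits into domain architectures with a
    score/length rule cascade, extracts orientation-normalized genomic
    neighborhoods around all genes of a queried orthologous group or Pfam
    domain, computes the per-neighborhood occurrence percentage of every
    co-occurring model, and renders comparative gene-arrow figures (SVG and
    PDF) with clan-aware coloring, a legend, and machine-readable per-gene
    annotation records. Includes a seeded synthetic-genome generator with
    planted conserved operons for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    xml2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
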