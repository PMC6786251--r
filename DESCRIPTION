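Package: mitoprofile
Title: Characterization Statistics for Annotated Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the descriptive characterization of circular insect
    mitochondrial genomes from existing annotations: base composition with
    AT/GC strand-skew statistics per region, strand class and codon position;
    relative synonymous codon usage (RSCU) and start/stop codon surveys under
    the invertebrate mitochondrial genetic code; intergenic/overlap geometry
    of the annotated gene ledger; signed circular gene-order encoding with
    breakpoint distances and rearrangement-event classification against the
    ancestral insect arrangement; tRNA cloverleaf and RNA secondary-structure
    pair statistics from dot-bracket input; and concatenated supermatrix and
    partition-scheme preparation for downstream phylogenetics.  A synthetic
    mitogenome generator with known ground truth supports end-to-end testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
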