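Package: dupscan
Title: Disorder-Aware Scanning of Chromosomal Duplication Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline asking why a stressed genome duplicates one
    particular chromosomal region rather than another, using intrinsic protein
    disorder as the ranking signal. Calls long intrinsically disordered
    regions from per-residue predictor scores, summarises disorder composition
    per chromosome, enumerates every continuous k-gene fragment of the genome
    and ranks a query region by its disorder content, selects a minimal-
    disorder duplication plan under a gene budget, tests functional term
    over-representation with the hypergeometric test and Benjamini-Hochberg
    FDR control, and compares protein-protein interaction network centralities
    between chromosome-defined groups. Ships a synthetic genome generator with
    planted structure so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
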