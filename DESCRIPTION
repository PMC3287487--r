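Package: comotif
Title: Combinatorial Motif Co-Occurrence Analysis of Conserved Promoter
    Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for detecting co-occurring cis-regulatory motifs in
    evolutionarily conserved promoter regions. Orthologous promoters are
    aligned (Smith-Waterman-Gotoh local alignment, reference-centred
    progressive multiple alignment with iterative refinement) and
    non-conserved positions are masked; motifs are discovered de novo by
    a zero-or-one-occurrence-per-sequence (ZOOPS) EM algorithm and located
    by PWM scanning with exact-null E-values or by degenerate string
    matching under a width-dependent substitution budget; group
    over-representation is scored with an Over-Representation Index (ORI);
    and directional co-occurrence among candidate motifs is inferred by
    fitting hierarchical log-linear models to the binary occurrence table
    via iterative proportional fitting with backward edge elimination,
    yielding a conditional-independence graph, motif combinations and a
    gene-by-combination star table. A synthetic-data generator with exact
    log-linear pattern sampling provides fully specified test inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
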