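Package: bipyrimidine
Title: Bipyrimidine Signatures and Theoretical Genomic UV Photoreactivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts overlapping dinucleotides in genome sequences, derives the
    four bipyrimidine incidences (TT, TC, CT, CC per genome base) and G+C
    content, and computes the theoretical genomic photoreactivity score P_g as
    a weighted sum of the incidences using experimentally determined intrinsic
    photoreactivities. Includes a seeded synthetic-genome simulator (i.i.d. and
    first-order Markov composition models) for grouped genome collections, the
    statistical stage used to compare taxonomic groups (group summaries with
    1.96 standard-error intervals, Welch two-sample t-tests, one-way ANOVA with
    Tukey HSD contrasts, and least-squares regression of P_g on G+C content),
    and command-line orchestration for end-to-end reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
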