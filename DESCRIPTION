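Package: rdrprospector
Title: Divergent RNA Virus Discovery in Metatranscriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable pipeline for prospecting highly divergent
    RNA viruses in assembled metatranscriptomes. Contigs are triaged into
    four evidence tiers (strong hit, weak hit, orphan with long ORF, dark
    matter) by protein-level similarity search against a labelled reference
    set; orphan contigs carrying open reading frames of at least 200 amino
    acids are screened with profile hidden Markov models for remote
    RNA-dependent RNA polymerase (RdRp) homology, with decoy profiles and
    winner-takes-all arbitration controlling false positives; candidates
    are verified by scanning for the catalytic motifs A, B and C of the
    RdRp palm domain; -1 ribosomal frameshift architectures (GGAUUUU
    slippery site) and the protozoan mitochondrial genetic code are handled
    explicitly; abundances are expressed as percentages of non-rRNA reads;
    and pairwise-identity species demarcation with threshold clustering and
    rank placement against intra/inter-genus identity distributions
    completes the taxonomic assessment. A seeded synthetic-metatranscriptome
    generator with a machine-readable truth table makes every stage testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
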