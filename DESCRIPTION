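Package: retrodate
Title: Dating and Annotation of Gene Retrocopies from Fixed and Polymorphic Variants
Version: 0.1.0
Authors@R: person("Retrodate", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for reconstructing the evolutionary history of recently
    inserted gene retrocopies (processed pseudogenes and retrogenes) from
    sequence panels. Implements HGVS-style coding coordinates, global
    pairwise alignment and variant extraction between a parent gene and its
    retrocopy, classification of variants as polymorphic or fixed and as
    ancestral or derived using outgroup parsimony, reconstruction of the
    parent allele at retrotransposition time, molecular-clock age estimation
    with rate intervals reconciled against phylogenetic presence/absence
    bounds, assignment of short reads among near-identical paralogs via
    diagnostic sites, annotation of retrocopy hallmarks (target-site
    duplications, poly(A) remnants, intron loss, strand-aware motif hits),
    allele-frequency summaries from genotype count tables, and a
    truth-annotated synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
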