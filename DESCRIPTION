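Package: fairledger
Title: Blockchain-Style Metadata Quality Control with Erasure-Coded
    Distributed Storage for FAIR Data Sharing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-process simulation of a decentralized FAIR data-sharing
    platform for life-science research consortia. Metadata records are
    validated against Dublin-Core-based templates by a permissioned network
    of endorser-validator-committer nodes under proof-of-authority majority
    consensus, committed to an append-only hash-chained ledger that doubles
    as the metadata database, and linked through a stable Data ID to
    immutable payloads held in a content-addressed object store. The store
    splits every payload into systematic Reed-Solomon erasure-coded shards
    over GF(2^8) placed across organizations, so that any half of the
    shards reconstructs the data. Metadata updates are re-validated as new
    versions while the full history is retained; tooling covers tamper
    detection with inconsistency localization, replica resynchronization,
    permissioned download, data purging and export to an open ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    openssl,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    digest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
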