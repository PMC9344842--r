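# fairledger

Blockchain-style metadata quality control with erasure-coded distributed
storage, for FAIR data sharing in research consortia — as a
self-contained, fully in-process R package.

## The problem

Cross-disciplinary life-science collaborations need to share
heterogeneous experimental data across institutions while (i) enforcing
that every dataset is described by metadata conforming to an agreed
standard, (ii) trusting no single party to decide what is valid, (iii)
keeping the metadata database tamper-evident and replicated, and (iv)
surviving hardware loss at any one site. `fairledger` simulates the whole
stack — validators, ledger, object store, version control — so the
architectural guarantees can be stated as executable properties and
tested on a laptop.

## The model

* **Metadata quality control.** Records are validated against templates
  extending the 15-element Dublin Core standard (required elements,
  two-letter ISO 639-1 language codes, controlled vocabularies, ISO 8601
  dates, numeric parsing). Validation is executed independently by every
  endorser–validator–committer (EVC) node.
* **Proof-of-authority majority consensus.** A transaction commits iff
  the number of signature-verified true verdicts is strictly greater than
  half of *all* registered EVC nodes on the channel: with $E$ registered
  nodes the commit condition is $\#\{\text{true}\} > E/2$, so a 100-node
  channel commits exactly when ≥ 51 nodes are available and honest.
  Ed25519 signatures; offline nodes count against the quorum.
* **Tamper-evident ledger.** Committed transactions are hash-chained with
  SHA-256 (`payload_hash` over the canonical transaction serialization,
  `previous_hash` over the predecessor's header). `verify_chain()`
  localizes any inconsistency to the earliest block where it is
  detectable. The ledger *is* the metadata database: search and version
  history are pure ledger scans.
* **Erasure-coded storage.** Each payload is split into $k$ data +
  $m$ parity shards by a systematic Cauchy/Reed–Solomon code over
  GF(2⁸) (polynomial 0x11D); any $k$ of $N = k+m$ shards reconstruct.
  With the default $k = m = N/2$ the store tolerates losing half the
  devices. Shards are placed round-robin across organizations.
* **Version control.** Every metadata revision is re-validated as a new
  entry and committed as version $n+1$ under the same Data ID
  (DID = first 32 hex chars of SHA-256(data digest ‖ initial metadata
  digest)); all versions point at the same immutable payload.

## Worked example

```r
library(fairledger)

platform <- create_platform()          # 3 orgs, 2 EVC + 3 storage nodes each
corpus   <- generate_corpus(seed = 42, n_records = 2)

up <- upload(platform, "alice", "alice-secret",
             corpus$record[[1]], corpus$payload[[1]])
up$did
#> [1] "05b78b3d496fbdb6ff7ef7bafe2a8e16"

rev <- corpus$record[[1]]
rev$values$Description <- "revised during demo"
update_metadata(platform, "bob", "bob-secret", up$did, rev)$version
#> [1] 2

tidy(platform_history(platform, up$did))
#> # A tibble: 2 × 6
#>   version block position metadata_digest                   template_id submitter
#>     <int> <int>    <int> <chr>                             <chr>       <chr>
#> 1       1     1        1 798489cec0bb755a08d48d57bca10ea6… manufacture alice
#> 2       2     2        1 887ec83d9bd2f3a599e54b37efc91fbf… manufacture bob

down <- download(platform, "carol", "carol-secret", up$did)
length(down$payload); down$data_status
#> [1] 1024
#> [1] "ok"
```

The DID is stable across both metadata versions, both versions resolve,
and the downloaded payload is byte-identical to what was uploaded. A
record with `Language = "eng"` (three letters) would be rejected by every
honest endorser and leave neither a block nor a shard behind.

A thin command-line front end over the same functions ships in
`inst/cli/fairledger.R` (`verify`, `search`, `fixtures`, `demo`):

```sh
Rscript inst/cli/fairledger.R demo
Rscript inst/cli/fairledger.R verify ledger.jsonl
```

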