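---
title: "Methods: majority-endorsed metadata quality control over a tamper-evident ledger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: majority-endorsed metadata quality control over a tamper-evident ledger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairledger)
```

`fairledger` is an in-process simulation of a decentralized FAIR
data-sharing platform of the kind used by cross-disciplinary life-science
consortia: metadata quality control by a permissioned validator network,
a hash-chained ledger doubling as the metadata database, erasure-coded
distributed object storage, and version control that pins every metadata
revision to immutable data. This vignette explains the model each
component implements, the tunable parameters and their defaults, the
numerical and design choices made where the design was genuinely open, and
what the synthetic test corpus does and does not demonstrate.

## Metadata model and quality control

A *metadata record* is a flat map of field names to text values, claiming
conformance with a *template* — the predefined standard the platform
enforces. The base template is the 15-element Dublin Core descriptive
standard (`Creator` through `Rights`); experiment templates extend it with
additional fields. Seven field kinds are supported: free text, controlled
vocabulary, language code, date, integer, decimal, and identifier.

Validation (`validate_record()`) reports one violation per failed check and
never throws: required fields must be present and nonempty, no field may
fall outside the template, language codes must be exactly two ASCII letters
(the ISO 639-1 surface form), controlled vocabularies are membership
checks, dates must be ISO 8601 calendar dates (`YYYY-MM-DD`), and numeric
kinds must parse from their string form.

Open points we had to decide:

* **Language rule.** The two-letter check is purely syntactic by default.
  An allowlist of the ISO 639-1 codes is built in (`iso639_1_codes()`)
  but off by default, because the enforced standard is the two-letter
  surface form; semantic code registries evolve independently.
* **Empty strings count as missing** for required fields: a blank form
  field carries no information.
* **Dates** use the ISO 8601 calendar-date convention; nothing in the
  domain requires times or timezones at the record level.
* **Units** live in field names (`collagen_concentration_mg_per_ml`) and
  in the `units` annotation; they are documentation, not checked
  semantics. Cross-field and unit-aware validation is out of scope.

Every node must hash identical metadata identically, so records have one
*canonical byte form*: compact UTF-8 JSON with keys sorted bytewise and
only the mandatory JSON escapes. Canonicalization is the foundation of the
whole trust chain — record digests, proposal signatures, transaction
serialization and block hashes are all derived from it.

## The ledger as metadata database

Transactions (one validated metadata version, bound to a Data ID, a data
digest, a submitter and the collected endorsements) are packaged into
blocks. A block stores its index, the hash of the previous block, a
payload hash over the canonical serialization of its transaction list, and
an orderer-assigned timestamp. SHA-256 is used everywhere; it is
deterministic, ubiquitous, and leaves no parameter choices.

`verify_chain()` recomputes every payload hash and every link, emitting a
finding that names the earliest block at which each discrepancy is
detectable: `payload-mismatch`, `broken-link`, `bad-genesis`, `bad-index`.
Two choices deserve comment:

* **Fixed genesis.** The genesis block carries the epoch timestamp
  `1970-01-01T00:00:00Z` and an all-zero previous hash, so independent
  deployments of the same consortium share a genesis and replicas are
  bit-comparable from block 0.
* **The tip-hash argument.** Pure link recomputation cannot see a
  corrupted timestamp in the *final* block: the tip's own hash is
  referenced by nothing inside the ledger. Replicas, however, always know
  the consensus tip digest, so `verify_chain(ledger, tip_hash =)` accepts
  it and closes the gap. This is what makes single-character tamper
  detection exhaustive, and it mirrors how the resynchronization path
  actually audits candidate replicas.
* **Timestamps come from the orderer's logical clock**, never wall time,
  so every run of the simulation is bit-reproducible.

Search is exact and case-insensitive over committed record values, in
chain order; free-text ranking is deliberately out of scope.

## Consensus: proof-of-authority majority endorsement

Each organization runs endorser–validator–committer (EVC) nodes holding a
ledger replica and an Ed25519 keypair. A proposal is broadcast to every
EVC node of the channel; honest online nodes validate the record against
the registered templates and sign their verdict, malicious nodes sign
*true* unconditionally (the endorse-everything fault model), offline nodes
return nothing.

The decision rule (`decide()`) commits iff the number of
signature-verified, verdict-true endorsements is **strictly greater than
half of all registered nodes** on the channel. Two consequences follow
directly:

* offline nodes count *against* the quorum — unavailability is a lost
  vote, so the system tolerates failures only while a strict majority
  remains available and honest; on a 100-node channel the commit boundary
  sits at exactly 51 nodes;
* endorsements whose signatures fail verification are discarded *before*
  counting, so forged or tampered endorsements can only lower the count.

Where the design was open: "majority" at even node counts is resolved as
strict (`> N/2`, so 4 of 6 commits and 3 of 6 does not); the quorum
denominator is all registered nodes rather than responders; there is a
single orderer per channel with a logical clock (orderer redundancy is out
of scope); and blocks carry one transaction each by default, matching the
per-submission upload flow. The malicious model is endorse-everything
only — equivocation and forged blocks are represented through the tamper
tests on the ledger itself.

Resynchronization adopts the longest candidate replica among non-offline
peers *that passes `verify_chain()`*; inconsistent candidates are refused
and reported, never silently adopted.

## Erasure-coded object storage

Payloads are content-addressed (object id = SHA-256 of the bytes) and
split with a systematic maximum-distance-separable code over GF(2⁸) with
reducing polynomial 0x11D: the payload is zero-padded to a multiple of
*k*, split into *k* stripes (the data shards), and *m* parity shards are
produced from a Cauchy-derived generator with $x_i = i$, $y_j = k + j$ —
disjoint index sets, so every square submatrix is invertible and **any
*k* of the *N = k + m* shards reconstruct the payload**. Decoding solves
the k×k system by Gaussian elimination over the field; corrupt shards are
detected by digest against the manifest and dropped, never trusted
(error-locating decoding is out of scope).

The default configuration is $k = m = N/2$ with $N = 8$: tolerance of
exactly half the storage devices, with $k = 1$ degenerating to full
replication. Placement is round-robin across organizations with a cap of
⌈N / organizations⌉ shards per organization per object, so no single
organization's loss can destroy recoverability in the default
configuration with at least two organizations.

## Version control and the Data ID

A Data ID (DID) is minted deterministically as the first 32 hex characters
of the digest of the concatenated data and initial-metadata digests —
content-based rather than random, so tests and replicas agree without
coordination. Metadata updates re-run the full endorsement lifecycle as if
new, commit as version *n + 1* with the unchanged data digest, and leave
all prior versions retrievable. The chain itself enforces immutability:
appending a transaction whose data digest differs from the DID's committed
digest is refused, versions must be contiguous, and the version index is
always reconstructed by scanning the ledger (no side database is
authoritative). Updates to one DID are serialized by the orderer's FIFO
order; there is no branching or merging — history is linear by design.

## The upload/download lifecycle

Upload is metadata-first with staged storage: shards are written to a
staging namespace, the transaction is endorsed and committed, and only
then is staging promoted. A rejected or failed submission therefore leaves
neither blocks nor live shards — committed metadata can never point at
data that was never stored, and rejected metadata never leaves orphaned
shards. Storage is deduplicated by content address, which is why purging
one DID's data reports every DID sharing the payload. Purge deletes all
shards everywhere but leaves the ledger untouched: the metadata still
resolves and downloads report an explicit missing-data status rather than
an opaque failure.

Access control is deliberately minimal: salted-hash credential checks and
consortium membership (channel membership of the user's organization).
Per-dataset ACLs and licensing are out of scope. Export to an *open
ledger* re-packages all versions of selected DIDs, in source order, into a
fresh chain whose genesis is stamped with the export instant: records are
not re-validated (that happened at submission), but every block hash is
recomputed — including a full-export chain, whose hashes must differ from
the source's because the open ledger is a new deployment whose provenance
is established by verifying the new chain.

## The synthetic corpus

The fixture generator emulates a two-phase tissue-fiber experiment from
engineered-living-materials work: a *manufacture* phase (core–shell
hydrogel fiber fabrication: cell type with a controlled vocabulary,
collagen concentration, cell density, alginate flow rate, CaCl₂
concentration, incubation temperature) and a *measurement* phase (inner
and outer fiber diameters at three points along the axis, microscope image
count, instrument id). The manufacture defaults are the reference wet-lab
protocol values (HEK293 cells, 4 mg/ml collagen, 10⁸ cells/ml, 200 µl/min,
100 mM CaCl₂, 37 °C); measurement diameters are drawn uniformly from
plausible ranges (inner 90–130 µm, outer 180–260 µm) with at least five
images. Payloads are seeded pseudo-random bytes, 1 KiB by default.
Corruption modes plant exactly one violation kind per record
(missing-required, bad-language-code, not-in-vocabulary, bad-date,
bad-number), which is what lets the planted-fault tests assert the *exact*
violation rather than mere invalidity. The generator is deterministic
under its seed and restores the caller's RNG state.

What passing tests show — and what they do not: the corpus exercises the
full validation surface, the consensus machinery and the storage fault
model, but its records are well-formed text with simple vocabularies. Real
laboratory metadata brings encoding noise, semantic unit errors,
vocabulary drift and schema evolution, none of which are represented; a
clean bill of health here is evidence about the *mechanism*, not about any
particular laboratory's data quality.

## Problem sizes and numerical choices

The shipped checks run at desk scale, chosen so each claim is tested
exhaustively where exhaustion is feasible: all 2⁸ shard-availability
subsets of an N = 8, 1 KiB object (reconstruction must succeed for all 163
subsets of size ≥ 4 and fail below); the full 0–100 availability sweep on
a 100-node channel; every single-character corruption of a 10-block
ledger; 200 random public-API operation sequences against one DID; resync
after 1, 5 and 20 missed commits; and the full 256×256 field
multiplication table against an independently written shift-and-xor
multiplier. Gaussian elimination over GF(2⁸) needs no pivoting tolerance —
arithmetic is exact — and the only tie-break in the system is the
bytewise key ordering of the canonical form.

## Worked example

```{r lifecycle}
platform <- create_platform()   # 3 organizations, 2 EVC + 3 storage nodes each

corpus <- generate_corpus(seed = 42, n_records = 2)
up <- upload(platform, "alice", "alice-secret",
             corpus$record[[1]], corpus$payload[[1]])
up$did

rev <- corpus$record[[1]]
rev$values$Description <- "corrected after measurement review"
update_metadata(platform, "bob", "bob-secret", up$did, rev)$version

tidy(platform_history(platform, up$did))

down <- download(platform, "carol", "carol-secret", up$did)
identical(down$payload, corpus$payload[[1]])
```

```{r liveness, fig.width = 6, fig.height = 3}
sweep <- liveness_sweep(n_nodes = 20)
autoplot(sweep)
```

## Known limitations

All actors are in-process: there is no real networking, TLS, certificate
infrastructure, gossip, or multi-orderer consensus, and orderer failure is
not modeled. Tamper detection is by digest only. Blocks use a linear
payload hash rather than Merkle trees, which is adequate at desk scale but
not for partial block proofs. The template language covers the rules the
enforced standards state; it is not an ontology service, and vocabulary
governance is left to the consortium.
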